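---
title: "Reference-based compression of similar genome collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based compression of similar genome collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refzip)
```

## The problem

Public archives hold tens of thousands of assemblies per bacterial species.
Within a species, genomes are nearly identical: long stretches are shared
verbatim, and a substantial fraction of the remaining differences are
segmental inversions, i.e. stretches that recur as the *reverse complement*
of sequence seen in another isolate. A compressor that only models direct
repeats leaves that second kind of redundancy on the table; a compressor
that keeps every previous genome as a dictionary drowns in memory.

`refzip` addresses both: it factors each contig into LZ-matches against a
single growing reference buffer that physically contains reverse-complement
copies, and it admits new sequence into that buffer only when it is novel
enough to pay for its memory.

## The model

Let G₁, …, Gₙ be the input genomes (ordered FASTA files; a "contig" here is
simply one FASTA record). The encoder maintains:

* **REF** — a byte buffer. In default mode it is initialized with G₁
  followed by rc(G₁); the decoder can rebuild this because G₁ itself is
  shipped through the literal stream. In max mode REF starts empty and G₁
  is encoded like any other genome.
* **A seed index** — a flat hash table of `2^table_bits` slots mapping a
  k-mer hash to one REF position. REF is sampled sparsely, every `stride`
  symbols; a collision simply overwrites the slot. Lookup therefore costs
  O(1) and the table never grows. Seeds containing non-ACGT symbols are
  never indexed.

Encoding a contig scans left to right. At each position the k-mer is hashed
and the candidate REF position (if any) is verified symbol by symbol —
verification is what makes hash collisions, and entries stale after a
buffer wrap, harmless. A verified seed is extended maximally right and
left. Extension compares raw bytes, so `N` runs extend only over `N` in
REF, and matches never cross the target contig's boundaries (REF-side
matches may span the concatenation, since REF is flat). Unmatched symbols
accumulate into literal runs.

Three mechanisms distinguish the scheme from textbook greedy LZ:

* **Swallowing.** The left extension of a new match may consume the pending
  literal run symbol by symbol and absorb *wholly covered* earlier tokens;
  a partially overlapped token truncates the extension at its boundary.
  One long match replaces several short ones, shrinking the token streams.
* **Skip margin.** After emitting a match ending at `e`, scanning resumes
  at `max(e − m, s + 1)` (`s` = the emitted token's start). Re-scanning the
  last `m` symbols lets a longer overlapping match be found and swallow its
  predecessor. The `s + 1` term guarantees progress. A consequence worth
  stating: when a new match partially overlaps the previous token, the
  truncated emission may be shorter than `k` — seeds are always `k` long,
  emitted tokens need not be.
* **Append policy.** At the end of each contig, the contig (and its reverse
  complement, when RC matching is on) is appended to REF only if its
  unmatched portion strictly exceeds `1/u` of its length
  (`unmatched · u > len`). Redundant contigs would enlarge REF without
  offering new matches. Once REF reaches `ref_limit` bytes it is
  overwritten circularly from position 0. Stale index entries are not
  purged: verification rejects them, and because the decoder replays REF
  byte-identically, even a match into overwritten content would be
  self-consistent.

The decoder is the exact inverse: it replays tokens against a REF rebuilt
under the same append/wrap policy, reading each append decision from an
explicit per-contig flag rather than re-deriving it from the threshold —
this keeps the decoder independent of encoder heuristics. Round trips are
exact at the (header, sequence) level; the original line layout of
sequences is deliberately not preserved (output has no line breaks by
default, or breaks at a user-chosen width).

## Parameters

| parameter    | default            | meaning and rationale                     |
|--------------|--------------------|-------------------------------------------|
| `k`          | 32 symbols         | seed length; long enough that spurious hits are rare in megabase references, configurable down to 4 for small test regimes |
| `stride`     | 16 symbols         | REF sampling interval: 16× smaller index at modest match-start loss (extensions recover most of it) |
| `skip_margin`| 16 symbols         | overlap re-scan window after each match    |
| `u`          | 192                | append threshold divisor: a contig must be >1/192 novel to enter REF |
| `table_bits` | 25                 | 2²⁵ slots; one 64-bit position per slot (256 MiB) |
| `ref_limit`  | 2³² (default) / 2⁴⁰ (max) | REF capacity before circular overwrite |
| `rc`         | on                 | store reverse complements in REF           |
| `swallow`    | on                 | left-extension token absorption            |
| `level`      | 6 (default) / 9 (max) | LZMA effort preset for the archive back end |

The k-mer hash packs symbols at 2 bits each; when `2k ≤ table_bits` the
packing addresses the table directly, making the hash *perfect* for short
seeds — the small-`k` test regime is thereby collision-free by
construction, which the oracle-equivalence test exploits. Longer seeds go
through a 64-bit multiply/xor-shift finalizer and take the top
`table_bits` bits.

## Numerical and degenerate-input choices

* Positions and offsets are 0-based, intervals half-open, matching the
  on-disk streams ([FORMAT.md](../FORMAT.md)).
* The complement table covers the full IUPAC alphabet and maps unknown
  bytes to themselves, so reverse complement is a total involution on
  arbitrary input.
* Empty contigs encode to zero tokens; an empty collection produces a
  valid, empty archive. A first genome larger than half the reference
  limit (RC on) is a configuration error in default mode.
* Collisions overwrite index slots (newest position wins); ties and stale
  entries resolve through verification, never through bookkeeping.
* Sequences are uppercased on read; lowercase soft-masking is not
  preserved.
* Streams that the LZMA back end cannot shrink are stored raw, so tiny
  archives do not pay the container overhead ten times.

## What the simulator emulates

`sim_params()` describes collections of near-identical genomes derived
from one random ancestor: substitutions (always to a different base),
indels with geometric lengths, reverse-complemented inversions (the
designated mechanism for exercising RC matching), and fragmentation into
contigs. Each genome draws from an RNG substream keyed by its index, so a
collection can be extended without disturbing existing genomes, and the
whole construction is deterministic for a fixed seed.

It does **not** emulate biological evolution: no phylogenetic structure
(every genome is one mutational step from the ancestor), no horizontal
transfer, no mobile elements, no GC skew, no codon structure. Passing tests
on simulated collections therefore demonstrates correctness of the codec
and the expected qualitative responses of the ratio to redundancy, RC
content and the swallowing mechanism — not the absolute ratios achievable
on real species collections, which have deeper (inter-isolate, not just
ancestor-descendant) redundancy.

## Design choices where the design was open

* **Controlled comparison for the swallowing benefit.** Toggling swallowing
  changes per-contig unmatched counts, which feeds back into the append
  policy and gives the two runs different reference dictionaries; on
  inversion-rich fixtures the swallow-off run can end up with *fewer*
  tokens purely because its bloated REF offers more match starts. The token
  count comparison in the tests therefore holds the reference fixed (seeded
  with G₁, appends disabled), isolating the mechanism; the archive-size
  comparison runs the full pipeline, where swallowing wins on every
  fixture.
* **Append decisions are stored, not recomputed.** One bit per contig
  decouples the decoder from the threshold heuristic and tolerates future
  policy changes.
* **REF-side matches may cross contig joins.** REF is a flat
  concatenation; only target-side extension stops at contig boundaries.
* **Single-worker encoding.** Genome order is strictly preserved and
  output is a pure function of input and parameters. Concurrency, if ever
  added, must not change the emitted streams (a `--threads` CLI flag is
  accepted but only ever parallelizes input reading).
* **LZMA for every stream** via the system liblzma, with a per-stream
  back-end id byte in the directory so alternate codecs can be added
  without a format break.
* **Offsets stored absolute** (not delta-coded): simpler, and the LZMA
  stage already exploits their regularity.

## Problem sizes used in the tests

The shipped suite runs collections from degenerate (empty, all-N, empty
contigs) through a 48-point parameter grid at a few kilobases per genome,
up to 100 near-identical 1-Mbp genomes for the redundancy-scaling check
and a 10-MB collection forced through a 64-kB circular reference for the
wrap stress test. These sizes keep the whole suite around a minute on one
CPU while exercising every code path the full-scale tool would use; the
scaling behaviour (ratio ≈ 3.6 → 35 → 283 for 1 → 10 → 100 genomes) is
computed by `scripts/acceptance.R`, not asserted from memory.

## Known limitations

* No random access: restoring one genome replays the whole prefix of the
  collection (the append policy makes REF history-dependent).
* No mismatch-tolerant matches; a single substitution splits a match.
* Compression of *dissimilar* collections degrades gracefully to roughly
  LZMA-of-literals, but no better.
* The archive format is this package's own; it does not read or write any
  other tool's containers.
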