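# refzip

Lossless compression of collections of highly similar genomes in FASTA
format — the situation a sequence archive faces when it stores thousands of
assemblies of one bacterial species. General-purpose compressors see each
genome afresh; `refzip` exploits the two dominant forms of redundancy in
such collections: long shared segments between isolates, and segments that
recur as **reverse complements** of segments seen elsewhere.

## How it works

Genomes G₁, …, Gₙ are processed in order. A reference buffer REF is seeded
with G₁ followed by rc(G₁), its reverse complement (so RC repeats become
ordinary substring matches). Every later contig is factored into LZ-matches
`(offset, length)` against REF plus literal runs:

* **Seeding.** REF positions are sampled every `stride` (16) symbols; each
  valid k-mer (k = 32, pure ACGT) is hashed into a fixed-size table
  (2²⁵ slots, collisions overwrite). A contig position with a verified hash
  hit becomes a match and is extended maximally in both directions.
* **Swallowing.** The left extension may absorb wholly covered earlier
  tokens, replacing several short tokens with one long match. After a match
  ending at `e`, scanning resumes at `e − m` (m = 16, the *skip margin*) so
  an overlapping longer match can still be found.
* **Reference growth.** At each contig end, the unmatched portion is
  checked: only if it exceeds 1/u of the contig length (u = 192) are the
  contig and its reverse complement appended to REF — near-duplicate
  contigs add nothing but memory. When REF reaches its capacity (2³² bytes
  by default, 2⁴⁰ in max mode) it becomes a circular buffer, overwritten
  from the start.
* **Back end.** The separated streams (offsets, lengths, literals, headers,
  file names, flags) are LZMA-compressed into a self-describing archive
  ([FORMAT.md](FORMAT.md)). The decoder replays the streams while rebuilding
  REF under the identical append/wrap policy — the round trip is exact at
  the (header, sequence) level; sequence line breaks are not preserved
  (none by default, or inserted at a user-chosen width).

`max` mode starts from an empty REF and runs every genome, including the
first, through the ordinary policy, trading speed for ratio. A deterministic
simulator of near-identical genome collections (SNPs, indels,
reverse-complemented inversions, contig fragmentation) is included as the
test-fixture source.

## Worked example

```r
library(refzip)

sim <- sim_params(ancestor_len = 1e5, n_genomes = 8, snp_rate = 5e-4,
                  inversion_rate = 4, inversion_len = c(1000, 4000), seed = 424)
dir <- tempfile(); paths <- generate_collection(sim, dir)

arc <- tempfile(fileext = ".rfz")
compress_genomes(basename(paths), arc, encoder_params(), base_dir = dir)
#> compressed 800361 bytes into 32778 bytes (ratio 24.418) across 8 file(s)

out <- tempfile()
decompress_genomes(arc, out, line_width = 70)
identical(read_fasta(file.path(out, "g001.fa"), name = "g001.fa"),
          read_fasta(paths[1], name = "g001.fa"))
#> [1] TRUE
```

The ratio line reports end-of-line-stripped input bytes over archive bytes
(24.4× here on eight 100-kb genomes). Turning reverse-complement matching
off on this inversion-rich collection (`encoder_params(rc = FALSE)`) grows
the archive by a factor of about 1.3 — the cost of treating inversions as
novel sequence.

The same operations are available from a shell via the installed script:

```sh
refzip compress -i genomes/ -o collection.rfz
refzip decompress -i collection.rfz -o restored/ --line-width 70
refzip simulate --config sim.json -o fixtures/
```

(`inst/cli/refzip`; exit codes 0 = ok, 1 = usage, 2 = I/O, 3 = corruption.)

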