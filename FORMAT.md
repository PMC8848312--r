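# refzip archive format, version 1

A refzip archive is a single binary file holding the separated, back-end
compressed streams produced by the matching engine, plus enough metadata to
decode without external configuration. All multi-byte integers are unsigned
LEB128 varints (7 value bits per byte, least-significant group first, high
bit set on every byte except the last). All offsets and positions are
0-based. This format is self-contained and is **not** compatible with any
other tool's container.

## Layout

| field          | size      | contents                                        |
|----------------|-----------|-------------------------------------------------|
| magic          | 4 bytes   | ASCII `RFZA`                                    |
| version        | 1 byte    | `0x01`                                          |
| params block   | varint + N| length-prefixed parameter echo (below)          |
| stream count   | varint    | always 10 in version 1                          |
| directory      | variable  | one entry per stream, in id order               |
| payloads       | variable  | concatenated stream payloads, directory order   |

## Params block

A varint byte length, then exactly eight varints:

```
k  stride  skip_margin  u  table_bits  ref_limit  flags  level
```

`flags` is a bitmask: bit 0 = reverse-complement matching enabled, bit 1 =
swallowing enabled, bit 2 = max mode (0 = default mode).

## Stream directory

Each entry is:

```
id (1 byte)  backend (1 byte)  raw_size (varint)  compressed_size (varint)
```

`backend` 0 means the payload is stored raw (used when compression does not
shrink a stream); 1 means LZMA (xz container, whole-buffer). The sum of all
`compressed_size` values must equal the number of bytes remaining in the
file; any mismatch is reported as truncation.

## Streams

| id | name          | encoding                                             |
|----|---------------|------------------------------------------------------|
| 1  | filenames     | NUL-terminated relative paths, collection order      |
| 2  | contig_counts | varints, one per file                                |
| 3  | headers       | NUL-terminated header lines, contig order            |
| 4  | appended      | bit-packed flags (LSB first), one per contig         |
| 5  | token_counts  | varints, one per contig                              |
| 6  | token_kinds   | bit-packed (LSB first), 0 = literal run, 1 = match   |
| 7  | match_offsets | varints, reference offsets in token order            |
| 8  | match_lengths | varints, parallel to match_offsets                   |
| 9  | literal_lens  | varints, literal-run lengths in token order          |
| 10 | literal_bytes | raw literal symbols, concatenated                    |

Counts chain together: the number of files is the number of NUL terminators
in stream 1; contigs are `sum(contig_counts)`; tokens are
`sum(token_counts)`; matches are the number of 1 bits among the first
`sum(token_counts)` kind bits; literal runs are the rest; the literal byte
stream length must equal `sum(literal_lens)`.

## Decoding contract

The decoder replays contigs in order, consuming tokens per `token_counts`
and `token_kinds`: a literal run copies `literal_lens[i]` bytes from the
literal stream; a match copies `match_lengths[j]` bytes from the reference
buffer at `match_offsets[j]`. In default mode the first file is rebuilt
purely from literals, after which the concatenation of its contigs followed
by its reverse complement initializes the reference. For every later contig
whose `appended` flag is set, the contig and (when flag bit 0 of the params
is set) its reverse complement are written at the reference append cursor,
wrapping circularly once `ref_limit` is reached. A match whose
`offset + length` exceeds the current valid reference extent, or any stream
exhausted early or left with trailing data, is archive corruption.
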