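Package: refzip
Title: Reference-Based Compression of Collections of Similar Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless compressor for collections of highly similar genomes in
    FASTA format, such as assemblies of many isolates of one bacterial species.
    Each contig is factored into LZ-matches against an incrementally grown
    reference buffer that also holds reverse complements, so segmental
    inversions compress as well as direct repeats. The reference is extended
    only by contigs that carry enough novel sequence, and once it reaches its
    capacity it is overwritten circularly. Match, literal and metadata streams
    are serialized compactly and compressed with LZMA into a self-describing
    archive; an exact inverse decoder reconstructs every file, header and
    contig byte for byte (modulo sequence line wrapping). Includes a
    deterministic simulator of near-identical genome collections with point
    mutations, indels and reverse-complemented inversions, and a command-line
    interface for compression, decompression and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
SystemRequirements: liblzma
Config/testthat/edition: 3
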