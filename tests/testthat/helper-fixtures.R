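# Shared fixture builders. Everything is generated in code; tests that need
# files write them under withr-free tempfile() dirs.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n, alphabet = BASES4) {
  if (n == 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a reference whose k-mers are all distinct, so the seed index is
# collision-free and the greedy parse at any position is unique
unique_seed_ref <- function(n, k) {
  repeat {
    s <- rand_seq(n)
    kmers <- substring(s, 1:(n - k + 1), k:n)
    if (!anyDuplicated(kmers)) return(s)
  }
}

# random genome_file, optionally with an empty contig and an N-run contig
rand_genome_file <- function(name, n_contigs = 2, len = 500,
                             with_empty = FALSE, with_n_run = FALSE) {
  seqs <- vapply(seq_len(n_contigs), function(i) rand_seq(len), character(1))
  if (with_n_run) {
    seqs <- c(seqs, paste0(rand_seq(50), strrep("N", 40), rand_seq(50)))
  }
  if (with_empty) seqs <- append(seqs, "", after = 1)
  genome_file(name, sprintf("%s contig %d", name, seq_along(seqs)), seqs)
}

# collection of near-identical genomes: mutated copies of one base sequence
mutated_collection <- function(n_genomes, len, n_mut = 20, n_contigs = 1) {
  base <- rand_seq(len)
  lapply(seq_len(n_genomes), function(i) {
    x <- strsplit(base, "", fixed = TRUE)[[1]]
    if (n_mut > 0) {
      idx <- sample(length(x), min(n_mut, length(x)))
      x[idx] <- sample(BASES4, length(idx), replace = TRUE)
    }
    bounds <- unique(c(0, sort(sample(length(x) - 1, n_contigs - 1)), length(x)))
    seqs <- vapply(seq_len(length(bounds) - 1), function(j) {
      paste(x[(bounds[j] + 1):bounds[j + 1]], collapse = "")
    }, character(1))
    genome_file(sprintf("g%02d.fa", i),
                sprintf("g%02d contig %d", i, seq_along(seqs)), seqs)
  })
}

# small-table params so tests do not allocate the default 2^25-slot index
test_params <- function(...) {
  args <- list(...)
  if (is.null(args$table_bits)) args$table_bits <- 16L
  do.call(encoder_params, args)
}

expect_collection_equal <- function(decoded, original) {
  expect_equal(length(decoded), length(original))
  for (i in seq_along(original)) {
    expect_identical(unclass(decoded[[i]]), unclass(original[[i]]))
  }
}

roundtrip <- function(genomes, params) {
  decode_streams(encode_collection(genomes, params))
}
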