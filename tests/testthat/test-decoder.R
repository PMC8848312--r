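manual_stream_set <- function(params, filenames, contig_counts, headers,
                              appended, token_counts, kinds, offsets,
                              lengths, lit_lens, lit_bytes) {
  structure(list(
    params = params, filenames = filenames,
    contig_counts = as.integer(contig_counts), headers = headers,
    appended = appended, token_counts = as.numeric(token_counts),
    token_kinds = as.raw(kinds), match_offsets = as.numeric(offsets),
    match_lengths = as.numeric(lengths), literal_lens = as.numeric(lit_lens),
    literal_bytes = lit_bytes
  ), class = "stream_set")
}

test_that("token replay concatenates literals and reference slices", {
  # contig 1 ("ACGT") is appended, so the reference reads "ACGTACGT" when
  # contig 2 = [Literal "AC", Match(0, 4)] is replayed -> "ACACGT"
  p <- test_params(k = 4, table_bits = 8, mode = "max")
  ss <- manual_stream_set(
    p, "f.fa", 2, c("c1", "c2"), c(TRUE, FALSE),
    token_counts = c(1, 2), kinds = c(0, 0, 1),
    offsets = 0, lengths = 4, lit_lens = c(4, 2),
    lit_bytes = charToRaw("ACGTAC")
  )
  out <- decode_streams(ss)
  expect_identical(out[[1]]$sequence, c("ACGT", "ACACGT"))

  # zero tokens decode to an empty contig
  ss0 <- manual_stream_set(p, "f.fa", 1, "empty", FALSE, token_counts = 0,
                           kinds = raw(), offsets = numeric(),
                           lengths = numeric(), lit_lens = numeric(),
                           lit_bytes = raw())
  expect_identical(decode_streams(ss0)[[1]]$sequence, "")
})

test_that("corrupt streams are rejected with corruption errors", {
  p <- test_params(k = 4, table_bits = 8, mode = "max")
  # match offset beyond the (empty) reference extent
  bad <- manual_stream_set(p, "f.fa", 1, "c", FALSE, token_counts = 1,
                           kinds = 1, offsets = 100, lengths = 4,
                           lit_lens = numeric(), lit_bytes = raw())
  expect_error(decode_streams(bad), class = "refzip_corruption")
  # more tokens promised than present
  bad2 <- manual_stream_set(p, "f.fa", 1, "c", FALSE, token_counts = 3,
                            kinds = c(0, 0), offsets = numeric(),
                            lengths = numeric(), lit_lens = c(1, 1),
                            lit_bytes = charToRaw("AC"))
  expect_error(decode_streams(bad2), class = "refzip_corruption")
})

test_that("decode(encode(C)) reproduces random collections byte-exactly", {
  set.seed(88)
  for (rep in 1:10) {
    gs <- c(
      mutated_collection(sample(2:4, 1), sample(500:2000, 1), n_mut = 15,
                         n_contigs = sample(1:3, 1)),
      list(rand_genome_file("extra.fa", n_contigs = 2, len = 300,
                            with_empty = TRUE, with_n_run = TRUE))
    )
    p <- test_params(k = sample(c(4, 8, 16), 1), table_bits = 12,
                     mode = sample(c("default", "max"), 1),
                     rc = sample(c(TRUE, FALSE), 1))
    expect_collection_equal(roundtrip(gs, p), gs)
  }
})

test_that("decoder reference stays in lockstep with the encoder", {
  set.seed(99)
  gs <- mutated_collection(5, 800, n_mut = 120, n_contigs = 2)
  # small limit forces wraps mid-collection; u = 2 forces frequent appends
  p <- test_params(k = 8, table_bits = 12, mode = "max", ref_limit = 3000,
                   u = 2)
  # drive the engine manually, snapshotting after each contig
  enc <- new_encoder(p)
  enc_refs <- list()
  for (g in gs) {
    for (s in g$sequence) {
      e <- encode_contig(enc, s)
      if (unmatched_exceeds_threshold(e$unmatched, nchar(s), p$u)) {
        append_contig(enc, s)
      }
      enc_refs[[length(enc_refs) + 1]] <- ref_bytes(enc, as = "raw")
      expect_lte(ref_state(enc)$extent, p$ref_limit)
    }
  }
  expect_true(ref_state(enc)$wrapped)
  # the pipeline is deterministic, so encode_collection replays identically
  ss <- encode_collection(gs, p)
  out <- decode_streams(ss, capture_ref = TRUE)
  dec_refs <- attr(out, "refs")
  expect_length(dec_refs, length(enc_refs))
  for (i in seq_along(enc_refs)) {
    expect_identical(dec_refs[[i]], enc_refs[[i]])
  }
  expect_collection_equal(out, gs)
})

test_that("decompressed files re-read equal at any line width", {
  set.seed(111)
  gs <- mutated_collection(3, 700)
  p <- test_params(k = 8, table_bits = 12)
  arc <- tempfile()
  write_archive(encode_collection(gs, p), arc)
  for (w in c(0, 70)) {
    out_dir <- tempfile()
    paths <- decode_collection(arc, out_dir, line_width = w)
    back <- lapply(seq_along(paths),
                   function(i) read_fasta(paths[i], name = gs[[i]]$name))
    expect_collection_equal(back, gs)
  }
  # gzip output round-trips as well
  out_dir <- tempfile()
  paths <- decode_collection(arc, out_dir, gzip_out = TRUE)
  expect_true(all(grepl("\\.gz$", paths)))
  back <- lapply(seq_along(paths),
                 function(i) read_fasta(paths[i], name = gs[[i]]$name))
  expect_collection_equal(back, gs)
})
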