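test_that("default-mode reference is the first genome plus its reverse complement", {
  cases <- list(
    list(seqs = "ACGT", ref = "ACGTACGT"),
    list(seqs = "AAC", ref = "AACGTT"),
    list(seqs = c("AC", "GT"), ref = "ACGTACGT")  # contigs concatenated first
  )
  for (cs in cases) {
    enc <- new_encoder(test_params(k = 4, table_bits = 8))
    init_reference(enc, genome_file("g.fa", seq_along(cs$seqs), cs$seqs))
    expect_identical(ref_bytes(enc), cs$ref)
  }
})

test_that("a first genome exceeding half the reference limit is rejected", {
  enc <- new_encoder(test_params(k = 4, table_bits = 8, ref_limit = 10))
  expect_error(init_reference(enc, genome_file("g.fa", "c", "ACGTACGT")),
               class = "refzip_usage_error")
})

test_that("indexing samples by stride and skips seeds containing N", {
  p <- test_params(k = 4, stride = 16, table_bits = 8, rc = FALSE)
  enc <- new_encoder(p)
  append_contig(enc, "AAAAAAAA")
  # stride exceeds the range: only position 0 sampled
  expect_identical(index_slot(enc, hash_kmer("AAAA", 8)), 0)

  p2 <- test_params(k = 4, stride = 4, table_bits = 8, rc = FALSE)
  enc2 <- new_encoder(p2)
  append_contig(enc2, "ACGTNNNNACGT")
  # positions 0 and 8 hold "ACGT" (8 overwrites 0); position 4 is invalid
  expect_identical(index_slot(enc2, hash_kmer("ACGT", 8)), 8)
  expect_identical(find_candidate(enc2, "ACGT", 0), 8)
})

test_that("hash collisions keep the later position and fail verification", {
  # with table_bits < 2k the packing is mixed and collisions exist; find one
  # by enumerating all 4-mers at a 16-slot table
  kmers <- do.call(paste0, expand.grid(BASES4, BASES4, BASES4, BASES4,
                                       stringsAsFactors = FALSE))
  slots <- hash_kmer(kmers, 4)
  dup_slot <- slots[anyDuplicated(slots)]
  pair <- kmers[slots == dup_slot][1:2]
  expect_false(pair[1] == pair[2])

  p <- test_params(k = 4, stride = 1, table_bits = 4, rc = FALSE)
  enc <- new_encoder(p)
  append_contig(enc, paste0(pair[1], pair[2]))
  # both 4-mers hash to the same slot; the later (position 4) wins
  expect_identical(index_slot(enc, dup_slot), 4)
  # looking up the earlier k-mer hits the slot but fails verification
  expect_null(find_candidate(enc, pair[1], 0))
  expect_identical(find_candidate(enc, pair[2], 0), 4)
})

test_that("candidate lookup agrees with a linear reference scan", {
  set.seed(33)
  p <- test_params(k = 8, stride = 1, table_bits = 16, rc = FALSE)
  for (rep in 1:20) {
    ref <- rand_seq(300)
    enc <- new_encoder(p)
    append_contig(enc, ref)
    pos <- sample(0:(300 - 8), 1)
    kmer <- substr(ref, pos + 1, pos + 8)
    got <- find_candidate(enc, kmer, 0)
    occurrences <- gregexpr(kmer, ref, fixed = TRUE)[[1]] - 1
    expect_true(got %in% occurrences)
    expect_identical(substr(ref, got + 1, got + 8), kmer)
    # a k-mer absent from the reference finds nothing
    repeat {
      absent <- rand_seq(8)
      if (!grepl(absent, ref, fixed = TRUE)) break
    }
    expect_null(find_candidate(enc, absent, 0))
  }
})

test_that("left extension swallows earlier tokens into one long match", {
  p <- test_params(k = 4, stride = 1, skip_margin = 0, table_bits = 8,
                   rc = FALSE)
  enc <- new_encoder(p)
  append_contig(enc, "AAAAAAAAAA")
  e <- encode_contig(enc, "AAAAAAAAAA")
  toks <- encoding_tokens(e)
  # swallowing merges everything reachable into a single long match
  expect_identical(sum(toks$kind == "match"), 1L)
  expect_identical(replay_encoding(e, ref_bytes(enc)), "AAAAAAAAAA")
  expect_identical(sum(toks$length), 10)

  # without swallowing the same input needs at least as many tokens
  enc2 <- new_encoder(test_params(k = 4, stride = 1, skip_margin = 0,
                                  table_bits = 8, rc = FALSE, swallow = FALSE))
  append_contig(enc2, "AAAAAAAAAA")
  e2 <- encode_contig(enc2, "AAAAAAAAAA")
  expect_gte(length(e2$kinds), length(e$kinds))
  expect_identical(replay_encoding(e2, ref_bytes(enc2)), "AAAAAAAAAA")
})

test_that("a contig matching an indexed region becomes a single match token", {
  set.seed(44)
  ref <- unique_seed_ref(300, 8)
  p <- test_params(k = 8, stride = 1, skip_margin = 0, table_bits = 16,
                   rc = FALSE)
  enc <- new_encoder(p)
  append_contig(enc, ref)
  contig <- substr(ref, 21, 121)
  e <- encode_contig(enc, contig)
  toks <- encoding_tokens(e)
  expect_identical(nrow(toks), 1L)
  expect_identical(toks$kind, "match")
  expect_identical(toks$ref_offset, 20)
  expect_identical(toks$length, 101)
  expect_identical(e$unmatched, 0)
})

test_that("contigs sharing nothing with the reference are one literal run", {
  p <- test_params(k = 8, table_bits = 8, rc = FALSE)
  enc <- new_encoder(p)
  append_contig(enc, strrep("A", 100))
  e <- encode_contig(enc, strrep("C", 50))
  expect_identical(as.integer(e$kinds), 0L)
  expect_identical(e$literal_lens, 50)
  expect_identical(e$unmatched, 50)
  # empty contig: no tokens at all
  e0 <- encode_contig(enc, "")
  expect_length(e0$kinds, 0)
  expect_identical(e0$unmatched, 0)
})

test_that("factorization always reconstructs the contig exactly", {
  set.seed(55)
  for (rep in 1:30) {
    k <- sample(c(4, 8), 1)
    p <- test_params(k = k, stride = sample(c(1, 4, 16), 1),
                     skip_margin = sample(c(0, 3, 16), 1),
                     table_bits = 10, rc = sample(c(TRUE, FALSE), 1),
                     swallow = sample(c(TRUE, FALSE), 1))
    enc <- new_encoder(p)
    ref <- rand_seq(400)
    append_contig(enc, ref)
    # contigs stitched from reference substrings, their RC, and noise
    parts <- replicate(6, {
      u <- runif(1)
      if (u < 0.4) {
        a <- sample(300, 1)
        substr(ref, a, a + sample(5:60, 1))
      } else if (u < 0.6) {
        a <- sample(300, 1)
        reverse_complement(substr(ref, a, a + sample(5:60, 1)))
      } else {
        rand_seq(sample(0:30, 1))
      }
    })
    contig <- paste(parts, collapse = "")
    e <- encode_contig(enc, contig)
    expect_identical(replay_encoding(e, ref_bytes(enc)), contig)
    expect_equal(sum(e$lengths) + sum(e$literal_lens), nchar(contig),
                 tolerance = 0)
    ext <- ref_state(enc)$extent
    expect_true(all(e$offsets + e$lengths <= ext))
  }
})

test_that("the append threshold is strict in the stated direction", {
  expect_false(unmatched_exceeds_threshold(1, 192, u = 192))
  expect_true(unmatched_exceeds_threshold(2, 192, u = 192))
  expect_false(unmatched_exceeds_threshold(0, 0, u = 192))
  expect_false(unmatched_exceeds_threshold(0, 1e9, u = 192))
})

test_that("appending wraps circularly at the capacity limit", {
  p <- test_params(k = 4, table_bits = 8, ref_limit = 8)
  enc <- new_encoder(p)
  append_contig(enc, "AAC")  # + rc "GTT" -> "AACGTT", end 6
  s <- ref_state(enc)
  expect_identical(s$end, 6)
  expect_false(s$wrapped)
  append_contig(enc, "ACGT")  # 8 bytes with rc: 2 fit, 6 wrap to the front
  s <- ref_state(enc)
  expect_true(s$wrapped)
  expect_identical(s$extent, 8)
  expect_identical(s$write_pos, 6)
  # first two bytes of "ACGTACGT" landed at 6..8, the rest overwrote 0..6
  expect_identical(ref_bytes(enc), "GTACGTAC")
  # below-threshold contigs leave the reference untouched (policy level)
  expect_false(unmatched_exceeds_threshold(0, 4))
})

test_that("the valid extent never exceeds the limit, even for huge appends", {
  p <- test_params(k = 4, table_bits = 8, ref_limit = 64)
  enc <- new_encoder(p)
  set.seed(66)
  for (i in 1:5) {
    append_contig(enc, rand_seq(sample(c(3, 40, 200), 1)))
    expect_lte(ref_state(enc)$extent, 64)
  }
  expect_true(ref_state(enc)$wrapped)
})

test_that("collection encoding is deterministic and covers redundant input", {
  set.seed(77)
  gs <- mutated_collection(10, 2000, n_mut = 0)  # identical genomes
  p <- test_params(k = 16, table_bits = 14)
  ss1 <- encode_collection(gs, p)
  ss2 <- encode_collection(gs, p)
  expect_identical(unclass(ss1), unclass(ss2))
  covered <- sum(ss1$match_lengths)
  total <- stream_set_symbols(ss1)
  expect_gte(covered / total, 0.9)
  # a single genome in default mode reconstructs from literals alone
  one <- encode_collection(gs[1], p)
  expect_length(one$match_offsets, 0)
  expect_collection_equal(decode_streams(one), gs[1])
})
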