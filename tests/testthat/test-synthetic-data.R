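test_that("ancestor generation is deterministic and near-uniform", {
  a1 <- generate_ancestor(1000, seed = 5)
  a2 <- generate_ancestor(1000, seed = 5)
  expect_identical(a1, a2)
  expect_false(identical(a1, generate_ancestor(1000, seed = 6)))

  big <- generate_ancestor(1e5, seed = 9)
  expect_identical(nchar(big), 100000L)
  freq <- table(strsplit(big, "", fixed = TRUE)[[1]])
  expect_setequal(names(freq), BASES4)
  # each base frequency within 5 sigma of 1/4 (binomial)
  sigma <- sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freq / 1e5 - 0.25) < 5 * sigma))
})

test_that("a mutation-free derivation reproduces the ancestor", {
  sim <- sim_params(ancestor_len = 5000, snp_rate = 0, indel_rate = 0,
                    inversion_rate = 0, contigs_per_genome = 1, seed = 3)
  anc <- generate_ancestor(5000, 3)
  g <- derive_genome(anc, sim, 1)
  expect_identical(g$sequence, anc)
})

test_that("substitution counts follow the binomial contract", {
  n <- 1e5
  sim <- sim_params(ancestor_len = n, snp_rate = 0.01, indel_rate = 0,
                    inversion_rate = 0, contigs_per_genome = 1, seed = 12)
  anc <- generate_ancestor(n, 12)
  g <- derive_genome(anc, sim, 1)
  a <- strsplit(anc, "", fixed = TRUE)[[1]]
  b <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
  hamming <- sum(a != b)
  # every substitution changes the base, so Hamming distance ~ Bin(n, 0.01)
  expect_lt(abs(hamming - n * 0.01), 5 * sqrt(n * 0.01 * 0.99))
})

test_that("inversions replace a segment by its reverse complement", {
  anc <- generate_ancestor(2000, 7)
  inv <- apply_inversion(anc, 501, 300)
  expect_identical(substr(inv, 1, 500), substr(anc, 1, 500))
  expect_identical(substr(inv, 801, 2000), substr(anc, 801, 2000))
  expect_identical(substr(inv, 501, 800),
                   reverse_complement(substr(anc, 501, 800)))
  # involution: inverting the same segment twice restores the input
  expect_identical(apply_inversion(inv, 501, 300), anc)
  expect_error(apply_inversion(anc, 1900, 300), class = "refzip_usage_error")
})

test_that("indels change length roughly as configured", {
  n <- 1e5
  sim <- sim_params(ancestor_len = n, snp_rate = 0, indel_rate = 2e-4,
                    indel_len_mean = 3, inversion_rate = 0,
                    contigs_per_genome = 1, seed = 21)
  anc <- generate_ancestor(n, 21)
  g <- derive_genome(anc, sim, 1)
  # insertions and deletions balance in expectation; the net shift stays
  # far below the total churn (~ 2e-4 * 3 * n = 60 symbols either way)
  expect_lt(abs(nchar(g$sequence) - n), 600)
  expect_false(identical(g$sequence, anc))
})

test_that("collections are deterministic on disk and honour n_genomes = 0", {
  sim <- sim_params(ancestor_len = 3000, n_genomes = 3, seed = 31,
                    inversion_len = c(100, 300))
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- generate_collection(sim, d1)
  p2 <- generate_collection(sim, d2)
  expect_identical(basename(p1), basename(p2))
  for (i in seq_along(p1)) {
    expect_identical(readBin(p1[i], "raw", file.size(p1[i])),
                     readBin(p2[i], "raw", file.size(p2[i])))
  }
  expect_identical(generate_collection(sim_params(n_genomes = 0), tempfile()),
                   character())
  # gzipped output parses back to the same genomes
  d3 <- tempfile()
  p3 <- generate_collection(sim, d3, gzip = TRUE)
  for (i in seq_along(p1)) {
    expect_identical(read_fasta(p3[i], name = "x")$sequence,
                     read_fasta(p1[i], name = "x")$sequence)
  }
})

test_that("per-genome substreams are stable under collection extension", {
  anc <- generate_ancestor(2000, 41)
  sim5 <- sim_params(ancestor_len = 2000, n_genomes = 5, seed = 41)
  sim9 <- sim_params(ancestor_len = 2000, n_genomes = 9, seed = 41)
  g3a <- derive_genome(anc, sim5, 3)
  g3b <- derive_genome(anc, sim9, 3)
  expect_identical(unclass(g3a), unclass(g3b))
})
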