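#' Simulation parameters for synthetic genome collections
#'
#' Describes a collection of near-identical genomes derived from one random
#' ancestor by point mutations, short indels and reverse-complemented
#' segmental inversions, fragmented into contigs. Fully deterministic for a
#' fixed seed (Mersenne-Twister, pinned).
#'
#' @param ancestor_len Ancestor length in symbols.
#' @param n_genomes Number of genomes in the collection.
#' @param snp_rate Per-symbol substitution probability (always to a
#'   different base).
#' @param indel_rate Per-symbol probability of starting an indel.
#' @param indel_len_mean Mean indel length (geometric).
#' @param inversion_rate Expected number of inversions per genome (Poisson).
#' @param inversion_len Length-2 vector: min and max inversion length.
#' @param contigs_per_genome Single count or length-2 range of contigs each
#'   genome is fragmented into.
#' @param seed RNG seed for the whole collection.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(ancestor_len = 1e5, n_genomes = 10L,
                       snp_rate = 0.001, indel_rate = 1e-4,
                       indel_len_mean = 3, inversion_rate = 2,
                       inversion_len = c(500L, 5000L),
                       contigs_per_genome = c(1L, 3L), seed = 1L) {
  p <- list(
    ancestor_len = as.numeric(ancestor_len), n_genomes = as.integer(n_genomes),
    snp_rate = as.numeric(snp_rate), indel_rate = as.numeric(indel_rate),
    indel_len_mean = as.numeric(indel_len_mean),
    inversion_rate = as.numeric(inversion_rate),
    inversion_len = as.integer(rep_len(inversion_len, 2L)),
    contigs_per_genome = as.integer(rep_len(contigs_per_genome, 2L)),
    seed = as.integer(seed)
  )
  if (p$ancestor_len < 1) stop_usage("ancestor_len must be >= 1")
  if (p$n_genomes < 0L) stop_usage("n_genomes must be >= 0")
  for (r in c(p$snp_rate, p$indel_rate)) {
    if (is.na(r) || r < 0 || r > 1) stop_usage("rates must be in [0, 1]")
  }
  structure(p, class = "sim_params")
}

BASES <- c("A", "C", "G", "T")

# Independent RNG substream per genome: hash the seed with the genome index
# so a collection can be extended without shifting existing genomes.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + index * 1013904223) %% 2147483647)
}

with_pinned_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate a random ancestor sequence
#'
#' Uniform i.i.d. over A, C, G, T; identical output for identical seed.
#'
#' @param len Length in symbols.
#' @param seed RNG seed.
#' @return A character string of length `len`.
#' @export
generate_ancestor <- function(len, seed = 1L) {
  if (len < 1) stop_usage("len must be >= 1")
  with_pinned_rng(seed, {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
  })
}

#' Replace a segment by its reverse complement
#'
#' The inversion primitive of the simulator: the `len` symbols starting at
#' 1-based position `start` are replaced by their reverse complement.
#'
#' @param x Character string or character vector of single symbols.
#' @param start 1-based start of the segment.
#' @param len Segment length.
#' @return Same type as `x`.
#' @export
apply_inversion <- function(x, start, len) {
  as_string <- is.character(x) && length(x) == 1L && nchar(x) > 1L
  v <- if (as_string) strsplit(x, "", fixed = TRUE)[[1L]] else x
  if (start < 1L || len < 1L || start + len - 1L > length(v))
    stop_usage("inversion segment out of range")
  seg <- paste(v[start:(start + len - 1L)], collapse = "")
  v[start:(start + len - 1L)] <- strsplit(reverse_complement(seg), "",
                                          fixed = TRUE)[[1L]]
  if (as_string) paste(v, collapse = "") else v
}

#' Derive one genome from an ancestor
#'
#' Applies substitutions (always to a different base), indels (geometric
#' lengths), and reverse-complemented inversions, then fragments the result
#' into contigs. Each genome uses an independent RNG substream keyed by
#' `genome_index`, so genomes are reproducible individually.
#'
#' @param ancestor Character string (e.g. from [generate_ancestor()]).
#' @param sim A [sim_params].
#' @param genome_index 1-based index of the genome within the collection.
#' @return A [genome_file] named `g<index>.fa`.
#' @export
derive_genome <- function(ancestor, sim, genome_index) {
  stopifnot(inherits(sim, "sim_params"))
  with_pinned_rng(substream_seed(sim$seed, genome_index), {
    x <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
    n <- length(x)
    # substitutions
    hit <- which(stats::runif(n) < sim$snp_rate)
    if (length(hit)) {
      shift <- sample(1:3, length(hit), replace = TRUE)
      idx <- (match(x[hit], BASES) - 1L + shift) %% 4L + 1L
      x[hit] <- BASES[idx]
    }
    # indels, assembled segment-wise in one pass; events landing inside an
    # earlier deletion are dropped
    starts <- which(stats::runif(length(x)) < sim$indel_rate)
    if (length(starts)) {
      lens <- stats::rgeom(length(starts), 1 / sim$indel_len_mean) + 1L
      del <- stats::runif(length(starts)) < 0.5
      parts <- vector("list", 2L * length(starts) + 1L)
      np <- 0L
      prev <- 1L
      for (i in seq_along(starts)) {
        s <- starts[i]
        if (s < prev) next
        if (del[i]) {
          if (s > prev) {
            np <- np + 1L
            parts[[np]] <- x[prev:(s - 1L)]
          }
          prev <- min(s + lens[i], length(x) + 1L)
        } else {
          np <- np + 1L
          parts[[np]] <- x[prev:s]
          np <- np + 1L
          parts[[np]] <- sample(BASES, lens[i], replace = TRUE)
          prev <- s + 1L
        }
      }
      if (prev <= length(x)) {
        np <- np + 1L
        parts[[np]] <- x[prev:length(x)]
      }
      x <- unlist(parts[seq_len(np)], use.names = FALSE)
    }
    # reverse-complemented inversions
    n_inv <- stats::rpois(1L, sim$inversion_rate)
    for (i in seq_len(n_inv)) {
      len <- if (sim$inversion_len[1L] == sim$inversion_len[2L]) {
        sim$inversion_len[1L]
      } else {
        sample(seq.int(sim$inversion_len[1L], sim$inversion_len[2L]), 1L)
      }
      if (len >= length(x)) next
      s <- sample.int(length(x) - len, 1L)
      x <- apply_inversion(x, s, len)
    }
    # fragmentation into contigs
    k <- if (sim$contigs_per_genome[1L] == sim$contigs_per_genome[2L]) {
      sim$contigs_per_genome[1L]
    } else {
      sample(seq.int(sim$contigs_per_genome[1L], sim$contigs_per_genome[2L]), 1L)
    }
    k <- max(1L, min(k, length(x)))
    cuts <- if (k > 1L) sort(sample.int(length(x) - 1L, k - 1L)) else integer()
    bounds <- c(0L, cuts, length(x))
    seqs <- vapply(seq_len(k), function(i) {
      paste(x[(bounds[i] + 1L):bounds[i + 1L]], collapse = "")
    }, character(1L))
    genome_file(sprintf("g%03d.fa", genome_index),
                sprintf("g%03d_contig%02d simulated", genome_index, seq_len(k)),
                seqs)
  })
}

#' Generate a synthetic genome collection on disk
#'
#' Writes `n_genomes` FASTA files derived from one shared ancestor.
#' Deterministic for a fixed seed: two runs produce byte-identical files.
#'
#' @param sim A [sim_params].
#' @param out_dir Output directory (created if missing).
#' @param gzip Write gzip-compressed FASTA files.
#' @return Character vector of the written paths, in collection order.
#' @export
generate_collection <- function(sim, out_dir, gzip = FALSE) {
  stopifnot(inherits(sim, "sim_params"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_io(sprintf("cannot create output directory '%s'", out_dir))
  if (sim$n_genomes == 0L) return(character())
  ancestor <- generate_ancestor(sim$ancestor_len, sim$seed)
  paths <- character(sim$n_genomes)
  for (i in seq_len(sim$n_genomes)) {
    g <- derive_genome(ancestor, sim, i)
    name <- if (gzip) paste0(g$name, ".gz") else g$name
    g$name <- name
    paths[i] <- file.path(out_dir, name)
    write_fasta(g, paths[i])
  }
  paths
}
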