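#' Decode a stream set back into genome files
#'
#' Exact inverse of [encode_collection()]: replays literal runs and matches
#' while rebuilding the reference buffer with the identical append and wrap
#' policy. Append decisions are read from the per-contig flags, never
#' recomputed, and the decoder never consults a seed index — correctness
#' depends only on the streams.
#'
#' @param ss A `stream_set` (from [encode_collection()] or
#'   [read_archive()]).
#' @param capture_ref If `TRUE`, attach a list of reference snapshots (one
#'   per contig, as raw vectors) as attribute `"refs"` — instrumentation
#'   for verifying encoder/decoder reference lockstep.
#' @return A list of [genome_file] objects in collection order.
#' @export
decode_streams <- function(ss, capture_ref = FALSE) {
  stopifnot(inherits(ss, "stream_set"))
  res <- tryCatch(
    cpp_decode_streams(
      unclass(ss$params), as.integer(ss$contig_counts), ss$token_counts,
      ss$token_kinds, ss$match_offsets, ss$match_lengths, ss$literal_lens,
      ss$literal_bytes, ss$appended, isTRUE(capture_ref)
    ),
    error = function(e) stop_corrupt(conditionMessage(e))
  )
  seqs <- vapply(res$sequences, rawToChar, character(1L))
  out <- vector("list", length(ss$filenames))
  at <- 0L
  for (i in seq_along(ss$filenames)) {
    n <- ss$contig_counts[[i]]
    idx <- if (n > 0L) at + seq_len(n) else integer()
    out[[i]] <- genome_file(ss$filenames[[i]], ss$headers[idx], seqs[idx])
    at <- at + n
  }
  if (isTRUE(capture_ref)) attr(out, "refs") <- res$refs
  out
}

#' Decompress an archive to FASTA files
#'
#' Recreates every file of the collection under `out_dir` with its stored
#' relative name (subdirectories are created as needed). Sequences are
#' written without end-of-line bytes by default; `line_width` inserts line
#' breaks at regular intervals. The original line layout of the input is
#' not preserved — the round trip is lossless at the (header, sequence)
#' level.
#'
#' @param archive Path to an archive written by [write_archive()] or
#'   [compress_genomes()].
#' @param out_dir Output directory (created if missing).
#' @param line_width Symbols per sequence line; 0 (default) writes each
#'   sequence on a single line.
#' @param gzip_out Write gzip-compressed FASTA; files whose stored name
#'   does not already end in `.gz` get the suffix appended.
#' @return Character vector of the written paths, invisibly.
#' @export
decode_collection <- function(archive, out_dir, line_width = 0L,
                              gzip_out = FALSE) {
  ss <- read_archive(archive)
  genomes <- decode_streams(ss)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_io(sprintf("cannot create output directory '%s'", out_dir))
  paths <- character(length(genomes))
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    rel <- g$name
    if (isTRUE(gzip_out) && !grepl("\\.gz$", rel)) rel <- paste0(rel, ".gz")
    path <- file.path(out_dir, rel)
    d <- dirname(path)
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE, showWarnings = FALSE))
      stop_io(sprintf("cannot create directory '%s'", d))
    write_fasta(g, path, line_width = line_width)
    paths[[i]] <- path
  }
  invisible(paths)
}
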