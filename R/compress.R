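#' Compress a genome collection to an archive
#'
#' Convenience wrapper: read the inputs, run [encode_collection()], write
#' the archive, and report sizes. The compression ratio is reported against
#' the end-of-line-stripped input by default (header and sequence bytes
#' actually encoded); `raw_ratio` reports against the on-disk file sizes
#' instead.
#'
#' @param inputs Character vector of FASTA paths (plain or gzip), in
#'   collection order, or a list of [genome_file] objects.
#' @param archive Output archive path.
#' @param params An [encoder_params].
#' @param base_dir Optional directory path inputs are resolved against.
#' @param raw_ratio Report the ratio against on-disk input bytes.
#' @param quiet Suppress the summary message.
#' @return Invisibly, a list with `input_bytes`, `archive_bytes`, `ratio`
#'   and `stream_sizes` (per-stream compressed bytes).
#' @export
compress_genomes <- function(inputs, archive, params = encoder_params(),
                             base_dir = NULL, raw_ratio = FALSE,
                             quiet = FALSE) {
  genomes <- if (is.character(inputs)) {
    read_collection(inputs, base_dir = base_dir)
  } else {
    inputs
  }
  ss <- encode_collection(genomes, params)
  write_archive(ss, archive)
  # input size net of EOL bytes: '>' + header + sequence per contig
  input_bytes <- sum(vapply(genomes, function(g) {
    sum(nchar(g$header, type = "bytes")) + length(g$header) +
      sum(nchar(g$sequence, type = "bytes"))
  }, numeric(1L)))
  if (isTRUE(raw_ratio)) {
    paths <- vapply(genomes, `[[`, character(1L), "name")
    if (!is.null(base_dir)) paths <- file.path(base_dir, paths)
    sizes <- suppressWarnings(file.size(paths))
    if (!anyNA(sizes)) input_bytes <- sum(sizes)
  }
  archive_bytes <- file.size(archive)
  streams <- serialize_streams(ss)
  stats <- list(
    input_bytes = input_bytes, archive_bytes = archive_bytes,
    ratio = input_bytes / archive_bytes,
    stream_sizes = vapply(streams, length, numeric(1L))
  )
  if (!quiet) {
    message(sprintf(
      "compressed %.0f bytes into %.0f bytes (ratio %.3f) across %d file(s)",
      stats$input_bytes, stats$archive_bytes, stats$ratio, length(genomes)))
  }
  invisible(stats)
}

#' @rdname compress_genomes
#' @param out_dir Directory the decompressed FASTA files are written to.
#' @param line_width,gzip_out See [decode_collection()].
#' @export
decompress_genomes <- function(archive, out_dir, line_width = 0L,
                               gzip_out = FALSE) {
  decode_collection(archive, out_dir, line_width = line_width,
                    gzip_out = gzip_out)
}
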