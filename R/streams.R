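#' Encode an ordered genome collection into a stream set
#'
#' Runs the full matching pipeline. In default mode the first genome seeds
#' the reference (its contigs are emitted as plain literal runs so the
#' decoder can rebuild both the genome and the reference) and matching
#' starts with the second genome. In max mode every genome, including the
#' first, is matched against the (initially empty) reference and appended
#' through the ordinary unmatched-fraction policy. Output is deterministic
#' for fixed input and parameters.
#'
#' @param genomes List of [genome_file] objects, in collection order.
#' @param params An [encoder_params].
#' @return An object of class `stream_set`: the separated streams (match
#'   offsets and lengths, literal bytes and run lengths, token kinds and
#'   per-contig token counts, headers, file names, per-file contig counts,
#'   per-contig append flags) plus the parameters.
#' @export
encode_collection <- function(genomes, params = encoder_params()) {
  stopifnot(inherits(params, "encoder_params"))
  if (!all(vapply(genomes, inherits, logical(1L), "genome_file")))
    stop_usage("genomes must be a list of genome_file objects")

  enc <- new_encoder(params)
  n_contigs <- sum(vapply(genomes, function(g) length(g$header), integer(1L)))
  token_counts <- numeric(n_contigs)
  appended <- logical(n_contigs)
  kinds <- vector("list", n_contigs)
  offsets <- vector("list", n_contigs)
  lengths <- vector("list", n_contigs)
  lit_lens <- vector("list", n_contigs)
  literals <- vector("list", n_contigs)

  ci <- 0L
  first <- params$mode == "default" && length(genomes) >= 1L
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    if (first && gi == 1L) {
      # first genome: literal runs only; reference seeded wholesale below
      for (s in g$sequence) {
        ci <- ci + 1L
        n <- nchar(s)
        if (n > 0L) {
          token_counts[ci] <- 1
          kinds[[ci]] <- as.raw(0L)
          lit_lens[[ci]] <- n
          literals[[ci]] <- charToRaw(s)
        }
      }
      init_reference(enc, g)
      next
    }
    for (s in g$sequence) {
      ci <- ci + 1L
      e <- cpp_encode_contig(enc$ptr, charToRaw(s))
      token_counts[ci] <- length(e$kinds)
      kinds[[ci]] <- e$kinds
      offsets[[ci]] <- e$offsets
      lengths[[ci]] <- e$lengths
      lit_lens[[ci]] <- e$literal_lens
      literals[[ci]] <- e$literals
      if (unmatched_exceeds_threshold(e$unmatched, nchar(s), params$u)) {
        appended[ci] <- TRUE
        cpp_append_sequence(enc$ptr, charToRaw(s))
      }
    }
  }

  structure(list(
    params = params,
    filenames = vapply(genomes, `[[`, character(1L), "name"),
    contig_counts = vapply(genomes, function(g) length(g$header), integer(1L)),
    headers = unlist(lapply(genomes, `[[`, "header")) %||% character(),
    appended = appended,
    token_counts = token_counts,
    token_kinds = unlist(kinds) %||% raw(),
    match_offsets = unlist(offsets) %||% numeric(),
    match_lengths = unlist(lengths) %||% numeric(),
    literal_lens = unlist(lit_lens) %||% numeric(),
    literal_bytes = unlist(literals) %||% raw()
  ), class = "stream_set")
}

#' @export
print.stream_set <- function(x, ...) {
  cat(sprintf(
    paste0("<stream_set> %d file(s), %d contig(s); %d match(es), ",
           "%d literal run(s), %s literal bytes\n"),
    length(x$filenames), sum(x$contig_counts), length(x$match_offsets),
    length(x$literal_lens),
    format(length(x$literal_bytes), big.mark = ",")))
  invisible(x)
}

#' Total input symbols represented by a stream set
#'
#' @param x A `stream_set`.
#' @return Sum of all token lengths (equals the total sequence bytes of the
#'   encoded collection).
#' @export
stream_set_symbols <- function(x) {
  stopifnot(inherits(x, "stream_set"))
  sum(x$match_lengths) + sum(x$literal_lens)
}
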