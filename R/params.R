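#' Encoder parameters
#'
#' Collects every tunable of the matching engine and the archive back-end.
#'
#' @param k Seed length in symbols (4-32). Matches are found by hashing
#'   k-mers; longer seeds give fewer spurious candidates, shorter seeds find
#'   shorter repeats. Default 32.
#' @param stride Sampling interval, in symbols, at which reference positions
#'   are inserted into the seed index. Default 16.
#' @param skip_margin After emitting a match ending at position `e`,
#'   scanning resumes at `e - skip_margin`, which lets a later, longer match
#'   overlap and absorb the one just found. Default 16.
#' @param u Append divisor: a contig is appended to the reference only when
#'   its unmatched (literal) portion strictly exceeds `1/u` of its length.
#'   Default 192.
#' @param table_bits Log2 of the number of seed-index slots. Default 25.
#' @param ref_limit Reference-buffer capacity in bytes. Once reached, the
#'   buffer is overwritten circularly from position 0. Defaults to `2^32` in
#'   default mode and `2^40` in max mode.
#' @param rc Store reverse complements in the reference alongside the
#'   forward sequence, so reverse-complemented repeats compress as matches.
#'   Default `TRUE`.
#' @param swallow Allow the left extension of a new match to absorb wholly
#'   covered earlier tokens. Default `TRUE`.
#' @param mode `"default"` seeds the reference with the whole first genome
#'   (emitted via the literal stream); `"max"` starts from an empty
#'   reference and runs every genome, including the first, through the
#'   ordinary match-and-append policy, trading speed for ratio.
#' @param level LZMA effort preset (0-9) for the archive back-end. Defaults
#'   to 6 in default mode and 9 in max mode.
#' @return An object of class `encoder_params`.
#' @export
encoder_params <- function(k = 32L, stride = 16L, skip_margin = 16L,
                           u = 192, table_bits = 25L, ref_limit = NULL,
                           rc = TRUE, swallow = TRUE,
                           mode = c("default", "max"), level = NULL) {
  mode <- match.arg(mode)
  if (is.null(ref_limit)) ref_limit <- if (mode == "max") 2^40 else 2^32
  if (is.null(level)) level <- if (mode == "max") 9L else 6L
  p <- list(
    k = as.integer(k), stride = as.integer(stride),
    skip_margin = as.integer(skip_margin), u = as.numeric(u),
    table_bits = as.integer(table_bits), ref_limit = as.numeric(ref_limit),
    rc = isTRUE(rc), swallow = isTRUE(swallow), mode = mode,
    level = as.integer(level)
  )
  if (is.na(p$k) || p$k < 4L || p$k > 32L)
    stop_usage("k must be an integer in [4, 32]")
  if (is.na(p$stride) || p$stride < 1L) stop_usage("stride must be >= 1")
  if (is.na(p$skip_margin) || p$skip_margin < 0L)
    stop_usage("skip_margin must be >= 0")
  if (is.na(p$u) || p$u < 1) stop_usage("u must be >= 1")
  if (is.na(p$table_bits) || p$table_bits < 2L || p$table_bits > 30L)
    stop_usage("table_bits must be in [2, 30]")
  if (is.na(p$ref_limit) || p$ref_limit < 1)
    stop_usage("ref_limit must be >= 1")
  if (is.na(p$level) || p$level < 0L || p$level > 9L)
    stop_usage("level must be in [0, 9]")
  structure(p, class = "encoder_params")
}

#' @export
print.encoder_params <- function(x, ...) {
  cat(sprintf(
    paste0("<encoder_params> mode=%s k=%d stride=%d skip_margin=%d u=%g ",
           "table_bits=%d ref_limit=%.0f rc=%s swallow=%s level=%d\n"),
    x$mode, x$k, x$stride, x$skip_margin, x$u, x$table_bits, x$ref_limit,
    x$rc, x$swallow, x$level))
  invisible(x)
}
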