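#' Create a matching engine
#'
#' Allocates the reference buffer state and the seed index for one
#' compression run. In default mode, seed the reference with the first
#' genome via [init_reference()]; in max mode the reference starts empty
#' and grows through the ordinary append policy.
#'
#' @param params An [encoder_params] object.
#' @return An object of class `ref_encoder`.
#' @export
new_encoder <- function(params = encoder_params()) {
  stopifnot(inherits(params, "encoder_params"))
  structure(list(ptr = cpp_encoder_new(unclass(params)), params = params),
            class = "ref_encoder")
}

#' @export
print.ref_encoder <- function(x, ...) {
  s <- ref_state(x)
  cat(sprintf("<ref_encoder> extent %.0f / limit %.0f bytes%s\n", s$extent,
              s$limit, if (s$wrapped) " (wrapped)" else ""))
  invisible(x)
}

as_seq_raw <- function(x) {
  if (is.raw(x)) x else charToRaw(as.character(x))
}

#' Seed the reference with the first genome (default mode)
#'
#' Writes the concatenation of all contigs of `genome`, followed by its
#' reverse complement (when `rc` is enabled), into the reference buffer and
#' indexes it. The caller is responsible for also emitting the genome via
#' the literal stream so the decoder can replay the same initialization;
#' [encode_collection()] does both.
#'
#' @param enc A [new_encoder()] engine in default mode.
#' @param genome A [genome_file].
#' @return `enc`, invisibly.
#' @export
init_reference <- function(enc, genome) {
  stopifnot(inherits(enc, "ref_encoder"), inherits(genome, "genome_file"))
  total <- sum(nchar(genome$sequence))
  copies <- if (enc$params$rc) 2 else 1
  if (total * copies > enc$params$ref_limit)
    stop_usage(sprintf(
      "first genome (%.0f bp) does not fit the reference limit (%.0f bytes%s)",
      total, enc$params$ref_limit,
      if (copies == 2) ", half of which holds the reverse complement" else ""))
  cpp_append_sequence(enc$ptr, charToRaw(paste(genome$sequence, collapse = "")))
  invisible(enc)
}

#' Reference-buffer state
#'
#' @param enc A `ref_encoder`.
#' @return A list with `end` (bytes written before the first wrap),
#'   `extent` (currently valid bytes), `limit`, `wrapped` and `write_pos`.
#' @export
ref_state <- function(enc) {
  stopifnot(inherits(enc, "ref_encoder"))
  cpp_ref_info(enc$ptr)
}

#' Current reference content
#'
#' @param enc A `ref_encoder`.
#' @param as Return type: `"character"` (default) or `"raw"`.
#' @return The valid extent of the reference buffer.
#' @export
ref_bytes <- function(enc, as = c("character", "raw")) {
  stopifnot(inherits(enc, "ref_encoder"))
  r <- cpp_ref_bytes(enc$ptr)
  if (match.arg(as) == "raw") r else rawToChar(r)
}

#' Index a reference range
#'
#' Samples positions `from, from + stride, ...` (0-based) whose k-mer lies
#' entirely inside `[from, to)` and stores valid seeds in the index; a hash
#' collision overwrites the previous occupant. Invalid seeds (containing
#' non-ACGT symbols) are skipped. Called automatically whenever reference
#' content is appended; exposed for inspection and testing.
#'
#' @param enc A `ref_encoder`.
#' @param from,to 0-based half-open range within the valid extent.
#' @return `enc`, invisibly.
#' @export
index_range <- function(enc, from, to) {
  stopifnot(inherits(enc, "ref_encoder"))
  cpp_index_range(enc$ptr, as.numeric(from), as.numeric(to))
  invisible(enc)
}

#' Look up a match candidate for one contig position
#'
#' Hashes the k-mer at `pos` (0-based), looks it up in the seed index, and
#' verifies the k stored symbols against the current reference content.
#' Verification makes hash collisions and entries gone stale after a
#' circular-buffer wrap harmless: they simply fail here.
#'
#' @param enc A `ref_encoder`.
#' @param contig Character string or raw vector.
#' @param pos 0-based position with `pos + k <= nchar(contig)`.
#' @return The 0-based reference offset of a verified candidate, or `NULL`.
#' @export
find_candidate <- function(enc, contig, pos) {
  stopifnot(inherits(enc, "ref_encoder"))
  r <- cpp_find_candidate(enc$ptr, as_seq_raw(contig), as.numeric(pos))
  if (r < 0) NULL else r
}

#' Factor a contig into matches and literal runs
#'
#' Scans the contig left to right. Positions without a verified seed hit
#' contribute literal symbols. A verified hit is extended maximally in both
#' directions (never across the contig ends nor past the valid reference
#' extent). The left extension may absorb ("swallow") wholly covered
#' previous tokens — a pending literal run is trimmed symbol by symbol,
#' committed tokens are only removed whole, and a partially overlapped
#' token truncates the extension at its boundary. After a match ending at
#' `e`, scanning resumes at `max(e - skip_margin, s + 1)` where `s` is the
#' emitted token's start, so overlapping longer matches can be found while
#' progress is guaranteed. Because truncation can cut into a seed, an
#' emitted match may occasionally be shorter than `k`.
#'
#' The reference buffer is not modified; use [append_contig()] afterwards
#' if the unmatched fraction warrants it (see
#' [unmatched_exceeds_threshold()]).
#'
#' @param enc A `ref_encoder`.
#' @param contig Character string or raw vector.
#' @return A `contig_encoding`: list with `kinds` (raw, one byte per token,
#'   0 = literal run, 1 = match), `offsets` and `lengths` (matches, in token
#'   order), `literal_lens` and `literals` (literal runs), and `unmatched`
#'   (total literal symbols).
#' @export
encode_contig <- function(enc, contig) {
  stopifnot(inherits(enc, "ref_encoder"))
  res <- cpp_encode_contig(enc$ptr, as_seq_raw(contig))
  structure(res, class = "contig_encoding")
}

#' @export
print.contig_encoding <- function(x, ...) {
  cat(sprintf("<contig_encoding> %d token(s): %d match(es), %d literal run(s) (%.0f unmatched symbols)\n",
              length(x$kinds), sum(as.integer(x$kinds) == 1L),
              sum(as.integer(x$kinds) == 0L), x$unmatched))
  invisible(x)
}

#' Token table of a contig encoding
#'
#' @param x A `contig_encoding`.
#' @return A data.frame with one row per token in emission order: `kind`
#'   ("match"/"literal"), `length`, and `ref_offset` (NA for literals).
#' @export
encoding_tokens <- function(x) {
  stopifnot(inherits(x, "contig_encoding"))
  kind <- ifelse(as.integer(x$kinds) == 1L, "match", "literal")
  len <- numeric(length(kind))
  off <- rep(NA_real_, length(kind))
  len[kind == "match"] <- x$lengths
  len[kind == "literal"] <- x$literal_lens
  off[kind == "match"] <- x$offsets
  data.frame(kind = kind, length = len, ref_offset = off)
}

#' Replay a contig encoding against a reference snapshot
#'
#' Reconstructs the contig from its tokens and the reference content the
#' encoder saw. Used by tests to check factorization exactness.
#'
#' @param encoding A `contig_encoding`.
#' @param ref Reference bytes (character or raw) at encode time.
#' @return The reconstructed contig as a character string.
#' @export
replay_encoding <- function(encoding, ref) {
  stopifnot(inherits(encoding, "contig_encoding"))
  refr <- as_seq_raw(ref)
  out <- raw(0)
  im <- 0L; il <- 0L; lit_pos <- 0L
  parts <- vector("list", length(encoding$kinds))
  for (i in seq_along(encoding$kinds)) {
    if (as.integer(encoding$kinds[[i]]) == 1L) {
      im <- im + 1L
      off <- encoding$offsets[[im]]; len <- encoding$lengths[[im]]
      if (off + len > length(refr)) stop_corrupt("match beyond reference extent")
      parts[[i]] <- refr[seq.int(off + 1L, length.out = len)]
    } else {
      il <- il + 1L
      len <- encoding$literal_lens[[il]]
      parts[[i]] <- encoding$literals[seq.int(lit_pos + 1L, length.out = len)]
      lit_pos <- lit_pos + len
    }
  }
  rawToChar(unlist(parts) %||% raw(0))
}

#' Does a contig carry enough novel sequence to extend the reference?
#'
#' The strict rule: append iff `unmatched * u > contig_len`, i.e. the
#' literal portion exceeds 1/u of the contig length. Contigs below the
#' threshold are considered redundant with the existing reference and do
#' not extend it.
#'
#' @param unmatched Total literal symbols in the contig's encoding.
#' @param contig_len Contig length in symbols.
#' @param u Append divisor (default 192).
#' @return `TRUE` or `FALSE`.
#' @examples
#' unmatched_exceeds_threshold(1, 192)  # FALSE: 1 * 192 == 192, not >
#' unmatched_exceeds_threshold(2, 192)  # TRUE
#' @export
unmatched_exceeds_threshold <- function(unmatched, contig_len, u = 192) {
  unmatched * u > contig_len
}

#' Append a contig (and its reverse complement) to the reference
#'
#' Writes the contig followed by its reverse complement (when `rc` is
#' enabled) at the append cursor. If the write would pass the capacity
#' limit, the buffer wraps and is overwritten from position 0; the valid
#' extent never exceeds the limit. Newly written ranges are indexed.
#'
#' @param enc A `ref_encoder`.
#' @param contig Character string or raw vector.
#' @return `enc`, invisibly.
#' @export
append_contig <- function(enc, contig) {
  stopifnot(inherits(enc, "ref_encoder"))
  cpp_append_sequence(enc$ptr, as_seq_raw(contig))
  invisible(enc)
}

#' Look up the reference position stored in one index slot
#'
#' Instrumentation for tests: returns the 0-based reference position held
#' by `slot`, or `NULL` when the slot is empty.
#'
#' @param enc A `ref_encoder`.
#' @param slot Slot index in `[0, 2^table_bits)`.
#' @return Numeric position or `NULL`.
#' @export
index_slot <- function(enc, slot) {
  stopifnot(inherits(enc, "ref_encoder"))
  r <- cpp_index_slot(enc$ptr, as.numeric(slot))
  if (r < 0) NULL else r
}
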