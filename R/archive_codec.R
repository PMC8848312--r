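# Container layout (see FORMAT.md): magic, version, LEB128 params block,
# stream directory (id, backend, raw size, compressed size), payloads.

ARCHIVE_MAGIC <- charToRaw("RFZA")
ARCHIVE_VERSION <- 1L

STREAM_IDS <- c(
  filenames = 1L, contig_counts = 2L, headers = 3L, appended = 4L,
  token_counts = 5L, token_kinds = 6L, match_offsets = 7L,
  match_lengths = 8L, literal_lens = 9L, literal_bytes = 10L
)

#' LEB128 varint encoding
#'
#' Unsigned little-endian base-128: 7 value bits per byte, high bit set on
#' every byte but the last. `leb128_encode(300)` is bytes `0xAC 0x02`.
#'
#' @param x Numeric vector of non-negative integers (< 2^53).
#' @return Raw vector of the concatenated varints.
#' @export
leb128_encode <- function(x) cpp_leb128_encode(as.numeric(x))

#' @rdname leb128_encode
#' @param bytes Raw vector holding exactly `n` varints.
#' @param n Number of values to decode.
#' @export
leb128_decode <- function(bytes, n) cpp_leb128_decode(bytes, as.numeric(n))

pack_flag_bits <- function(x) {
  # bit-packed little-endian: first flag in the least significant bit
  if (!length(x)) return(raw())
  pad <- (8L - length(x) %% 8L) %% 8L
  packBits(c(as.logical(x), rep(FALSE, pad)), type = "raw")
}

unpack_flag_bits <- function(bytes, n) {
  if (n == 0) return(logical())
  bits <- as.logical(rawToBits(bytes))
  if (length(bits) < n || length(bits) - n >= 8L)
    stop_corrupt("flag stream has the wrong size")
  bits[seq_len(n)]
}

join_nul <- function(x) {
  if (!length(x)) return(raw())
  unlist(lapply(x, function(s) c(charToRaw(s), as.raw(0L))))
}

split_nul <- function(bytes) {
  if (!length(bytes)) return(character())
  if (bytes[[length(bytes)]] != as.raw(0L))
    stop_corrupt("text stream is not NUL-terminated")
  ends <- which(bytes == as.raw(0L))
  starts <- c(1L, head(ends, -1L) + 1L)
  vapply(seq_along(ends), function(i) {
    if (starts[i] > ends[i] - 1L) "" else rawToChar(bytes[starts[i]:(ends[i] - 1L)])
  }, character(1L))
}

#' Serialize a stream set into per-stream byte strings
#'
#' Integers are unsigned LEB128 varints in stream order, flags are
#' bit-packed little-endian, text streams are NUL-separated, literal bytes
#' pass through verbatim. Bijective with [deserialize_streams()].
#'
#' @param ss A `stream_set`.
#' @return Named list of raw vectors, one per stream.
#' @export
serialize_streams <- function(ss) {
  stopifnot(inherits(ss, "stream_set"))
  list(
    filenames = join_nul(ss$filenames),
    contig_counts = leb128_encode(ss$contig_counts),
    headers = join_nul(ss$headers),
    appended = pack_flag_bits(ss$appended),
    token_counts = leb128_encode(ss$token_counts),
    token_kinds = pack_flag_bits(as.integer(ss$token_kinds)),
    match_offsets = leb128_encode(ss$match_offsets),
    match_lengths = leb128_encode(ss$match_lengths),
    literal_lens = leb128_encode(ss$literal_lens),
    literal_bytes = ss$literal_bytes
  )
}

#' @rdname serialize_streams
#' @param streams Named list of raw vectors as produced by
#'   [serialize_streams()].
#' @param params The [encoder_params] the streams were produced with.
#' @export
deserialize_streams <- function(streams, params) {
  filenames <- split_nul(streams$filenames)
  n_files <- length(filenames)
  contig_counts <- as.integer(leb128_decode(streams$contig_counts, n_files))
  n_contigs <- sum(contig_counts)
  headers <- split_nul(streams$headers)
  if (length(headers) != n_contigs)
    stop_corrupt("header count does not match contig structure")
  appended <- unpack_flag_bits(streams$appended, n_contigs)
  token_counts <- leb128_decode(streams$token_counts, n_contigs)
  n_tokens <- sum(token_counts)
  kinds <- as.raw(unpack_flag_bits(streams$token_kinds, n_tokens))
  n_match <- sum(kinds == as.raw(1L))
  match_offsets <- leb128_decode(streams$match_offsets, n_match)
  match_lengths <- leb128_decode(streams$match_lengths, n_match)
  literal_lens <- leb128_decode(streams$literal_lens, n_tokens - n_match)
  if (sum(literal_lens) != length(streams$literal_bytes))
    stop_corrupt("literal stream size does not match run lengths")
  structure(list(
    params = params, filenames = filenames, contig_counts = contig_counts,
    headers = headers, appended = appended, token_counts = token_counts,
    token_kinds = kinds, match_offsets = match_offsets,
    match_lengths = match_lengths, literal_lens = literal_lens,
    literal_bytes = streams$literal_bytes
  ), class = "stream_set")
}

#' General-purpose back-end codec (LZMA)
#'
#' Whole-buffer LZMA in the xz container via liblzma. `level` selects the
#' effort preset; default mode archives use 6, max mode 9. Lossless:
#' `backend_decompress(backend_compress(x, l), length(x))` is `x`.
#'
#' @param raw Raw vector to compress.
#' @param level Preset in 0-9.
#' @return Raw vector.
#' @export
backend_compress <- function(raw, level = 6L) {
  cpp_xz_compress(raw, as.integer(level))
}

#' @rdname backend_compress
#' @param compressed Raw vector produced by [backend_compress()].
#' @param raw_size Exact size of the original data.
#' @export
backend_decompress <- function(compressed, raw_size) {
  tryCatch(cpp_xz_decompress(compressed, as.numeric(raw_size)),
           error = function(e) stop_corrupt(conditionMessage(e)))
}

params_to_block <- function(p) {
  flags <- p$rc * 1L + p$swallow * 2L + (p$mode == "max") * 4L
  body <- leb128_encode(c(p$k, p$stride, p$skip_margin, p$u, p$table_bits,
                          p$ref_limit, flags, p$level))
  c(leb128_encode(length(body)), body)
}

read_varint <- function(bytes, pos) {
  v <- 0; mult <- 1
  repeat {
    if (pos > length(bytes)) stop_corrupt("archive truncated",
                                          "refzip_truncated")
    b <- as.integer(bytes[[pos]]); pos <- pos + 1L
    v <- v + (b %% 128L) * mult
    if (b < 128L) break
    mult <- mult * 128
  }
  list(value = v, pos = pos)
}

params_from_block <- function(bytes, pos) {
  len <- read_varint(bytes, pos)
  if (len$pos + len$value - 1L > length(bytes))
    stop_corrupt("archive truncated", "refzip_truncated")
  vals <- leb128_decode(bytes[seq.int(len$pos, length.out = len$value)], 8)
  flags <- vals[[7]]
  p <- encoder_params(
    k = vals[[1]], stride = vals[[2]], skip_margin = vals[[3]], u = vals[[4]],
    table_bits = vals[[5]], ref_limit = vals[[6]],
    rc = bitwAnd(flags, 1) > 0, swallow = bitwAnd(flags, 2) > 0,
    mode = if (bitwAnd(flags, 4) > 0) "max" else "default", level = vals[[8]]
  )
  list(params = p, pos = len$pos + len$value)
}

#' Write a stream set to an archive file
#'
#' Serializes the streams, compresses each with the LZMA back-end (streams
#' that do not shrink are stored raw), and writes the self-describing
#' container: the encoder parameters are echoed in the header so decoding
#' needs no external configuration.
#'
#' @param ss A `stream_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_archive <- function(ss, path) {
  stopifnot(inherits(ss, "stream_set"))
  streams <- serialize_streams(ss)
  level <- ss$params$level
  directory <- raw()
  payload <- vector("list", length(streams))
  for (i in seq_along(streams)) {
    rawv <- streams[[i]]
    comp <- backend_compress(rawv, level)
    backend <- 1L
    if (length(comp) >= length(rawv)) {  # incompressible: store raw
      comp <- rawv
      backend <- 0L
    }
    payload[[i]] <- comp
    directory <- c(directory,
                   as.raw(STREAM_IDS[[names(streams)[i]]]), as.raw(backend),
                   leb128_encode(c(length(rawv), length(comp))))
  }
  out <- c(ARCHIVE_MAGIC, as.raw(ARCHIVE_VERSION), params_to_block(ss$params),
           leb128_encode(length(streams)), directory,
           unlist(payload) %||% raw())
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_io(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' @rdname write_archive
#' @return For `read_archive`, the `stream_set` stored in the archive, with
#'   the parameter echo attached.
#' @export
read_archive <- function(path) {
  if (!file.exists(path))
    stop_io(sprintf("cannot read '%s': no such file", path))
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 5L || !identical(bytes[1:4], ARCHIVE_MAGIC))
    stop_corrupt(sprintf("'%s' is not an archive (bad magic)", path),
                 "refzip_bad_magic")
  if (as.integer(bytes[[5L]]) != ARCHIVE_VERSION)
    stop_corrupt(sprintf("unsupported archive version %d",
                         as.integer(bytes[[5L]])), "refzip_bad_version")
  pb <- params_from_block(bytes, 6L)
  pos <- pb$pos
  ns <- read_varint(bytes, pos)
  pos <- ns$pos
  if (ns$value != length(STREAM_IDS))
    stop_corrupt("unexpected stream count")
  dir_ids <- integer(ns$value)
  dir_backend <- integer(ns$value)
  dir_raw <- numeric(ns$value)
  dir_comp <- numeric(ns$value)
  for (i in seq_len(ns$value)) {
    if (pos + 1L > length(bytes)) stop_corrupt("archive truncated",
                                               "refzip_truncated")
    dir_ids[i] <- as.integer(bytes[[pos]])
    dir_backend[i] <- as.integer(bytes[[pos + 1L]])
    pos <- pos + 2L
    v <- read_varint(bytes, pos); dir_raw[i] <- v$value; pos <- v$pos
    v <- read_varint(bytes, pos); dir_comp[i] <- v$value; pos <- v$pos
  }
  if (!identical(dir_ids, unname(STREAM_IDS)))
    stop_corrupt("unexpected stream directory")
  if (length(bytes) - pos + 1L != sum(dir_comp))
    stop_corrupt("archive truncated: payload size mismatch",
                 "refzip_truncated")
  streams <- vector("list", ns$value)
  names(streams) <- names(STREAM_IDS)
  for (i in seq_len(ns$value)) {
    comp <- if (dir_comp[i] > 0) bytes[seq.int(pos, length.out = dir_comp[i])] else raw()
    pos <- pos + dir_comp[i]
    streams[[i]] <- switch(dir_backend[i] + 1L,
      comp,                                   # 0: stored raw
      backend_decompress(comp, dir_raw[i]),   # 1: LZMA
      stop_corrupt(sprintf("unknown back-end id %d", dir_backend[i]))
    )
    if (length(streams[[i]]) != dir_raw[i])
      stop_corrupt("stream size mismatch after decompression")
  }
  deserialize_streams(streams, pb$params)
}
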