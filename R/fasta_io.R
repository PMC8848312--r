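#' In-memory representation of one FASTA file
#'
#' A `genome_file` holds the ordered contigs of a single FASTA file: the
#' header lines (text after `>`, verbatim, without the end-of-line bytes)
#' and the sequences with all end-of-line bytes removed.
#'
#' @param name Relative path the file is (or will be) stored under.
#' @param header Character vector of header lines, one per contig.
#' @param sequence Character vector of sequences, parallel to `header`.
#' @return An object of class `genome_file`.
#' @export
genome_file <- function(name, header = character(), sequence = character()) {
  if (!is.character(name) || length(name) != 1L)
    stop_usage("name must be a single string")
  header <- as.character(header)
  sequence <- as.character(sequence)
  if (length(header) != length(sequence))
    stop_usage("header and sequence must have the same length")
  if (any(grepl("[\r\n]", header)))
    stop_usage("headers must not contain end-of-line bytes")
  if (any(grepl("[\r\n>]", sequence)))
    stop_usage("sequences must not contain end-of-line or '>' bytes")
  structure(list(name = name, header = header, sequence = sequence),
            class = "genome_file")
}

#' @export
print.genome_file <- function(x, ...) {
  cat(sprintf("<genome_file> %s: %d contig(s), %s bp\n", x$name,
              length(x$header),
              format(sum(nchar(x$sequence)), big.mark = ",")))
  invisible(x)
}

#' @export
format.genome_file <- function(x, ...) {
  sprintf("genome_file(%s, %d contigs)", x$name, length(x$header))
}

# Two genome_files are equal iff names, headers and sequences all match.
#' @method all.equal genome_file
#' @export
all.equal.genome_file <- function(target, current, ...) {
  if (!inherits(current, "genome_file")) return("not a genome_file")
  msg <- character()
  if (target$name != current$name) msg <- c(msg, "names differ")
  if (!identical(target$header, current$header)) msg <- c(msg, "headers differ")
  if (!identical(target$sequence, current$sequence))
    msg <- c(msg, "sequences differ")
  if (length(msg)) msg else TRUE
}

#' Read a FASTA file (plain or gzip)
#'
#' Every line starting with `>` opens a new contig. End-of-line bytes (LF or
#' CRLF) inside sequence blocks are removed, sequences are uppercased, blank
#' lines are ignored, and gzip input (by any name) is decompressed
#' transparently. Headers are preserved verbatim. The original line layout
#' of the sequences is deliberately not recorded: two files differing only
#' in sequence line breaks parse to equal values.
#'
#' @param path File to read.
#' @param name Name to store in the result; defaults to `path`.
#' @return A [genome_file].
#' @export
read_fasta <- function(path, name = path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s': no such file", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- tryCatch(readLines(con, warn = FALSE), error = function(e) {
    stop_format(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  })
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(genome_file(name))
  if (!startsWith(lines[[1L]], ">"))
    stop_format(sprintf("'%s' is not FASTA: first non-blank byte is not '>'", path))
  is_hdr <- startsWith(lines, ">")
  headers <- substring(lines[is_hdr], 2L)
  grp <- cumsum(is_hdr)
  sequences <- character(length(headers))
  if (any(!is_hdr)) {
    joined <- vapply(
      split(lines[!is_hdr], factor(grp[!is_hdr], levels = seq_along(headers))),
      paste, character(1L), collapse = ""
    )
    sequences <- unname(joined)
  }
  genome_file(name, headers, toupper(sequences))
}

#' Write a FASTA file (plain or gzip)
#'
#' Emits `>` + header, then the sequence either on a single line
#' (`line_width = 0`, the default) or broken every `line_width` symbols.
#' Lines always end in LF. Paths ending in `.gz` are written
#' gzip-compressed. Reading the result back with [read_fasta()] reproduces
#' the input object for any width.
#'
#' @param g A [genome_file].
#' @param path Output path; overwritten if it exists.
#' @param line_width Symbols per sequence line; 0 means no wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, line_width = 0L) {
  stopifnot(inherits(g, "genome_file"))
  line_width <- as.integer(line_width)
  if (is.na(line_width) || line_width < 0L)
    stop_usage("line_width must be 0 (no wrapping) or a positive integer")
  lines <- vector("list", length(g$header))
  for (i in seq_along(g$header)) {
    s <- g$sequence[[i]]
    body <- if (line_width == 0L || nchar(s) <= line_width) {
      s
    } else {
      starts <- seq(1L, nchar(s), by = line_width)
      substring(s, starts, pmin(starts + line_width - 1L, nchar(s)))
    }
    lines[[i]] <- c(paste0(">", g$header[[i]]), body)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(unlist(lines, use.names = FALSE) %||% character(), con, sep = "\n")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an ordered collection of FASTA files
#'
#' @param paths Character vector of FASTA paths (plain or `.gz`), in the
#'   order they should be compressed. The stored names are the paths as
#'   given (normally relative).
#' @param base_dir Optional directory the paths are resolved against for
#'   reading; names keep the relative form.
#' @return A list of [genome_file] objects, in input order.
#' @export
read_collection <- function(paths, base_dir = NULL) {
  lapply(paths, function(p) {
    full <- if (is.null(base_dir)) p else file.path(base_dir, p)
    read_fasta(full, name = p)
  })
}

#' Read a collection list file
#'
#' One path per line, UTF-8; blank lines and lines starting with `#` are
#' ignored. Order is preserved.
#'
#' @param path List file.
#' @return Character vector of paths.
#' @export
parse_list_file <- function(path) {
  if (!file.exists(path))
    stop_io(sprintf("cannot read list file '%s': no such file", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
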