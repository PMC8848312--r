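#' Reverse complement of a nucleotide sequence
#'
#' Reverses the sequence and complements every symbol. The complement table
#' covers the full IUPAC alphabet (A/T, C/G, R/Y, K/M, B/V, D/H; S, W and N
#' are self-complementary) and maps any other byte to itself, so the
#' function is a total involution on arbitrary byte strings:
#' `reverse_complement(reverse_complement(x)) == x` always.
#'
#' @param x A character string or a raw vector of sequence bytes.
#' @return An object of the same type as `x`.
#' @examples
#' reverse_complement("AAC")    # "GTT"
#' reverse_complement("ACGTN")  # "NACGT"
#' @export
reverse_complement <- function(x) {
  if (is.raw(x)) return(cpp_reverse_complement(x))
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_usage("x must be a single character string or a raw vector")
  rawToChar(cpp_reverse_complement(charToRaw(x)))
}

#' Is a k-mer usable as a match seed?
#'
#' Seeds are hashed into the reference index; only k-mers consisting purely
#' of A, C, G, T qualify. Anything containing N or another IUPAC code is
#' skipped by the indexer and can never start a match (it can still be
#' covered by match extension, which compares raw bytes).
#'
#' @param kmer A character string or raw vector of exactly `k` symbols.
#' @param k Expected seed length; defaults to the length of `kmer`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_valid_seed("ACGT")  # TRUE
#' is_valid_seed("ACNT")  # FALSE
#' @export
is_valid_seed <- function(kmer, k = NULL) {
  r <- if (is.raw(kmer)) kmer else charToRaw(kmer)
  if (!is.null(k) && length(r) != k)
    stop_usage(sprintf("seed has %d symbols, expected k = %d", length(r), k))
  cpp_is_valid_seed(r)
}

#' Hash a seed k-mer to a table slot
#'
#' Packs the k-mer 2 bits per symbol and maps it to a slot in a table of
#' `2^table_bits` entries. Seeds short enough that their packing fits the
#' table (`2 * k <= table_bits`) are used directly, which makes the hash
#' perfect (collision-free) for them; longer seeds go through a 64-bit
#' mix-and-shift finalizer. Deterministic across platforms and sessions.
#'
#' @param kmer Character vector of k-mers (all the same length, symbols in
#'   A/C/G/T only).
#' @param table_bits Log2 of the table size.
#' @return Numeric vector of slot indices in `[0, 2^table_bits)`.
#' @export
hash_kmer <- function(kmer, table_bits) {
  if (!is.character(kmer)) stop_usage("kmer must be a character vector")
  tryCatch(cpp_hash_kmers(kmer, as.integer(table_bits)),
           error = function(e) stop_usage(conditionMessage(e)))
}
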