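# Brute-force greedy LZ oracle, independent of the C++ engine: at each
# target position, enumerate every reference occurrence of the k-mer and
# extend each character by character; take the longest match (>= k) or emit
# a literal and advance one symbol. Returns covered symbol count and the
# matches as (target_pos, ref_pos, len), all 0-based.
greedy_lz_oracle <- function(ref, contig, k) {
  n <- nchar(contig)
  rlen <- nchar(ref)
  matches <- list()
  covered <- 0
  if (rlen >= k) {
    ref_kmers <- substring(ref, 1:(rlen - k + 1), k:rlen)
    i <- 1
    while (i + k - 1 <= n) {
      cand <- which(ref_kmers == substr(contig, i, i + k - 1))
      best_len <- 0
      best_j <- NA
      for (j in cand) {
        l <- k
        while (i + l <= n && j + l <= rlen &&
               substr(contig, i + l, i + l) == substr(ref, j + l, j + l)) {
          l <- l + 1
        }
        if (l > best_len) {
          best_len <- l
          best_j <- j
        }
      }
      if (best_len >= k) {
        matches[[length(matches) + 1]] <- c(i - 1, best_j - 1, best_len)
        covered <- covered + best_len
        i <- i + best_len
      } else {
        i <- i + 1
      }
    }
  }
  list(covered = covered, matches = matches)
}
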