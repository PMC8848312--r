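#include "refzip.h"

using namespace Rcpp;

namespace refzip {

const uint8_t* complement_table() {
  static const std::vector<uint8_t> table = [] {
    std::vector<uint8_t> t(256);
    for (int i = 0; i < 256; ++i) t[i] = (uint8_t)i;
    auto pair = [&](char a, char b) {
      t[(uint8_t)a] = (uint8_t)b;
      t[(uint8_t)b] = (uint8_t)a;
    };
    // Watson-Crick pairs plus the IUPAC ambiguity codes; S, W and N are
    // their own complements. Lowercase handled for completeness even though
    // sequences are uppercased on read.
    pair('A', 'T'); pair('C', 'G');
    pair('R', 'Y'); pair('K', 'M');
    pair('B', 'V'); pair('D', 'H');
    pair('a', 't'); pair('c', 'g');
    pair('r', 'y'); pair('k', 'm');
    pair('b', 'v'); pair('d', 'h');
    return t;
  }();
  return table.data();
}

}  // namespace refzip

// [[Rcpp::export]]
RawVector cpp_reverse_complement(RawVector s) {
  R_xlen_t n = s.size();
  RawVector out(n);
  refzip::reverse_complement(RAW(s), RAW(out), (long long)n);
  return out;
}

// [[Rcpp::export]]
bool cpp_is_valid_seed(RawVector kmer) {
  uint64_t packed;
  if (kmer.size() == 0 || kmer.size() > 32) return false;
  return refzip::pack_kmer(RAW(kmer), (int)kmer.size(), packed);
}

// [[Rcpp::export]]
NumericVector cpp_hash_kmers(CharacterVector kmers, int table_bits) {
  if (table_bits < 1 || table_bits > 62)
    stop("table_bits must be in [1, 62]");
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  uint64_t mask = (((uint64_t)1 << table_bits) - 1);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    int k = (int)LENGTH(STRING_ELT(kmers, i));
    if (k < 1 || k > 32) stop("seed length must be in [1, 32]");
    uint64_t packed;
    if (!refzip::pack_kmer((const uint8_t*)s, k, packed))
      stop("invalid seed: symbols outside {A,C,G,T}");
    out[i] = (double)(refzip::slot_for(packed, k, table_bits) & mask);
  }
  return out;
}
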