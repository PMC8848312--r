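#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <utility>
#include <vector>

namespace refzip {

// Full IUPAC complement table; unknown bytes map to themselves so that
// complementing is a total involution on arbitrary byte strings.
const uint8_t* complement_table();

inline void reverse_complement(const uint8_t* src, uint8_t* dst, long long n) {
  const uint8_t* t = complement_table();
  for (long long i = 0; i < n; ++i) dst[i] = t[src[n - 1 - i]];
}

inline int base2bits(uint8_t c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

// 2 bits per symbol; returns false if any symbol is outside {A,C,G,T}.
inline bool pack_kmer(const uint8_t* p, int k, uint64_t& packed) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(p[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  packed = v;
  return true;
}

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Seeds short enough to address the table directly use their 2-bit packing
// as a perfect hash (collision-free); longer seeds are mixed and take the
// high bits of the 64-bit finalizer.
inline uint64_t slot_for(uint64_t packed, int k, int table_bits) {
  if (2 * k <= table_bits) return packed;
  return splitmix64(packed) >> (64 - table_bits);
}

struct EncParams {
  int k;
  int stride;
  int m;  // skip margin
  long long u;
  int table_bits;
  long long ref_limit;
  bool rc_enabled;
  bool swallow;
  int mode;  // 0 = default, 1 = max
  int level;
};

EncParams params_from_list(const Rcpp::List& p);

// The reference buffer: append-only until it reaches its capacity, then a
// circular buffer overwritten from position 0.
struct RefBuf {
  std::vector<uint8_t> buf;
  long long end = 0;     // bytes written before the first wrap
  long long limit = 0;   // capacity
  bool wrapped = false;
  long long wpos = 0;    // next write position once wrapped

  long long extent() const { return wrapped ? limit : end; }

  // Append n bytes circularly; every physically written range is pushed onto
  // segs in write order (later writes may overwrite earlier ones).
  void append(const uint8_t* d, long long n,
              std::vector<std::pair<long long, long long>>* segs);
};

struct Encoder {
  EncParams p;
  RefBuf ref;
  std::vector<long long> index;  // slot -> reference position, -1 = empty

  explicit Encoder(const EncParams& p_) : p(p_) {
    ref.limit = p.ref_limit;
    index.assign((size_t)1 << p.table_bits, -1);
  }

  void index_range(long long from, long long to);
  long long find_candidate(const uint8_t* contig, long long clen,
                           long long pos) const;
  // Write seq (plus its reverse complement when enabled) and index the
  // newly written ranges.
  void append_sequence(const uint8_t* d, long long n);
};

}  // namespace refzip
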