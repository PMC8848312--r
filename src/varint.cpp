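#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Unsigned LEB128: 7 value bits per byte, least significant group first,
// high bit set on every byte except the last.

// [[Rcpp::export]]
RawVector cpp_leb128_encode(NumericVector x) {
  std::vector<uint8_t> out;
  out.reserve(x.size() * 2);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    if (ISNAN(v) || v < 0 || v > 9007199254740992.0)
      stop("LEB128 values must be non-negative integers < 2^53");
    uint64_t u = (uint64_t)v;
    do {
      uint8_t b = u & 0x7f;
      u >>= 7;
      if (u) b |= 0x80;
      out.push_back(b);
    } while (u);
  }
  return RawVector(out.begin(), out.end());
}

// Decode exactly n values; the stream must be consumed exactly.
// [[Rcpp::export]]
NumericVector cpp_leb128_decode(RawVector bytes, double n) {
  R_xlen_t count = (R_xlen_t)n;
  NumericVector out(count);
  R_xlen_t pos = 0;
  for (R_xlen_t i = 0; i < count; ++i) {
    uint64_t v = 0;
    int shift = 0;
    while (true) {
      if (pos >= bytes.size()) stop("varint stream underrun");
      uint8_t b = bytes[pos++];
      if (shift >= 63 && (b >> 1) != 0) stop("varint value overflow");
      v |= (uint64_t)(b & 0x7f) << shift;
      if (!(b & 0x80)) break;
      shift += 7;
    }
    out[i] = (double)v;
  }
  if (pos != bytes.size()) stop("varint stream has trailing bytes");
  return out;
}
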