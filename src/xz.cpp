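#include <Rcpp.h>
#include <lzma.h>

using namespace Rcpp;

// Whole-buffer LZMA (xz container) via liblzma; preset 0..9 selects effort.

// [[Rcpp::export]]
RawVector cpp_xz_compress(RawVector data, int preset) {
  if (preset < 0 || preset > 9) stop("xz preset must be in [0, 9]");
  size_t bound = lzma_stream_buffer_bound(data.size());
  std::vector<uint8_t> out(bound);
  size_t out_pos = 0;
  lzma_ret r = lzma_easy_buffer_encode(
      (uint32_t)preset, LZMA_CHECK_CRC32, NULL, RAW(data), data.size(),
      out.data(), &out_pos, bound);
  if (r != LZMA_OK) stop("xz compression failed (liblzma error %d)", (int)r);
  return RawVector(out.begin(), out.begin() + out_pos);
}

// [[Rcpp::export]]
RawVector cpp_xz_decompress(RawVector data, double raw_size) {
  if (raw_size < 0 || raw_size > 9007199254740992.0)
    stop("invalid raw size");
  RawVector out((R_xlen_t)raw_size);
  size_t in_pos = 0, out_pos = 0;
  uint64_t memlimit = UINT64_MAX;
  lzma_ret r = lzma_stream_buffer_decode(
      &memlimit, 0, NULL, RAW(data), &in_pos, data.size(), RAW(out),
      &out_pos, (size_t)raw_size);
  if (r != LZMA_OK || out_pos != (size_t)raw_size || in_pos != (size_t)data.size())
    stop("xz payload is corrupt or truncated");
  return out;
}
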