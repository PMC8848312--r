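#include "refzip.h"

using namespace Rcpp;

// Replay the token streams of a whole collection, rebuilding the reference
// buffer with the same append/wrap policy the encoder used. The decoder
// never consults a seed index: correctness depends only on the streams and
// the per-contig append flags.
//
// contig_counts: contigs per file (in file order)
// token_counts:  tokens per contig (in global contig order)
// kinds:         one byte per token, 0 = literal run, 1 = match
// capture_ref:   also return a snapshot of the reference after each contig
//                (instrumentation for lockstep tests; expensive)
// [[Rcpp::export]]
List cpp_decode_streams(List params, IntegerVector contig_counts,
                        NumericVector token_counts, RawVector kinds,
                        NumericVector offsets, NumericVector lengths,
                        NumericVector literal_lens, RawVector literals,
                        LogicalVector appended, bool capture_ref) {
  refzip::EncParams p = refzip::params_from_list(params);
  refzip::RefBuf ref;
  ref.limit = p.ref_limit;

  long long n_contigs = 0;
  for (R_xlen_t i = 0; i < contig_counts.size(); ++i)
    n_contigs += contig_counts[i];
  if ((R_xlen_t)n_contigs != token_counts.size() ||
      (R_xlen_t)n_contigs != appended.size())
    stop("archive corruption: inconsistent contig structure counts");

  long long tok_cur = 0, match_cur = 0, lit_run_cur = 0, lit_byte_cur = 0;
  List out(n_contigs);
  List refs(capture_ref ? (R_xlen_t)n_contigs : 0);

  auto append_with_rc = [&](const uint8_t* d, long long n) {
    ref.append(d, n, nullptr);
    if (p.rc_enabled) {
      std::vector<uint8_t> rc((size_t)n);
      refzip::reverse_complement(d, rc.data(), n);
      ref.append(rc.data(), n, nullptr);
    }
  };

  long long first_file_contigs =
      (p.mode == 0 && contig_counts.size() > 0) ? contig_counts[0] : 0;
  std::vector<uint8_t> g1;  // default mode: first genome, replayed from
                            // literals, seeds the reference afterwards

  for (long long ci = 0; ci < n_contigs; ++ci) {
    long long ntok = (long long)token_counts[ci];
    if (tok_cur + ntok > kinds.size())
      stop("archive corruption: token stream underrun");
    // first pass: contig length
    long long clen = 0;
    {
      long long mc = match_cur, lc = lit_run_cur;
      for (long long t = 0; t < ntok; ++t) {
        if (kinds[tok_cur + t] != 0) {
          if (mc >= lengths.size())
            stop("archive corruption: match stream underrun");
          clen += (long long)lengths[mc++];
        } else {
          if (lc >= literal_lens.size())
            stop("archive corruption: literal-length stream underrun");
          clen += (long long)literal_lens[lc++];
        }
      }
    }
    RawVector seq(clen);
    uint8_t* dst = RAW(seq);
    long long w = 0;
    for (long long t = 0; t < ntok; ++t) {
      if (kinds[tok_cur + t] != 0) {
        long long off = (long long)offsets[match_cur];
        long long len = (long long)lengths[match_cur];
        ++match_cur;
        if (off < 0 || len < 0 || off + len > ref.extent())
          stop("archive corruption: match beyond reference extent");
        std::copy(ref.buf.data() + off, ref.buf.data() + off + len, dst + w);
        w += len;
      } else {
        long long len = (long long)literal_lens[lit_run_cur++];
        if (lit_byte_cur + len > literals.size())
          stop("archive corruption: literal stream underrun");
        std::copy(RAW(literals) + lit_byte_cur,
                  RAW(literals) + lit_byte_cur + len, dst + w);
        lit_byte_cur += len;
        w += len;
      }
    }
    tok_cur += ntok;
    out[ci] = seq;

    if (ci < first_file_contigs) {
      g1.insert(g1.end(), dst, dst + clen);
      if (ci == first_file_contigs - 1) append_with_rc(g1.data(), (long long)g1.size());
    } else if (appended[ci]) {
      append_with_rc(dst, clen);
    }
    if (capture_ref) {
      RawVector snap(ref.extent());
      std::copy(ref.buf.data(), ref.buf.data() + ref.extent(), RAW(snap));
      refs[ci] = snap;
    }
  }
  if (tok_cur != kinds.size() || match_cur != offsets.size() ||
      lit_run_cur != literal_lens.size() || lit_byte_cur != literals.size())
    stop("archive corruption: trailing data in streams");

  List res = List::create(_["sequences"] = out);
  if (capture_ref) res["refs"] = refs;
  return res;
}
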