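#include "refzip.h"

using namespace Rcpp;

namespace refzip {

EncParams params_from_list(const List& p) {
  EncParams e;
  e.k = as<int>(p["k"]);
  e.stride = as<int>(p["stride"]);
  e.m = as<int>(p["skip_margin"]);
  e.u = (long long)as<double>(p["u"]);
  e.table_bits = as<int>(p["table_bits"]);
  e.ref_limit = (long long)as<double>(p["ref_limit"]);
  e.rc_enabled = as<bool>(p["rc"]);
  e.swallow = as<bool>(p["swallow"]);
  e.mode = std::string(as<std::string>(p["mode"])) == "max" ? 1 : 0;
  e.level = as<int>(p["level"]);
  if (e.k < 1 || e.k > 32) stop("k must be in [1, 32]");
  if (e.stride < 1) stop("stride must be >= 1");
  if (e.m < 0) stop("skip_margin must be >= 0");
  if (e.u < 1) stop("u must be >= 1");
  if (e.table_bits < 1 || e.table_bits > 30) stop("table_bits must be in [1, 30]");
  if (e.ref_limit < 1) stop("ref_limit must be >= 1");
  return e;
}

void RefBuf::append(const uint8_t* d, long long n,
                    std::vector<std::pair<long long, long long>>* segs) {
  while (n > 0) {
    if (!wrapped) {
      long long space = limit - end;
      if (space == 0) {
        wrapped = true;
        wpos = 0;
        continue;
      }
      long long take = std::min(space, n);
      buf.insert(buf.end(), d, d + take);
      if (segs) segs->push_back({end, end + take});
      end += take;
      wpos = end;
      d += take;
      n -= take;
      if (end == limit && n > 0) {
        wrapped = true;
        wpos = 0;
      }
    } else {
      long long take = std::min(limit - wpos, n);
      std::copy(d, d + take, buf.begin() + (size_t)wpos);
      if (segs) segs->push_back({wpos, wpos + take});
      wpos += take;
      if (wpos == limit) wpos = 0;
      d += take;
      n -= take;
    }
  }
}

void Encoder::index_range(long long from, long long to) {
  long long ext = ref.extent();
  if (to > ext) to = ext;
  const uint8_t* b = ref.buf.data();
  for (long long pos = from; pos + p.k <= to; pos += p.stride) {
    uint64_t packed;
    if (!pack_kmer(b + pos, p.k, packed)) continue;
    index[(size_t)slot_for(packed, p.k, p.table_bits)] = pos;
  }
}

long long Encoder::find_candidate(const uint8_t* contig, long long clen,
                                  long long pos) const {
  if (pos + p.k > clen) return -1;
  uint64_t packed;
  if (!pack_kmer(contig + pos, p.k, packed)) return -1;
  long long cand = index[(size_t)slot_for(packed, p.k, p.table_bits)];
  if (cand < 0 || cand + p.k > ref.extent()) return -1;
  // Verify the k seed symbols against the current reference content; this
  // also screens out hash collisions and entries gone stale after a wrap.
  const uint8_t* b = ref.buf.data();
  for (int i = 0; i < p.k; ++i)
    if (b[cand + i] != contig[pos + i]) return -1;
  return cand;
}

void Encoder::append_sequence(const uint8_t* d, long long n) {
  std::vector<std::pair<long long, long long>> segs;
  ref.append(d, n, &segs);
  if (p.rc_enabled) {
    std::vector<uint8_t> rc((size_t)n);
    reverse_complement(d, rc.data(), n);
    ref.append(rc.data(), n, &segs);
  }
  for (auto& s : segs) index_range(s.first, s.second);
}

namespace {

struct Tok {
  bool is_match;
  long long start;    // target position of the first covered symbol
  long long len;
  long long ref_off;  // matches only
};

// Remove committed tokens wholly covered by a left extension down to
// `sstart`; returns the coverage end of what remains (the final start of the
// incoming match, i.e. truncation point for a partially overlapped token).
long long pop_swallowed(std::vector<Tok>& toks, long long sstart) {
  while (!toks.empty() && toks.back().start >= sstart) toks.pop_back();
  return toks.empty() ? 0 : toks.back().start + toks.back().len;
}

}  // namespace

// Factor one contig into matches and literal runs against the current
// reference. Returns token streams; does not touch the reference.
List encode_contig_impl(Encoder& enc, const uint8_t* contig, long long len) {
  const EncParams& p = enc.p;
  const uint8_t* rbuf = enc.ref.buf.data();

  std::vector<Tok> toks;
  long long pos = 0;        // scan position (may re-visit covered ground)
  long long cov = 0;        // covered prefix [0, cov)
  long long pend = -1;      // pending literal run start, -1 = none

  auto commit_literal = [&](long long from, long long to) {
    if (to > from) toks.push_back({false, from, to - from, 0});
  };

  while (pos + p.k <= len) {
    long long cand = enc.find_candidate(contig, len, pos);
    if (cand < 0) {
      if (pos == cov) {  // fresh ground missed: buffer one literal symbol
        if (pend < 0) pend = pos;
        cov = pos + 1;
      }
      ++pos;
      continue;
    }
    long long ext = enc.ref.extent();
    // maximal right extension (cannot cross the contig end or the valid
    // reference extent)
    long long e = pos + p.k, re = cand + p.k;
    while (e < len && re < ext && contig[e] == rbuf[re]) { ++e; ++re; }
    if (e <= cov) { ++pos; continue; }  // nothing new would be covered
    // maximal left extension
    long long sstart = pos, rs = cand;
    long long floor = p.swallow ? 0 : cov;
    while (sstart > floor && rs > 0 && contig[sstart - 1] == rbuf[rs - 1]) {
      --sstart; --rs;
    }
    long long final_start;
    if (!p.swallow) {
      // never consume pending or committed output
      commit_literal(pend < 0 ? cov : pend, cov);
      pend = -1;
      final_start = std::max(sstart, cov);
    } else if (pend >= 0 && sstart >= pend) {
      // the extension eats the tail of the pending literal run only
      commit_literal(pend, sstart);
      pend = -1;
      final_start = sstart;
    } else {
      // pending literal (if any) wholly swallowed; then swallow whole
      // committed tokens, truncating at a partially overlapped one
      pend = -1;
      final_start = pop_swallowed(toks, sstart);
    }
    toks.push_back({true, final_start, e - final_start,
                    rs + (final_start - sstart)});
    cov = e;
    // resume m symbols before the match end (skip margin), but always make
    // progress past the start of the token just emitted
    pos = std::max(e - p.m, final_start + 1);
  }
  // trailing uncovered symbols become the final literal run
  if (pend < 0) pend = cov;
  commit_literal(pend, len);
  cov = len;

  // flatten into streams
  R_xlen_t ntok = (R_xlen_t)toks.size();
  RawVector kinds(ntok);
  long long nmatch = 0, nlit_bytes = 0;
  for (auto& t : toks) {
    if (t.is_match) ++nmatch; else nlit_bytes += t.len;
  }
  NumericVector offs(nmatch), lens(nmatch), lit_lens(ntok - nmatch);
  RawVector lits(nlit_bytes);
  long long im = 0, il = 0, ib = 0;
  for (R_xlen_t i = 0; i < ntok; ++i) {
    const Tok& t = toks[i];
    kinds[i] = t.is_match ? 1 : 0;
    if (t.is_match) {
      offs[im] = (double)t.ref_off;
      lens[im] = (double)t.len;
      ++im;
    } else {
      lit_lens[il++] = (double)t.len;
      std::copy(contig + t.start, contig + t.start + t.len, RAW(lits) + ib);
      ib += t.len;
    }
  }
  return List::create(_["kinds"] = kinds, _["offsets"] = offs,
                      _["lengths"] = lens, _["literal_lens"] = lit_lens,
                      _["literals"] = lits,
                      _["unmatched"] = (double)nlit_bytes);
}

}  // namespace refzip

using refzip::Encoder;

// [[Rcpp::export]]
SEXP cpp_encoder_new(List params) {
  refzip::EncParams p = refzip::params_from_list(params);
  XPtr<Encoder> ptr(new Encoder(p), true);
  return ptr;
}

// [[Rcpp::export]]
void cpp_append_sequence(SEXP enc, RawVector seq) {
  XPtr<Encoder> e(enc);
  e->append_sequence(RAW(seq), (long long)seq.size());
}

// [[Rcpp::export]]
void cpp_index_range(SEXP enc, double from, double to) {
  XPtr<Encoder> e(enc);
  if (from < 0 || to < from || to > e->ref.extent())
    stop("invalid index range");
  e->index_range((long long)from, (long long)to);
}

// [[Rcpp::export]]
double cpp_find_candidate(SEXP enc, RawVector contig, double pos) {
  XPtr<Encoder> e(enc);
  if (pos < 0 || pos + e->p.k > contig.size()) stop("position out of range");
  return (double)e->find_candidate(RAW(contig), (long long)contig.size(),
                                   (long long)pos);
}

// [[Rcpp::export]]
List cpp_encode_contig(SEXP enc, RawVector contig) {
  XPtr<Encoder> e(enc);
  return refzip::encode_contig_impl(*e, RAW(contig),
                                    (long long)contig.size());
}

// [[Rcpp::export]]
List cpp_ref_info(SEXP enc) {
  XPtr<Encoder> e(enc);
  return List::create(_["end"] = (double)e->ref.end,
                      _["extent"] = (double)e->ref.extent(),
                      _["limit"] = (double)e->ref.limit,
                      _["wrapped"] = e->ref.wrapped,
                      _["write_pos"] = (double)e->ref.wpos);
}

// [[Rcpp::export]]
RawVector cpp_ref_bytes(SEXP enc) {
  XPtr<Encoder> e(enc);
  long long n = e->ref.extent();
  RawVector out(n);
  std::copy(e->ref.buf.data(), e->ref.buf.data() + n, RAW(out));
  return out;
}

// [[Rcpp::export]]
double cpp_index_slot(SEXP enc, double slot) {
  XPtr<Encoder> e(enc);
  if (slot < 0 || slot >= (double)e->index.size()) stop("slot out of range");
  return (double)e->index[(size_t)slot];
}
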