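// Smith-Waterman affine-gap local alignment core and the seeded/exhaustive
// translated search driver. Gap of length g costs gap_open + g * gap_extend,
// matching the usual BLAST parameterisation (open 11, extend 1 => a length-1
// gap costs 12). Score matrices are symmetric, so row/column order of the
// residue codes does not matter.

#include <Rcpp.h>
#include <climits>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

// Score-only SW in O(n) memory.
static int sw_score_only(const int* q, int m, const int* s, int n,
                         const int* S, int nrow, int go, int ge) {
  std::vector<int> H(n + 1, 0), E(n + 1, NEG_INF);
  const int gopen = go + ge;
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int* Sq = S + (size_t)q[i - 1] * nrow;
    int Hdiag = 0, F = NEG_INF, Hprev = 0;
    for (int j = 1; j <= n; ++j) {
      int e = H[j] - gopen;
      int e2 = E[j] - ge;
      if (e2 > e) e = e2;
      int f = Hprev - gopen;
      int f2 = F - ge;
      if (f2 > f) f = f2;
      F = f;
      int h = Hdiag + Sq[s[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      Hprev = h;
      E[j] = e;
      if (h > best) best = h;
    }
  }
  return best;
}

struct AlnDetail {
  int score, qstart, qend, sstart, send;
  int matches, paired, cols, gaps, gapopens;
};

// Full DP with traceback. Best cell ties broken by smallest i, then smallest j;
// traceback prefers diagonal, then gap-in-subject (E), then gap-in-query (F),
// so repeated runs are byte-identical.
static AlnDetail sw_traceback(const int* q, int m, const int* s, int n,
                              const int* S, int nrow, int go, int ge) {
  const int gopen = go + ge;
  const size_t W = (size_t)n + 1;
  std::vector<int> H((size_t)(m + 1) * W, 0), E((size_t)(m + 1) * W, NEG_INF),
      F((size_t)(m + 1) * W, NEG_INF);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int* Sq = S + (size_t)q[i - 1] * nrow;
    for (int j = 1; j <= n; ++j) {
      size_t c = (size_t)i * W + j, up = c - W, lf = c - 1;
      int e = std::max(H[lf] - gopen, E[lf] - ge);
      int f = std::max(H[up] - gopen, F[up] - ge);
      int h = H[up - 1] + Sq[s[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[c] = e;
      F[c] = f;
      H[c] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  AlnDetail d = {best, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  if (best <= 0) return d;
  int i = bi, j = bj;
  d.qend = bi;
  d.send = bj;
  int state = 0;  // 0 = H, 1 = E (gap in query string? no: consumes subject), 2 = F
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * W + j, up = c - W, lf = c - 1;
    if (state == 0) {
      if (H[c] == 0) break;
      int diag = H[up - 1] + S[(size_t)q[i - 1] * nrow + s[j - 1]];
      if (H[c] == diag) {
        d.cols++; d.paired++;
        if (q[i - 1] == s[j - 1]) d.matches++;
        i--; j--;
      } else if (H[c] == E[c]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // gap consuming subject residue j
      d.cols++; d.gaps++;
      if (E[c] == H[lf] - gopen) { d.gapopens++; state = 0; }
      j--;
    } else {  // gap consuming query residue i
      d.cols++; d.gaps++;
      if (F[c] == H[up] - gopen) { d.gapopens++; state = 0; }
      i--;
    }
  }
  d.qstart = i + 1;
  d.sstart = j + 1;
  return d;
}

// [[Rcpp::export]]
List sw_pair_cpp(IntegerVector q, IntegerVector s, IntegerMatrix smat,
                 int gap_open, int gap_extend) {
  if (q.size() == 0 || s.size() == 0)
    stop("peptides must be non-empty");
  AlnDetail d = sw_traceback(INTEGER(q), q.size(), INTEGER(s), s.size(),
                             INTEGER(smat), smat.nrow(), gap_open, gap_extend);
  return List::create(_["score"] = d.score, _["qstart"] = d.qstart,
                      _["qend"] = d.qend, _["sstart"] = d.sstart,
                      _["send"] = d.send, _["matches"] = d.matches,
                      _["paired"] = d.paired, _["cols"] = d.cols,
                      _["gaps"] = d.gaps, _["gapopens"] = d.gapopens);
}

// Translated search driver. Queries and subjects are peptide strings,
// encoded against `alphabet` (unknown residues fall back to the code of
// 'X'). Seeding uses exact words over the 20 standard amino acids (codes
// 0..19); a subject becomes a candidate for a query if they share at least
// one word. Candidates are then aligned with the full DP, so the seeded hit
// set equals the exhaustive one whenever a reportable hit contains one
// exact word.
// [[Rcpp::export]]
DataFrame translated_search_cpp(CharacterVector qseqs, CharacterVector sseqs,
                                std::string alphabet, IntegerMatrix smat,
                                int gap_open, int gap_extend, double lambda,
                                double K, double n_eff, double cutoff,
                                bool seeded, int word) {
  const int nq = qseqs.size(), ns = sseqs.size();
  const int nrow = smat.nrow();
  const int* S = INTEGER(smat);

  int lut[256];
  {
    int xcode = 0;
    for (size_t a = 0; a < alphabet.size(); ++a)
      if (alphabet[a] == 'X') xcode = (int)a;
    for (int c = 0; c < 256; ++c) lut[c] = xcode;
    for (size_t a = 0; a < alphabet.size(); ++a)
      lut[(unsigned char)alphabet[a]] = (int)a;
  }
  std::vector<std::vector<int>> qs(nq), ss(ns);
  for (int i = 0; i < nq; ++i) {
    const char* p = CHAR(STRING_ELT(qseqs, i));
    size_t len = strlen(p);
    qs[i].resize(len);
    for (size_t j = 0; j < len; ++j) qs[i][j] = lut[(unsigned char)p[j]];
  }
  for (int i = 0; i < ns; ++i) {
    const char* p = CHAR(STRING_ELT(sseqs, i));
    size_t len = strlen(p);
    ss[i].resize(len);
    for (size_t j = 0; j < len; ++j) ss[i][j] = lut[(unsigned char)p[j]];
  }

  // Inverted word index over subjects.
  int nwords = 1;
  for (int w = 0; w < word; ++w) nwords *= 20;
  std::vector<std::vector<int>> index;
  if (seeded) {
    index.assign(nwords, std::vector<int>());
    for (int si = 0; si < ns; ++si) {
      const std::vector<int>& s = ss[si];
      int len = (int)s.size();
      for (int p = 0; p + word <= len; ++p) {
        int code = 0;
        bool ok = true;
        for (int w = 0; w < word; ++w) {
          int c = s[p + w];
          if (c < 0 || c >= 20) { ok = false; break; }
          code = code * 20 + c;
        }
        if (!ok) continue;
        std::vector<int>& bucket = index[code];
        if (bucket.empty() || bucket.back() != si) bucket.push_back(si);
      }
    }
  }

  std::vector<int> r_qidx, r_sidx, r_score, r_qstart, r_qend, r_sstart, r_send;
  std::vector<int> r_matches, r_paired, r_cols, r_gaps, r_gapopens;
  std::vector<double> r_evalue, r_bits;

  std::vector<int> stamp(ns, -1);
  std::vector<int> cand;
  cand.reserve(ns);

  for (int qi = 0; qi < nq; ++qi) {
    const std::vector<int>& q = qs[qi];
    const int m = (int)q.size();
    if (m == 0) continue;
    cand.clear();
    if (!seeded) {
      for (int si = 0; si < ns; ++si) cand.push_back(si);
    } else {
      for (int p = 0; p + word <= m; ++p) {
        int code = 0;
        bool ok = true;
        for (int w = 0; w < word; ++w) {
          int c = q[p + w];
          if (c < 0 || c >= 20) { ok = false; break; }
          code = code * 20 + c;
        }
        if (!ok) continue;
        for (int si : index[code]) {
          if (stamp[si] != qi) { stamp[si] = qi; cand.push_back(si); }
        }
      }
      std::sort(cand.begin(), cand.end());
    }
    for (int si : cand) {
      const std::vector<int>& s = ss[si];
      if (s.empty()) continue;
      int sc = sw_score_only(q.data(), m, s.data(), (int)s.size(), S, nrow,
                             gap_open, gap_extend);
      if (sc <= 0) continue;
      double E = K * (double)m * n_eff * std::exp(-lambda * sc);
      if (E > cutoff) continue;
      AlnDetail d = sw_traceback(q.data(), m, s.data(), (int)s.size(), S, nrow,
                                 gap_open, gap_extend);
      r_qidx.push_back(qi + 1);
      r_sidx.push_back(si + 1);
      r_score.push_back(d.score);
      r_qstart.push_back(d.qstart);
      r_qend.push_back(d.qend);
      r_sstart.push_back(d.sstart);
      r_send.push_back(d.send);
      r_matches.push_back(d.matches);
      r_paired.push_back(d.paired);
      r_cols.push_back(d.cols);
      r_gaps.push_back(d.gaps);
      r_gapopens.push_back(d.gapopens);
      r_evalue.push_back(E);
      r_bits.push_back((lambda * d.score - std::log(K)) / std::log(2.0));
    }
  }

  return DataFrame::create(
      _["qidx"] = r_qidx, _["sidx"] = r_sidx, _["raw_score"] = r_score,
      _["qstart"] = r_qstart, _["qend"] = r_qend, _["sstart"] = r_sstart,
      _["send"] = r_send, _["matches"] = r_matches, _["paired"] = r_paired,
      _["cols"] = r_cols, _["gaps"] = r_gaps, _["gapopens"] = r_gapopens,
      _["evalue"] = r_evalue, _["bitscore"] = r_bits);
}

// Stem-loop candidate scan for the terminator screen. seq is coded A=0, C=1,
// G=2, T=3, other=4; pair_e is a 5x5 energy matrix with NA for disallowed
// pairs. Reports every (start, stem, loop) whose full stem pairs and whose
// energy (pair sum + loop_base + loop_slope * (loop_len - 3)) is <= threshold,
// optionally requiring a run of >= tail_min_t T's starting within tail_window
// nt after the right stem; the reported end then covers that T run.
// [[Rcpp::export]]
DataFrame scan_hairpins_cpp(IntegerVector seq, NumericMatrix pair_e,
                            int stem_min, int stem_max, int loop_min,
                            int loop_max, double loop_base, double loop_slope,
                            double threshold, bool require_tail,
                            int tail_window, int tail_min_t) {
  const int n = seq.size();
  const int* x = INTEGER(seq);
  std::vector<int> r_start, r_end, r_stem, r_loop;
  std::vector<double> r_energy;
  for (int s0 = 0; s0 < n; ++s0) {
    for (int l = loop_min; l <= loop_max; ++l) {
      for (int k = stem_min; k <= stem_max; ++k) {
        int rend = s0 + 2 * k + l - 1;
        if (rend >= n) break;
        double esum = 0.0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          double pe = pair_e(x[s0 + j], x[rend - j]);
          if (NumericVector::is_na(pe)) { ok = false; break; }
          esum += pe;
        }
        if (!ok) continue;  // a longer stem pairs different partners
        double energy = esum + loop_base + loop_slope * (l - 3);
        if (energy > threshold) continue;
        int end0 = rend;
        if (require_tail) {
          int run_start = -1;
          for (int t = rend + 1; t <= rend + tail_window && t < n; ++t) {
            if (x[t] == 3) {
              int r = t;
              while (r + 1 < n && x[r + 1] == 3) ++r;
              if (r - t + 1 >= tail_min_t) { run_start = t; end0 = r; }
              break;  // only the first T run in the window counts
            }
          }
          if (run_start < 0) continue;
        }
        r_start.push_back(s0 + 1);
        r_end.push_back(end0 + 1);
        r_stem.push_back(k);
        r_loop.push_back(l);
        r_energy.push_back(energy);
      }
    }
  }
  return DataFrame::create(_["start"] = r_start, _["end"] = r_end,
                           _["stem_len"] = r_stem, _["loop_len"] = r_loop,
                           _["energy"] = r_energy);
}
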