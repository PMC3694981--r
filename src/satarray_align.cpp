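// Affine-gap alignment kernels used throughout the package:
//  - global (Needleman-Wunsch/Gotoh) pairwise alignment with traceback,
//  - all-pairs percent-identity matrices,
//  - banded global scan of a consensus along an array (monomer tiling),
//  - free-rotation local fragment search against a doubled consensus,
//  - best cyclic rotation of a monomer against a reference,
//  - ungapped sliding-window identity scans (box discovery).
//
// Scoring convention: a gap of length g costs gap_open + g * gap_extend
// (both <= 0; the opening charge is applied once, at the first gapped
// position). Percent identity = 100 * matches / columns where neither
// row is a gap.
#include <Rcpp.h>
#include <cfloat>
#include <climits>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const double NEG_INF = -1e30;

struct AlnStats {
  double score;
  int matches;
  int paircols;   // columns with a residue in both rows
  int u_eff;      // first consensus (a) position aligned to a residue of b
  int v_eff;      // one past the last consensus (a) position aligned to a residue of b
  std::string aln_a, aln_b;
};

// Global Gotoh alignment of a vs b. Deterministic traceback preference:
// diagonal (M), then gap-in-b (consume a), then gap-in-a (consume b).
static AlnStats global_align(const std::string& a, const std::string& b,
                             double match, double mismatch,
                             double gap_open, double gap_extend,
                             bool build_strings) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF); // gap in b (vertical, consumes a)
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF); // gap in a (horizontal, consumes b)
  std::vector<signed char> tM((n + 1) * (m + 1), 0), tX((n + 1) * (m + 1), 0),
      tY((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = gap_open + i * gap_extend;
    tX[idx(i, 0)] = (i == 1) ? 0 : 1; // from M at origin, else extend
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = gap_open + j * gap_extend;
    tY[idx(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M
      double best = M[idx(i - 1, j - 1)]; signed char st = 0;
      if (X[idx(i - 1, j - 1)] > best) { best = X[idx(i - 1, j - 1)]; st = 1; }
      if (Y[idx(i - 1, j - 1)] > best) { best = Y[idx(i - 1, j - 1)]; st = 2; }
      if (best > NEG_INF / 2) { M[idx(i, j)] = best + s; tM[idx(i, j)] = st; }
      // X: consume a[i-1] against a gap
      best = M[idx(i - 1, j)] + gap_open + gap_extend; st = 0;
      if (X[idx(i - 1, j)] + gap_extend > best) { best = X[idx(i - 1, j)] + gap_extend; st = 1; }
      if (Y[idx(i - 1, j)] + gap_open + gap_extend > best) {
        best = Y[idx(i - 1, j)] + gap_open + gap_extend; st = 2;
      }
      if (best > NEG_INF / 2) { X[idx(i, j)] = best; tX[idx(i, j)] = st; }
      // Y: consume b[j-1] against a gap
      best = M[idx(i, j - 1)] + gap_open + gap_extend; st = 0;
      if (Y[idx(i, j - 1)] + gap_extend > best) { best = Y[idx(i, j - 1)] + gap_extend; st = 1; }
      if (X[idx(i, j - 1)] + gap_open + gap_extend > best) {
        best = X[idx(i, j - 1)] + gap_open + gap_extend; st = 2;
      }
      if (best > NEG_INF / 2) { Y[idx(i, j)] = best; tY[idx(i, j)] = st; }
    }
  }

  AlnStats out; out.matches = 0; out.paircols = 0;
  int state = 0; double best = M[idx(n, m)];
  if (X[idx(n, m)] > best) { best = X[idx(n, m)]; state = 1; }
  if (Y[idx(n, m)] > best) { best = Y[idx(n, m)]; state = 2; }
  out.score = best;

  int i = n, j = m;
  int first_pair = -1, last_pair = -1;
  std::string ra, rb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const signed char st = tM[idx(i, j)];
      if (a[i - 1] == b[j - 1]) out.matches++;
      out.paircols++;
      if (last_pair < 0) last_pair = i;   // highest a-position in a paired column
      first_pair = i - 1;                 // keeps updating; ends at lowest
      if (build_strings) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); }
      --i; --j; state = st;
    } else if (state == 1) {
      const signed char st = tX[idx(i, j)];
      if (build_strings) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      --i; state = st;
    } else {
      const signed char st = tY[idx(i, j)];
      if (build_strings) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      --j; state = st;
    }
  }
  out.u_eff = (first_pair < 0) ? 0 : first_pair;
  out.v_eff = (last_pair < 0) ? 0 : last_pair;
  if (build_strings) {
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    out.aln_a = ra; out.aln_b = rb;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b, double match, double mismatch,
                      double gap_open, double gap_extend, bool strings = true) {
  AlnStats st = global_align(a, b, match, mismatch, gap_open, gap_extend, strings);
  double ident = st.paircols > 0 ? 100.0 * st.matches / st.paircols : 0.0;
  return List::create(_["score"] = st.score, _["matches"] = st.matches,
                      _["paircols"] = st.paircols, _["identity"] = ident,
                      _["aligned_a"] = st.aln_a, _["aligned_b"] = st.aln_b);
}

// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(CharacterVector seqs, double match, double mismatch,
                                  double gap_open, double gap_extend) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  // pairs are aligned in lexicographic order: co-optimal alignments can
  // carry different match counts, and a canonical orientation keeps the
  // reported identity symmetric
  for (int i = 0; i < n; ++i) {
    out(i, i) = 100.0;
    for (int j = i + 1; j < n; ++j) {
      const bool swap = s[j] < s[i];
      AlnStats st = swap
        ? global_align(s[j], s[i], match, mismatch, gap_open, gap_extend, false)
        : global_align(s[i], s[j], match, mismatch, gap_open, gap_extend, false);
      double ident = st.paircols > 0 ? 100.0 * st.matches / st.paircols : 0.0;
      out(i, j) = ident; out(j, i) = ident;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_identity_vector(std::string a, CharacterVector seqs, double match,
                                  double mismatch, double gap_open, double gap_extend) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string b = as<std::string>(seqs[i]);
    AlnStats st = (b < a)
      ? global_align(b, a, match, mismatch, gap_open, gap_extend, false)
      : global_align(a, b, match, mismatch, gap_open, gap_extend, false);
    out[i] = st.paircols > 0 ? 100.0 * st.matches / st.paircols : 0.0;
  }
  return out;
}

// Banded global alignment of `cons` (rows) against clone[start .. start+cmax)
// for every start. For each start the best end column within [L-band, L+band]
// is reported together with identity and the effective consensus coordinates
// at the clone-segment edges (leading/trailing consensus deletions trimmed).
// [[Rcpp::export]]
List cpp_scan_complete(std::string clone, std::string cons, double match,
                       double mismatch, double gap_open, double gap_extend,
                       int band = 15) {
  const int N = (int)clone.size(), L = (int)cons.size();
  const int W = 2 * band + 1;
  std::vector<double> M((L + 1) * W), X((L + 1) * W), Y((L + 1) * W);
  std::vector<signed char> TB((L + 1) * W * 3);
  auto col_ok = [&](int r, int c) { return c >= r - band && c <= r + band; };
  auto off = [&](int r, int c) { return r * W + (c - r + band); };

  const int nst = N - (L - band) + 1 > 0 ? N - (L - band) + 1 : 0;
  IntegerVector v_start(nst), v_end(nst), v_u(nst), v_v(nst);
  NumericVector v_score(nst), v_ident(nst);
  LogicalVector v_valid(nst);

  for (int s = 0; s + (L - band) <= N; ++s) {
    const int cmax = std::min(L + band, N - s);
    for (int r = 0; r <= L; ++r)
      for (int c = std::max(0, r - band); c <= std::min(cmax, r + band); ++c) {
        M[off(r, c)] = X[off(r, c)] = Y[off(r, c)] = NEG_INF;
      }
    M[off(0, 0)] = 0.0;
    for (int r = 1; r <= std::min(L, band); ++r) {
      X[off(r, 0)] = gap_open + r * gap_extend;
      TB[off(r, 0) * 3 + 1] = (r == 1) ? 0 : 1;
    }
    for (int c = 1; c <= std::min(cmax, band); ++c) {
      Y[off(0, c)] = gap_open + c * gap_extend;
      TB[off(0, c) * 3 + 2] = (c == 1) ? 0 : 2;
    }
    for (int r = 1; r <= L; ++r) {
      const int clo = std::max(1, r - band), chi = std::min(cmax, r + band);
      for (int c = clo; c <= chi; ++c) {
        const double sc = (cons[r - 1] == clone[s + c - 1]) ? match : mismatch;
        double best = NEG_INF; signed char st = 0;
        if (col_ok(r - 1, c - 1)) {
          best = M[off(r - 1, c - 1)]; st = 0;
          if (X[off(r - 1, c - 1)] > best) { best = X[off(r - 1, c - 1)]; st = 1; }
          if (Y[off(r - 1, c - 1)] > best) { best = Y[off(r - 1, c - 1)]; st = 2; }
        }
        M[off(r, c)] = (best > NEG_INF / 2) ? best + sc : NEG_INF;
        TB[off(r, c) * 3 + 0] = st;
        // X: consume consensus row r against gap
        best = NEG_INF; st = 0;
        if (col_ok(r - 1, c)) {
          best = M[off(r - 1, c)] + gap_open + gap_extend; st = 0;
          if (X[off(r - 1, c)] + gap_extend > best) { best = X[off(r - 1, c)] + gap_extend; st = 1; }
          if (Y[off(r - 1, c)] + gap_open + gap_extend > best) {
            best = Y[off(r - 1, c)] + gap_open + gap_extend; st = 2;
          }
        }
        X[off(r, c)] = (best > NEG_INF / 2) ? best : NEG_INF;
        TB[off(r, c) * 3 + 1] = st;
        // Y: consume clone col c against gap
        best = NEG_INF; st = 0;
        if (col_ok(r, c - 1)) {
          best = M[off(r, c - 1)] + gap_open + gap_extend; st = 0;
          if (Y[off(r, c - 1)] + gap_extend > best) { best = Y[off(r, c - 1)] + gap_extend; st = 1; }
          if (X[off(r, c - 1)] + gap_open + gap_extend > best) {
            best = X[off(r, c - 1)] + gap_open + gap_extend; st = 2;
          }
        }
        Y[off(r, c)] = (best > NEG_INF / 2) ? best : NEG_INF;
        TB[off(r, c) * 3 + 2] = st;
      }
    }
    // best end column on the last consensus row
    double bestv = NEG_INF; int bestc = -1; int bestState = 0;
    for (int c = std::max(1, L - band); c <= std::min(cmax, L + band); ++c) {
      double v = M[off(L, c)]; int stt = 0;
      if (X[off(L, c)] > v) { v = X[off(L, c)]; stt = 1; }
      if (Y[off(L, c)] > v) { v = Y[off(L, c)]; stt = 2; }
      if (v > bestv) { bestv = v; bestc = c; bestState = stt; }
    }
    v_start[s] = s;
    if (bestc < 0 || bestv < NEG_INF / 2) { v_valid[s] = false; continue; }
    // traceback for matches / paircols / effective consensus edges
    int r = L, c = bestc, state = bestState;
    int matches = 0, paircols = 0, first_pair = -1, last_pair = -1;
    while (r > 0 || c > 0) {
      if (state == 0) {
        if (cons[r - 1] == clone[s + c - 1]) matches++;
        paircols++;
        if (last_pair < 0) last_pair = r;
        first_pair = r - 1;
        state = TB[off(r, c) * 3 + 0]; --r; --c;
      } else if (state == 1) {
        state = TB[off(r, c) * 3 + 1]; --r;
      } else {
        state = TB[off(r, c) * 3 + 2]; --c;
      }
    }
    v_valid[s] = true;
    v_end[s] = s + bestc;
    v_score[s] = bestv;
    v_ident[s] = paircols > 0 ? 100.0 * matches / paircols : 0.0;
    v_u[s] = first_pair < 0 ? 0 : first_pair;
    v_v[s] = last_pair < 0 ? 0 : last_pair;
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["start"] = v_start, _["end"] = v_end, _["score"] = v_score,
                      _["identity"] = v_ident, _["u"] = v_u, _["v"] = v_v,
                      _["valid"] = v_valid);
}

// Local (Smith-Waterman, affine) alignment of a doubled consensus (rows)
// against a clone segment (cols). Free start/end on both; the traceback path
// is trimmed from its tail until the consensus row span is at most one period
// L, so a fragment never wraps past a full monomer. Returns the best fragment.
// [[Rcpp::export]]
List cpp_local_fragment(std::string segment, std::string cons2, int period,
                        double match, double mismatch, double gap_open,
                        double gap_extend) {
  const int n = (int)cons2.size(), m = (int)segment.size();
  std::vector<double> M((n + 1) * (m + 1), 0.0), X((n + 1) * (m + 1), NEG_INF),
      Y((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> tM((n + 1) * (m + 1), 0), tX((n + 1) * (m + 1), 0),
      tY((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  double bestv = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (cons2[i - 1] == segment[j - 1]) ? match : mismatch;
      double best = M[idx(i - 1, j - 1)]; signed char st = 0;
      if (X[idx(i - 1, j - 1)] > best) { best = X[idx(i - 1, j - 1)]; st = 1; }
      if (Y[idx(i - 1, j - 1)] > best) { best = Y[idx(i - 1, j - 1)]; st = 2; }
      double v = best + s;
      if (v <= 0.0) { M[idx(i, j)] = 0.0; tM[idx(i, j)] = 0; }
      else { M[idx(i, j)] = v; tM[idx(i, j)] = st; }
      if (M[idx(i, j)] > bestv) { bestv = M[idx(i, j)]; bi = i; bj = j; }
      best = M[idx(i - 1, j)] + gap_open + gap_extend; st = 0;
      if (X[idx(i - 1, j)] + gap_extend > best) { best = X[idx(i - 1, j)] + gap_extend; st = 1; }
      X[idx(i, j)] = best; tX[idx(i, j)] = st;
      best = M[idx(i, j - 1)] + gap_open + gap_extend; st = 0;
      if (Y[idx(i, j - 1)] + gap_extend > best) { best = Y[idx(i, j - 1)] + gap_extend; st = 1; }
      Y[idx(i, j)] = best; tY[idx(i, j)] = st;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  if (bestv <= 0.0)
    return List::create(_["found"] = false);
  // collect the path (tail first): step kinds 0 = diag, 1 = up (gap in
  // segment), 2 = left (gap in consensus)
  std::vector<int> pr, pc; std::vector<signed char> pk;
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (M[idx(i, j)] <= 0.0) break; // local origin
      pr.push_back(i); pc.push_back(j); pk.push_back(0);
      state = tM[idx(i, j)]; --i; --j;
    } else if (state == 1) {
      pr.push_back(i); pc.push_back(j); pk.push_back(1);
      state = tX[idx(i, j)]; --i;
    } else {
      pr.push_back(i); pc.push_back(j); pk.push_back(2);
      state = tY[idx(i, j)]; --j;
    }
  }
  std::reverse(pr.begin(), pr.end());
  std::reverse(pc.begin(), pc.end());
  std::reverse(pk.begin(), pk.end());
  // per-step score deltas, then the maximum-score contiguous sub-path whose
  // consensus row span stays within one period (the raw local path can
  // accumulate weakly positive junk before/after a monomer, or wrap past a
  // full period through a repeated box)
  const int np = (int)pr.size();
  std::vector<double> delta(np);
  bool ingap = false;
  for (int k = 0; k < np; ++k) {
    if (pk[k] == 0) {
      delta[k] = (cons2[pr[k] - 1] == segment[pc[k] - 1]) ? match : mismatch;
      ingap = false;
    } else {
      delta[k] = gap_extend + (ingap ? 0.0 : gap_open);
      ingap = true;
    }
  }
  std::vector<double> prefix(np + 1, 0.0);
  for (int k = 0; k < np; ++k) prefix[k + 1] = prefix[k] + delta[k];
  double bestsum = 0.0; int ba = -1, bb = -1;
  int a = 0;
  for (int b = 0; b < np; ++b) {
    while (pr[b] - pr[a] + 1 > period) ++a;
    // best start within [a, b]: minimize prefix over the allowed window
    double minpref = prefix[a]; int mini = a;
    for (int s = a; s <= b; ++s)
      if (prefix[s] < minpref) { minpref = prefix[s]; mini = s; }
    const double sum = prefix[b + 1] - minpref;
    if (sum > bestsum) { bestsum = sum; ba = mini; bb = b; }
  }
  if (ba < 0 || bestsum <= 0.0) return List::create(_["found"] = false);
  int matches = 0, paircols = 0;
  int minr = INT_MAX, maxr = -1, minc = INT_MAX, maxc = -1;
  for (int k = ba; k <= bb; ++k) {
    if (pk[k] == 0) {
      paircols++;
      if (cons2[pr[k] - 1] == segment[pc[k] - 1]) matches++;
    }
    if (pk[k] != 1) { minc = std::min(minc, pc[k]); maxc = std::max(maxc, pc[k]); }
    if (pk[k] != 2) { minr = std::min(minr, pr[k]); maxr = std::max(maxr, pr[k]); }
  }
  if (maxc < 0 || maxr < 0 || paircols == 0) return List::create(_["found"] = false);
  const double ident = 100.0 * matches / paircols;
  return List::create(_["found"] = true, _["seg_start"] = minc - 1,
                      _["seg_end"] = maxc, _["u"] = minr - 1, _["v"] = maxr,
                      _["score"] = bestsum, _["identity"] = ident,
                      _["matches"] = matches, _["paircols"] = paircols);
}

// Best cyclic rotation of seq against ref. The winning rotation maximizes
// the global alignment score (ties: higher identity, then smaller offset);
// identity alone would be fooled by end gaps, which it does not pay for.
// [[Rcpp::export]]
List cpp_best_rotation(std::string seq, std::string ref, double match,
                       double mismatch, double gap_open, double gap_extend) {
  const int L = (int)seq.size();
  std::string dbl = seq + seq;
  double best_ident = -1.0; int best_off = 0; double best_score = NEG_INF;
  for (int off = 0; off < L; ++off) {
    std::string rot = dbl.substr(off, L);
    AlnStats st = global_align(rot, ref, match, mismatch, gap_open, gap_extend, false);
    double ident = st.paircols > 0 ? 100.0 * st.matches / st.paircols : 0.0;
    if (st.score > best_score + 1e-12 ||
        (st.score > best_score - 1e-12 && ident > best_ident + 1e-12)) {
      best_ident = ident; best_off = off; best_score = st.score;
    }
    if (off % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["offset"] = best_off, _["identity"] = best_ident,
                      _["score"] = best_score);
}

// For every window [s, s+L) of `anchor` (L in [Lmin, Lmax]) and every
// target sequence, the best ungapped placement identity (and its offset) of
// the window on the target. Computed from per-shift match prefix sums, so
// the cost is (shifts x positions), not (positions x offsets x L).
// [[Rcpp::export]]
List cpp_window_scan_range(std::string anchor, CharacterVector targets,
                           int Lmin, int Lmax) {
  const int A = (int)anchor.size();
  const int nt = targets.size();
  const int nL = Lmax - Lmin + 1;
  // per (L): identity and offset matrices (ns_L x nt)
  List out(nL);
  std::vector<NumericMatrix> ident(nL);
  std::vector<IntegerMatrix> offm(nL);
  for (int li = 0; li < nL; ++li) {
    const int L = Lmin + li;
    const int ns = std::max(A - L + 1, 0);
    ident[li] = NumericMatrix(ns, nt);
    offm[li] = IntegerMatrix(ns, nt);
    std::fill(ident[li].begin(), ident[li].end(), -1.0);
  }
  std::vector<int> pref(A + 1);
  for (int t = 0; t < nt; ++t) {
    const std::string T = as<std::string>(targets[t]);
    const int Tn = (int)T.size();
    for (int r = -(A - Lmin); r <= Tn - Lmin; ++r) {
      const int kmin = std::max(0, -r);
      const int kmax = std::min(A, Tn - r); // exclusive
      if (kmax - kmin < Lmin) continue;
      pref[kmin] = 0;
      for (int k = kmin; k < kmax; ++k)
        pref[k + 1] = pref[k] + (anchor[k] == T[k + r] ? 1 : 0);
      for (int li = 0; li < nL; ++li) {
        const int L = Lmin + li;
        const int smin = kmin, smax = kmax - L; // window fully inside overlap
        for (int s = smin; s <= smax; ++s) {
          const double id = 100.0 * (pref[s + L] - pref[s]) / L;
          if (id > ident[li](s, t)) {
            ident[li](s, t) = id;
            offm[li](s, t) = s + r;
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  for (int li = 0; li < nL; ++li)
    out[li] = List::create(_["L"] = Lmin + li, _["identity"] = ident[li],
                           _["offset"] = offm[li]);
  return out;
}
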