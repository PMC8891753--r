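#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Affine gap convention throughout: a gap of length L costs open + L * extend
// (BLAST convention, so open = 11 / extend = 1 reproduces BLASTP defaults).

static const double NEG = -1e30;

// Score-only Smith-Waterman with rolling rows: used by database search,
// where most pairs fall above the E-value cutoff and need no traceback.
// [[Rcpp::export]]
double cpp_sw_score(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const int nl = S.nrow();
  const double gopen = gap_open + gap_extend;
  const double *s = S.begin();
  std::vector<double> M0(m + 1, 0.0), M1(m + 1, 0.0);
  std::vector<double> X0(m + 1, NEG), X1(m + 1, NEG);
  std::vector<double> Y0(m + 1, NEG), Y1(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    M1[0] = 0.0; X1[0] = NEG; Y1[0] = NEG;
    const double *srow = s + (size_t)a[i - 1];
    for (int j = 1; j <= m; ++j) {
      double diag = M0[j - 1];
      if (X0[j - 1] > diag) diag = X0[j - 1];
      if (Y0[j - 1] > diag) diag = Y0[j - 1];
      if (diag < 0.0) diag = 0.0;
      double mm = srow[(size_t)b[j - 1] * nl] + diag;
      M1[j] = mm;
      double x1 = M0[j] - gopen, x2 = X0[j] - gap_extend;
      X1[j] = x1 >= x2 ? x1 : x2;
      double y1 = M1[j - 1] - gopen, y2 = Y1[j - 1] - gap_extend;
      Y1[j] = y1 >= y2 ? y1 : y2;
      if (mm > best) best = mm;
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  return best;
}

// Full Smith-Waterman local alignment on integer-encoded sequences
// (0-based codes into the substitution matrix). Tie-break: the optimum with
// the smallest (end_i, end_j) lexicographically; traceback prefers
// stop > diag > up > left.
// [[Rcpp::export]]
List cpp_sw_affine(IntegerVector a, IntegerVector b, NumericMatrix S,
                   double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const int nl = S.nrow();
  const double gopen = gap_open + gap_extend;
  const double *s = S.begin();
  const size_t W = (size_t)m + 1;
  std::vector<double> M((n + 1) * W, 0.0), Ix((n + 1) * W, NEG),
      Iy((n + 1) * W, NEG);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const double *srow = s + (size_t)a[i - 1];
    double *Mi = &M[i * W], *Mp = &M[(i - 1) * W];
    double *Xi = &Ix[i * W], *Xp = &Ix[(i - 1) * W];
    double *Yi = &Iy[i * W];
    for (int j = 1; j <= m; ++j) {
      double diag = Mp[j - 1];
      if (Xp[j - 1] > diag) diag = Xp[j - 1];
      double ypd = Iy[(i - 1) * W + j - 1];
      if (ypd > diag) diag = ypd;
      if (diag < 0.0) diag = 0.0;
      double mm = srow[(size_t)b[j - 1] * nl] + diag;
      Mi[j] = mm;
      double x1 = Mp[j] - gopen, x2 = Xp[j] - gap_extend;
      Xi[j] = x1 >= x2 ? x1 : x2;
      double y1 = Mi[j - 1] - gopen, y2 = Yi[j - 1] - gap_extend;
      Yi[j] = y1 >= y2 ? y1 : y2;
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0,
                        _["q_start"] = 0, _["q_end"] = -1,
                        _["t_start"] = 0, _["t_end"] = -1,
                        _["a_path"] = IntegerVector(0),
                        _["b_path"] = IntegerVector(0));

  // traceback (states: 0 = M, 1 = Ix (gap in b), 2 = Iy (gap in a))
  std::vector<int> ai, bi_;
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      double here = M[i * W + j];
      double sub = s[(size_t)a[i - 1] + (size_t)b[j - 1] * nl];
      ai.push_back(i); bi_.push_back(j);
      double rem = here - sub;
      --i; --j;
      if (std::abs(rem) < 1e-9) break;                       // local start
      if (std::abs(rem - M[i * W + j]) < 1e-9 && M[i * W + j] > 0.0)
        state = 0;
      else if (std::abs(rem - Ix[i * W + j]) < 1e-9) state = 1;
      else if (std::abs(rem - Iy[i * W + j]) < 1e-9) state = 2;
      else break;
    } else if (state == 1) {
      ai.push_back(i); bi_.push_back(0);
      double here = Ix[i * W + j];
      if (std::abs(here - (M[(i - 1) * W + j] - gopen)) < 1e-9) state = 0;
      --i;
    } else {
      ai.push_back(0); bi_.push_back(j);
      double here = Iy[i * W + j];
      if (std::abs(here - (M[i * W + j - 1] - gopen)) < 1e-9) state = 0;
      --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi_.begin(), bi_.end());
  int qs = 0, ts = 0;
  for (size_t k = 0; k < ai.size(); ++k) if (ai[k] > 0) { qs = ai[k]; break; }
  for (size_t k = 0; k < bi_.size(); ++k) if (bi_[k] > 0) { ts = bi_[k]; break; }
  return List::create(_["score"] = best,
                      _["q_start"] = qs, _["q_end"] = bi,
                      _["t_start"] = ts, _["t_end"] = bj,
                      _["a_path"] = wrap(ai), _["b_path"] = wrap(bi_));
}

// Global affine (Gotoh) alignment over a precomputed column-score matrix.
// Used both for pairwise global alignment (scores = S[a_i, b_j]) and for
// profile-profile merges in the progressive aligner (scores = mean sum of
// pairs between columns). Returns the aligned column paths (0 = gap).
// Tie-break prefers diag > up > left, giving a deterministic alignment.
// [[Rcpp::export]]
List cpp_nw_affine(NumericMatrix colscore, double gap_open, double gap_extend) {
  const int n = colscore.nrow(), m = colscore.ncol();
  const double gopen = gap_open + gap_extend;
  const size_t W = (size_t)m + 1;
  std::vector<double> M((n + 1) * W, NEG), Ix((n + 1) * W, NEG),
      Iy((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) Ix[i * W] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Iy[j] = -(gap_open + j * gap_extend);
  const double *cs = colscore.begin();
  for (int i = 1; i <= n; ++i) {
    double *Mi = &M[i * W], *Mp = &M[(i - 1) * W];
    double *Xi = &Ix[i * W], *Xp = &Ix[(i - 1) * W];
    double *Yi = &Iy[i * W], *Yp = &Iy[(i - 1) * W];
    for (int j = 1; j <= m; ++j) {
      double diag = Mp[j - 1];
      if (Xp[j - 1] > diag) diag = Xp[j - 1];
      if (Yp[j - 1] > diag) diag = Yp[j - 1];
      Mi[j] = cs[(size_t)(i - 1) + (size_t)(j - 1) * n] + diag;
      double x1 = Mp[j] - gopen, x2 = Xp[j] - gap_extend,
             x3 = Yp[j] - gopen;
      Xi[j] = std::max(x1, std::max(x2, x3));
      double y1 = Mi[j - 1] - gopen, y2 = Yi[j - 1] - gap_extend,
             y3 = Xi[j - 1] - gopen;
      Yi[j] = std::max(y1, std::max(y2, y3));
    }
  }
  double fM = M[n * W + m], fX = Ix[n * W + m], fY = Iy[n * W + m];
  int state = 0; double score = fM;
  if (fX > score) { score = fX; state = 1; }
  if (fY > score) { score = fY; state = 2; }

  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { pa.push_back(0); pb.push_back(j); --j; continue; }
    if (j == 0) { pa.push_back(i); pb.push_back(0); --i; continue; }
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      double rem = M[i * W + j] - cs[(size_t)(i - 1) + (size_t)(j - 1) * n];
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(rem - M[i * W + j]) < 1e-9) state = 0;
      else if (std::abs(rem - Ix[i * W + j]) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      double here = Ix[i * W + j];
      if (std::abs(here - (M[(i - 1) * W + j] - gopen)) < 1e-9) state = 0;
      else if (std::abs(here - (Iy[(i - 1) * W + j] - gopen)) < 1e-9)
        state = 2;
      --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      double here = Iy[i * W + j];
      if (std::abs(here - (M[i * W + j - 1] - gopen)) < 1e-9) state = 0;
      else if (std::abs(here - (Ix[i * W + j - 1] - gopen)) < 1e-9)
        state = 1;
      --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["a_path"] = wrap(pa), _["b_path"] = wrap(pb));
}

// Pairwise p-distances with pairwise deletion over an integer-coded
// alignment matrix (rows = sequences, gap_code marks gaps).
// Returns the proportion-different matrix and the shared-column counts.
// [[Rcpp::export]]
List cpp_pdist(IntegerMatrix msa, int gap_code) {
  const int n = msa.nrow(), L = msa.ncol();
  NumericMatrix p(n, n);
  IntegerMatrix shared(n, n);
  // column-major copy per row for cache-friendly pair sweeps
  std::vector<int> rows((size_t)n * L);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < L; ++k) rows[(size_t)i * L + k] = msa(i, k);
  for (int i = 0; i < n; ++i) {
    const int *ri = &rows[(size_t)i * L];
    for (int j = i + 1; j < n; ++j) {
      const int *rj = &rows[(size_t)j * L];
      int ns = 0, nd = 0;
      for (int k = 0; k < L; ++k) {
        int x = ri[k], y = rj[k];
        if (x == gap_code || y == gap_code) continue;
        ++ns;
        if (x != y) ++nd;
      }
      shared(i, j) = ns; shared(j, i) = ns;
      double pd = ns > 0 ? (double)nd / ns : NA_REAL;
      p(i, j) = pd; p(j, i) = pd;
    }
  }
  return List::create(_["p"] = p, _["shared"] = shared);
}
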