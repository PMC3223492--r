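#include <Rcpp.h>
#include <vector>
#include <cfloat>
using namespace Rcpp;

// Affine-gap optimal pairwise alignment (Gotoh three-state DP).
//
// Gap cost convention: a gap of length g costs gop + gep * g, i.e. opening a
// gap charges gop + gep for its first position and gep for each further one.
// Global mode penalizes end gaps in full.
//
// States: 0 = M (residue/residue), 1 = X (s1 residue over gap in s2),
//         2 = Y (gap in s1 under s2 residue).
// Deterministic tie-breaking: M preferred over X, X over Y, both when taking
// maxima and during traceback.  In local mode, among co-optimal end cells the
// one with the lexicographically smallest (end_i, end_j) is kept.

static const double NEG_INF = -DBL_MAX / 4.0;

static inline int best3(double m, double x, double y, double &out) {
  // preference order M > X > Y on exact ties
  if (m >= x && m >= y) { out = m; return 0; }
  if (x >= y)           { out = x; return 1; }
  out = y; return 2;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector s1, IntegerVector s2, NumericMatrix sub,
                 double gop, double gep, bool local) {
  const int n1 = s1.size(), n2 = s2.size();
  const double open_ = gop + gep, ext = gep;
  const int W = n2 + 1;

  std::vector<double> M((n1 + 1) * W, NEG_INF), X(M), Y(M);
  // packed traceback: for each cell, per-state predecessor state (2 bits each)
  std::vector<unsigned char> ptrM(M.size(), 0), ptrX(M.size(), 0), ptrY(M.size(), 0);

  M[0] = 0.0;
  if (!local) {
    for (int i = 1; i <= n1; ++i) { X[i * W] = -(gop + gep * i); ptrX[i * W] = 1; }
    ptrX[W] = 0; // first gap position opens from M at origin
    for (int j = 1; j <= n2; ++j) { Y[j] = -(gop + gep * j); ptrY[j] = 2; }
    ptrY[1] = 0;
  } else {
    for (int i = 1; i <= n1; ++i) M[i * W] = 0.0; // local: fresh start anywhere
    for (int j = 1; j <= n2; ++j) M[j] = 0.0;
  }

  double best = local ? 0.0 : NEG_INF;
  int best_i = 0, best_j = 0, best_state = 0;

  for (int i = 1; i <= n1; ++i) {
    const int a = s1[i - 1];
    const double *subrow = &sub(a, 0); // column-major: use sub(a, b) below instead
    (void)subrow;
    for (int j = 1; j <= n2; ++j) {
      const int idx = i * W + j, up = idx - W, left = idx - 1, diag = up - 1;
      const int b = s2[j - 1];
      double sc;
      // M
      int st = best3(M[diag], X[diag], Y[diag], sc);
      if (local && sc <= 0.0) { sc = 0.0; st = 3; } // 3 = local start (fresh fragment)
      double m_here = sc + sub(a, b);
      M[idx] = m_here; ptrM[idx] = (unsigned char)st;
      // X: consume s1[i], gap in s2
      {
        double mo = M[up] - open_, xo = X[up] - ext, yo = Y[up] - open_;
        int stx = best3(mo, xo, yo, sc);
        X[idx] = sc; ptrX[idx] = (unsigned char)stx;
      }
      // Y: consume s2[j], gap in s1
      {
        double mo = M[left] - open_, xo = X[left] - open_, yo = Y[left] - ext;
        int sty = best3(mo, xo, yo, sc);
        Y[idx] = sc; ptrY[idx] = (unsigned char)sty;
      }
      if (local && M[idx] > best) { // strict > keeps smallest (i, j)
        best = M[idx]; best_i = i; best_j = j; best_state = 0;
      }
    }
  }

  double score;
  if (!local) {
    best_state = best3(M[n1 * W + n2], X[n1 * W + n2], Y[n1 * W + n2], score);
    best_i = n1; best_j = n2;
  } else {
    score = best;
  }

  // traceback
  std::vector<int> ci, cj;
  if (!(local && score <= 0.0)) {
    int i = best_i, j = best_j, state = best_state;
    while (i > 0 || j > 0) {
      if (!local && i == 0 && j == 0) break;
      const int idx = i * W + j;
      if (state == 0) {
        int prev = ptrM[idx];
        ci.push_back(i); cj.push_back(j);
        --i; --j;
        if (local && prev == 3) break; // local alignment start
        state = prev;
      } else if (state == 1) {
        int prev = ptrX[idx];
        ci.push_back(i); cj.push_back(NA_INTEGER);
        --i; state = prev;
      } else {
        int prev = ptrY[idx];
        ci.push_back(NA_INTEGER); cj.push_back(j);
        --j; state = prev;
      }
      if (local && i == 0 && j == 0) break;
    }
  }
  const int n = ci.size();
  IntegerVector oi(n), oj(n);
  for (int k = 0; k < n; ++k) { oi[k] = ci[n - 1 - k]; oj[k] = cj[n - 1 - k]; }
  if (local && score < 0.0) score = 0.0;
  return List::create(_["score"] = score, _["i"] = oi, _["j"] = oj);
}

// Iterated PAM1 substitution cycles on integer-coded residues (0-based codes).
// cum is the 20 x 20 row-wise cumulative transition matrix; each cycle
// resamples every position from the row of its current residue.  Uses R's RNG
// (one uniform per position per cycle) so results are reproducible under
// set.seed().
// [[Rcpp::export(name = ".mutate_cycles")]]
IntegerVector mutate_cycles(IntegerVector s, NumericMatrix cum, int cycles) {
  const int L = s.size(), K = cum.ncol();
  IntegerVector out = clone(s);
  for (int c = 0; c < cycles; ++c) {
    for (int p = 0; p < L; ++p) {
      const double u = unif_rand();
      const int row = out[p];
      int k = 0;
      while (k < K - 1 && u > cum(row, k)) ++k;
      out[p] = k;
    }
  }
  return out;
}
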