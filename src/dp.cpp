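#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming (Gotoh, three-state). A gap of length k
// costs open + k * ext. States: M (residue pair), Ix (residue of a vs gap),
// Iy (gap vs residue of b). With end_gaps = false, terminal gap runs in
// either sequence are free (semi-global scoring).

static const double NEG = -1e30;

static inline double max3(double x, double y, double z) {
  return std::max(x, std::max(y, z));
}

// [[Rcpp::export]]
List nw_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                 double open, double ext, bool end_gaps) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);

  M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = end_gaps ? -(open + i * ext) : 0.0;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = end_gaps ? -(open + j * ext) : 0.0;
  }

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      M(i, j) = S(ai, b[j - 1] - 1) +
        max3(M(i - 1, j - 1), Ix(i - 1, j - 1), Iy(i - 1, j - 1));
      Ix(i, j) = std::max(std::max(M(i - 1, j), Iy(i - 1, j)) - open - ext,
                          Ix(i - 1, j) - ext);
      Iy(i, j) = std::max(std::max(M(i, j - 1), Ix(i, j - 1)) - open - ext,
                          Iy(i, j - 1) - ext);
    }
  }

  // locate the traceback start (free ends: best over last row/column)
  int bi0 = n, bj0 = m;
  double best = max3(M(n, m), Ix(n, m), Iy(n, m));
  if (!end_gaps) {
    for (int i = 0; i <= n; ++i) {
      double v = max3(M(i, m), Ix(i, m), Iy(i, m));
      if (v > best + 1e-12) { best = v; bi0 = i; bj0 = m; }
    }
    for (int j = 0; j <= m; ++j) {
      double v = max3(M(n, j), Ix(n, j), Iy(n, j));
      if (v > best + 1e-12) { best = v; bi0 = n; bj0 = j; }
    }
  }

  std::vector<int> outa, outb;
  // free trailing gaps
  for (int i = n; i > bi0; --i) { outa.push_back(i); outb.push_back(0); }
  for (int j = m; j > bj0; --j) { outa.push_back(0); outb.push_back(j); }

  int i = bi0, j = bj0;
  int state; // 0 = M, 1 = Ix, 2 = Iy
  {
    double vm = M(i, j), vx = Ix(i, j), vy = Iy(i, j);
    state = (vm >= vx && vm >= vy) ? 0 : (vx >= vy ? 1 : 2);
  }
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) { outa.push_back(0); outb.push_back(j); --j; continue; }
    if (j == 0) { outa.push_back(i); outb.push_back(0); --i; continue; }
    if (state == 0) {
      outa.push_back(i); outb.push_back(j);
      double need = M(i, j) - S(a[i - 1] - 1, b[j - 1] - 1);
      --i; --j;
      if (std::abs(need - M(i, j)) < eps) state = 0;
      else if (std::abs(need - Ix(i, j)) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      outa.push_back(i); outb.push_back(0);
      double v = Ix(i, j);
      if (std::abs(v - (Ix(i - 1, j) - ext)) < eps) state = 1;
      else if (std::abs(v - (M(i - 1, j) - open - ext)) < eps) state = 0;
      else state = 2;
      --i;
    } else {
      outa.push_back(0); outb.push_back(j);
      double v = Iy(i, j);
      if (std::abs(v - (Iy(i, j - 1) - ext)) < eps) state = 2;
      else if (std::abs(v - (M(i, j - 1) - open - ext)) < eps) state = 0;
      else state = 1;
      --j;
    }
  }
  std::reverse(outa.begin(), outa.end());
  std::reverse(outb.begin(), outb.end());
  return List::create(_["score"] = best,
                      _["ai"] = wrap(outa), _["bi"] = wrap(outb));
}

// Profile-profile alignment. SA(r, i) = sum_a S(r, a) * freqA(a, i), so the
// expected substitution score of columns (i, j) is dot(SA[, i], B[, j]).
// End gaps are always penalized (profiles come from complete alignments).
// [[Rcpp::export]]
List nw_profile_cpp(NumericMatrix SA, NumericMatrix B,
                    double open, double ext) {
  const int n = SA.ncol(), m = B.ncol(), R = SA.nrow();
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  NumericMatrix sc(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int r = 0; r < R; ++r) s += SA(r, i) * B(r, j);
      sc(i, j) = s;
    }

  M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG; Ix(i, 0) = -(open + i * ext);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG; Iy(0, j) = -(open + j * ext);
  }
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      M(i, j) = sc(i - 1, j - 1) +
        max3(M(i - 1, j - 1), Ix(i - 1, j - 1), Iy(i - 1, j - 1));
      Ix(i, j) = std::max(std::max(M(i - 1, j), Iy(i - 1, j)) - open - ext,
                          Ix(i - 1, j) - ext);
      Iy(i, j) = std::max(std::max(M(i, j - 1), Ix(i, j - 1)) - open - ext,
                          Iy(i, j - 1) - ext);
    }

  int i = n, j = m, state;
  {
    double vm = M(i, j), vx = Ix(i, j), vy = Iy(i, j);
    state = (vm >= vx && vm >= vy) ? 0 : (vx >= vy ? 1 : 2);
  }
  double best = max3(M(n, m), Ix(n, m), Iy(n, m));
  std::vector<bool> gapA, gapB;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) { gapA.push_back(true); gapB.push_back(false); --j; continue; }
    if (j == 0) { gapA.push_back(false); gapB.push_back(true); --i; continue; }
    if (state == 0) {
      gapA.push_back(false); gapB.push_back(false);
      double need = M(i, j) - sc(i - 1, j - 1);
      --i; --j;
      if (std::abs(need - M(i, j)) < eps) state = 0;
      else if (std::abs(need - Ix(i, j)) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      gapA.push_back(false); gapB.push_back(true);
      double v = Ix(i, j);
      if (std::abs(v - (Ix(i - 1, j) - ext)) < eps) state = 1;
      else if (std::abs(v - (M(i - 1, j) - open - ext)) < eps) state = 0;
      else state = 2;
      --i;
    } else {
      gapA.push_back(true); gapB.push_back(false);
      double v = Iy(i, j);
      if (std::abs(v - (Iy(i, j - 1) - ext)) < eps) state = 2;
      else if (std::abs(v - (M(i, j - 1) - open - ext)) < eps) state = 0;
      else state = 1;
      --j;
    }
  }
  std::reverse(gapA.begin(), gapA.end());
  std::reverse(gapB.begin(), gapB.end());
  return List::create(_["score"] = best,
                      _["gapA"] = wrap(gapA), _["gapB"] = wrap(gapB));
}

// Pairwise mismatch fractions with pairwise deletion. Codes <= 0 are
// missing (gap or unknown) and excluded from both numerator and overlap.
// [[Rcpp::export]]
List pdist_cpp(IntegerMatrix X) {
  const int n = X.nrow(), L = X.ncol();
  NumericMatrix p(n, n);
  IntegerMatrix ov(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int mism = 0, tot = 0;
      for (int s = 0; s < L; ++s) {
        int xi = X(i, s), xj = X(j, s);
        if (xi > 0 && xj > 0) { ++tot; if (xi != xj) ++mism; }
      }
      double d = tot > 0 ? (double)mism / tot : NA_REAL;
      p(i, j) = d; p(j, i) = d;
      ov(i, j) = tot; ov(j, i) = tot;
    }
  return List::create(_["p"] = p, _["n"] = ov);
}
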