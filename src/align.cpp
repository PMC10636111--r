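#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment of two alignment profiles (rows A,C,G,T,gap as
// column frequencies). Column score is the expected substitution score over
// base pairs; positions opposite an existing profile gap contribute 0. Gap
// costs are affine: the first gap column costs gap_open, each further column
// gap_extend. Ties are broken deterministically: diagonal, then a gap in the
// second profile, then a gap in the first (encoded in the order of the
// max comparisons below, using strict > for later alternatives).
//
// Returns the edit path from the start of both profiles: 0 = column from
// both, 1 = column from profile 1 only (gap inserted in profile 2),
// 2 = column from profile 2 only.
// [[Rcpp::export(name = ".align_profiles")]]
IntegerVector align_profiles_cpp(NumericMatrix p1, NumericMatrix p2,
                                 double match, double mismatch,
                                 double gap_open, double gap_extend) {
  const int L1 = p1.ncol(), L2 = p2.ncol();
  const double NEG = -1e30;

  // column-pair substitution scores
  NumericMatrix s(L1, L2);
  for (int i = 0; i < L1; ++i)
    for (int j = 0; j < L2; ++j) {
      double v = 0.0;
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          v += p1(a, i) * p2(b, j) * (a == b ? match : mismatch);
      s(i, j) = v;
    }

  const int W = L2 + 1;
  std::vector<double> M((L1 + 1) * W, NEG), X((L1 + 1) * W, NEG),
      Y((L1 + 1) * W, NEG);
  // predecessor state (0 = M, 1 = X, 2 = Y) for each matrix cell
  std::vector<signed char> fromM((L1 + 1) * W, -1), fromX((L1 + 1) * W, -1),
      fromY((L1 + 1) * W, -1);
  auto idx = [W](int i, int j) { return i * W + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= L1; ++i) {
    X[idx(i, 0)] = gap_open + (i - 1) * gap_extend;
    fromX[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= L2; ++j) {
    Y[idx(0, j)] = gap_open + (j - 1) * gap_extend;
    fromY[idx(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= L1; ++i) {
    for (int j = 1; j <= L2; ++j) {
      const int c = idx(i, j), dg = idx(i - 1, j - 1), up = idx(i - 1, j),
                lf = idx(i, j - 1);
      // M: prefer diagonal-from-M, then X, then Y
      double best = M[dg]; signed char st = 0;
      if (X[dg] > best) { best = X[dg]; st = 1; }
      if (Y[dg] > best) { best = Y[dg]; st = 2; }
      M[c] = best + s(i - 1, j - 1);
      fromM[c] = st;
      // X (gap in profile 2): from M (open), X (extend), Y (open)
      best = M[up] + gap_open; st = 0;
      if (X[up] + gap_extend > best) { best = X[up] + gap_extend; st = 1; }
      if (Y[up] + gap_open > best) { best = Y[up] + gap_open; st = 2; }
      X[c] = best;
      fromX[c] = st;
      // Y (gap in profile 1): from M (open), Y (extend), X (open)
      best = M[lf] + gap_open; st = 0;
      if (Y[lf] + gap_extend > best) { best = Y[lf] + gap_extend; st = 2; }
      if (X[lf] + gap_open > best) { best = X[lf] + gap_open; st = 1; }
      Y[c] = best;
      fromY[c] = st;
    }
  }

  std::vector<int> path;
  int i = L1, j = L2;
  const int e = idx(i, j);
  int state = 0;
  {
    double best = M[e];
    if (X[e] > best) { best = X[e]; state = 1; }
    if (Y[e] > best) { best = Y[e]; state = 2; }
  }
  while (i > 0 || j > 0) {
    const int c = idx(i, j);
    if (state == 0) {
      path.push_back(0);
      state = fromM[c];
      --i; --j;
    } else if (state == 1) {
      path.push_back(1);
      state = fromX[c];
      --i;
    } else {
      path.push_back(2);
      state = fromY[c];
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}
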