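#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment raw score, affine gaps.
// a, b: 1-based residue indices into sub; a gap of length g costs open + g*ext.
// [[Rcpp::export]]
double sw_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                double open, double ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0), Fcol(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double E = NEG;
    Hcur[0] = 0.0;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hcur[j - 1] - open - ext, E - ext);
      Fcol[j] = std::max(Hprev[j] - open - ext, Fcol[j] - ext);
      double h = Hprev[j - 1] + sub(ai, b[j - 1] - 1);
      h = std::max(h, std::max(E, Fcol[j]));
      h = std::max(h, 0.0);
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// All-vs-all Smith-Waterman raw scores for a list of encoded proteins.
// Returns an upper-triangle matrix (i<j) of raw scores.
// [[Rcpp::export]]
NumericMatrix sw_all(List seqs, NumericMatrix sub, double open, double ext) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> enc(n);
  for (int i = 0; i < n; ++i) enc[i] = as<IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = sw_score(enc[i], enc[j], sub, open, ext);
      out(i, j) = s;
      out(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Global profile-profile Needleman-Wunsch with affine gaps.
// fa, fb: nres x L column frequency matrices (gap mass omitted so columns may
// sum to < 1). Column pair score = fa(.,i)' * sub * fb(.,j).
// Returns the move sequence from the start: 1 = both, 2 = column of A only
// (gap inserted in B), 3 = column of B only (gap in A).
// Ties broken diagonal > up > left for determinism.
// [[Rcpp::export]]
IntegerVector nw_profile(NumericMatrix fa, NumericMatrix fb, NumericMatrix sub,
                         double open, double ext) {
  const int La = fa.ncol(), Lb = fb.ncol(), R = sub.nrow();
  const double NEG = -1e30;
  // precompute column-pair scores: tmp = sub * fb, S(i,j) = fa(.,i) . tmp(.,j)
  NumericMatrix tmp(R, Lb);
  for (int j = 0; j < Lb; ++j)
    for (int r = 0; r < R; ++r) {
      double s = 0.0;
      for (int q = 0; q < R; ++q) s += sub(r, q) * fb(q, j);
      tmp(r, j) = s;
    }
  NumericMatrix S(La, Lb);
  for (int i = 0; i < La; ++i)
    for (int j = 0; j < Lb; ++j) {
      double s = 0.0;
      for (int r = 0; r < R; ++r) s += fa(r, i) * tmp(r, j);
      S(i, j) = s;
    }
  // M: align i,j; X: gap in B (consume A); Y: gap in A (consume B)
  std::vector<std::vector<double>> M(La + 1, std::vector<double>(Lb + 1, NEG)),
      X(La + 1, std::vector<double>(Lb + 1, NEG)),
      Y(La + 1, std::vector<double>(Lb + 1, NEG));
  // traceback: which layer each cell's best predecessor came from (0=M,1=X,2=Y)
  std::vector<std::vector<signed char>> tbM(La + 1, std::vector<signed char>(Lb + 1, -1)),
      tbX(La + 1, std::vector<signed char>(Lb + 1, -1)),
      tbY(La + 1, std::vector<signed char>(Lb + 1, -1));
  M[0][0] = 0.0;
  for (int i = 1; i <= La; ++i) {
    X[i][0] = -open - ext * i;
    tbX[i][0] = 1;
  }
  for (int j = 1; j <= Lb; ++j) {
    Y[0][j] = -open - ext * j;
    tbY[0][j] = 2;
  }
  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      // M
      double bm = M[i - 1][j - 1];
      signed char wm = 0;
      if (X[i - 1][j - 1] > bm) { bm = X[i - 1][j - 1]; wm = 1; }
      if (Y[i - 1][j - 1] > bm) { bm = Y[i - 1][j - 1]; wm = 2; }
      M[i][j] = bm + S(i - 1, j - 1);
      tbM[i][j] = wm;
      // X: consume A column i
      double bx = M[i - 1][j] - open - ext;
      signed char wx = 0;
      if (X[i - 1][j] - ext > bx) { bx = X[i - 1][j] - ext; wx = 1; }
      X[i][j] = bx;
      tbX[i][j] = wx;
      // Y: consume B column j
      double by = M[i][j - 1] - open - ext;
      signed char wy = 0;
      if (Y[i][j - 1] - ext > by) { by = Y[i][j - 1] - ext; wy = 2; }
      Y[i][j] = by;
      tbY[i][j] = wy;
    }
  }
  // pick end layer: M > X > Y on ties
  int layer = 0;
  double bestEnd = M[La][Lb];
  if (X[La][Lb] > bestEnd) { bestEnd = X[La][Lb]; layer = 1; }
  if (Y[La][Lb] > bestEnd) { bestEnd = Y[La][Lb]; layer = 2; }
  std::vector<int> moves;
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    if (layer == 0) {
      signed char w = tbM[i][j];
      moves.push_back(1);
      --i; --j;
      layer = w;
    } else if (layer == 1) {
      signed char w = tbX[i][j];
      moves.push_back(2);
      --i;
      layer = w;
    } else {
      signed char w = tbY[i][j];
      moves.push_back(3);
      --j;
      layer = w;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return wrap(moves);
}
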