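#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment over an arbitrary pair-score matrix S (n x m), where
// S(i-1, j-1) is the score for pairing row-unit i with column-unit j.  Used
// for sequence-vs-sequence (S built from a substitution matrix),
// profile-vs-sequence (S built from PSSM columns) and sequence-vs-profile
// alignments alike.  A gap of length L costs gap_open + L * gap_extend.
//
// local = true  : Smith-Waterman semantics (best-scoring pair of substrings)
// local = false : Needleman-Wunsch global with end gaps charged
//
// Deterministic tie-breaks: predecessor preference diagonal (M), then up
// (gap in column sequence, consuming a row), then left; for local mode the
// best cell is the first maximal M cell in row-major order.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List align_dp_cpp(NumericMatrix S, double gap_open, double gap_extend,
                  bool local, bool traceback) {
  const int n = S.nrow(), m = S.ncol();
  const double open_cost = gap_open + gap_extend;

  // state matrices, (n+1) x (m+1)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // pointers: for M 0=start,1=M,2=X,3=Y ; for X/Y 1=M,2=X,3=Y
  IntegerMatrix PM, PX, PY;
  if (traceback) {
    PM = IntegerMatrix(n + 1, m + 1);
    PX = IntegerMatrix(n + 1, m + 1);
    PY = IntegerMatrix(n + 1, m + 1);
  }

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) {
      M(i, j) = NEG_INF; X(i, j) = NEG_INF; Y(i, j) = NEG_INF;
    }
  M(0, 0) = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) X(i, 0) = -(gap_open + i * gap_extend);
    for (int j = 1; j <= m; ++j) Y(0, j) = -(gap_open + j * gap_extend);
    if (traceback) {
      for (int i = 2; i <= n; ++i) PX(i, 0) = 2;
      if (n >= 1) PX(1, 0) = 1;
      for (int j = 2; j <= m; ++j) PY(0, j) = 3;
      if (m >= 1) PY(0, 1) = 1;
    }
  }

  double best = 0.0; int bi = 0, bj = 0;  // local best (empty alignment = 0)

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: pair i with j
      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double prev = dM; int ptr = 1;
      if (dX > prev) { prev = dX; ptr = 2; }
      if (dY > prev) { prev = dY; ptr = 3; }
      if (local && 0.0 > prev) { prev = 0.0; ptr = 0; }
      if (prev > NEG_INF / 2) {
        M(i, j) = prev + S(i - 1, j - 1);
        if (traceback) PM(i, j) = ptr;
      }
      // X: consume row-unit i against a gap ("up")
      double xM = M(i - 1, j) - open_cost, xX = X(i - 1, j) - gap_extend,
             xY = Y(i - 1, j) - open_cost;
      double xv = xM; int xp = 1;
      if (xX > xv) { xv = xX; xp = 2; }
      if (xY > xv) { xv = xY; xp = 3; }
      if (xv > NEG_INF / 2) { X(i, j) = xv; if (traceback) PX(i, j) = xp; }
      // Y: consume column-unit j against a gap ("left")
      double yM = M(i, j - 1) - open_cost, yX = X(i, j - 1) - open_cost,
             yY = Y(i, j - 1) - gap_extend;
      double yv = yM; int yp = 1;
      if (yX > yv) { yv = yX; yp = 2; }
      if (yY > yv) { yv = yY; yp = 3; }
      if (yv > NEG_INF / 2) { Y(i, j) = yv; if (traceback) PY(i, j) = yp; }

      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  double score;
  int state;  // 1=M,2=X,3=Y
  int ei, ej;
  if (local) {
    score = best; state = 1; ei = bi; ej = bj;
  } else {
    double vM = M(n, m), vX = X(n, m), vY = Y(n, m);
    score = vM; state = 1;
    if (vX > score) { score = vX; state = 2; }
    if (vY > score) { score = vY; state = 3; }
    ei = n; ej = m;
  }

  if (!traceback || (local && best <= 0.0)) {
    return List::create(_["score"] = score,
                        _["a_idx"] = IntegerVector(0),
                        _["b_idx"] = IntegerVector(0));
  }

  std::vector<int> ai, bj_;
  int i = ei, j = ej, st = state;
  while (true) {
    if (st == 1) {
      if (i == 0 && j == 0) break;
      int p = PM(i, j);
      ai.push_back(i); bj_.push_back(j);
      --i; --j;
      if (local && p == 0) break;
      st = (p == 0) ? 1 : p;
      if (i == 0 && j == 0) break;
    } else if (st == 2) {
      int p = PX(i, j);
      ai.push_back(i); bj_.push_back(0);
      --i;
      st = p;
      if (i == 0 && j == 0) break;
    } else {
      int p = PY(i, j);
      ai.push_back(0); bj_.push_back(j);
      --j;
      st = p;
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj_.begin(), bj_.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bj_));
}
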