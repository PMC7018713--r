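#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment with affine gap costs.
//
// A gap of length L costs gap_open + (L - 1) * gap_extend, with
// gap_open <= gap_extend <= 0.  Three-state recursion (M = residues aligned,
// X = gap in b / vertical, Y = gap in a / horizontal).  Ties are broken
// deterministically: M over X over Y, i.e. prefer diagonal, then up.

static const double NEG_INF = -1e18;

struct TB {
  // trace[state][i][j] = previous state (0 = M, 1 = X, 2 = Y)
  std::vector<signed char> m, x, y;
  int cols;
  TB(int n, int mcols) : m((n + 1) * (mcols + 1)), x((n + 1) * (mcols + 1)),
                         y((n + 1) * (mcols + 1)), cols(mcols + 1) {}
  signed char &at(int state, int i, int j) {
    switch (state) {
    case 0: return m[i * cols + j];
    case 1: return x[i * cols + j];
    default: return y[i * cols + j];
    }
  }
};

// Core DP over a precomputed cell-score matrix sc (n x m, sc(i-1, j-1) is the
// score for aligning unit i of a with unit j of b).  Returns the aligned unit
// indices (1-based, 0 = gap) via out_a / out_b, and the optimal score.
static double gotoh_core(const NumericMatrix &sc, double go, double ge,
                         std::vector<int> &out_a, std::vector<int> &out_b) {
  const int n = sc.nrow(), m = sc.ncol();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  TB tb(n, m);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    Y(i, 0) = NEG_INF;
    X(i, 0) = go + (i - 1) * ge;
    tb.at(1, i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = go + (j - 1) * ge;
    tb.at(2, 0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: prefer M, then X, then Y on ties
      double best = M(i - 1, j - 1);
      signed char src = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); src = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); src = 2; }
      M(i, j) = best + sc(i - 1, j - 1);
      tb.at(0, i, j) = src;

      // X: vertical gap (consume a_i, gap in b)
      best = M(i - 1, j) + go; src = 0;
      if (X(i - 1, j) + ge > best) { best = X(i - 1, j) + ge; src = 1; }
      if (Y(i - 1, j) + go > best) { best = Y(i - 1, j) + go; src = 2; }
      X(i, j) = best;
      tb.at(1, i, j) = src;

      // Y: horizontal gap (consume b_j, gap in a)
      best = M(i, j - 1) + go; src = 0;
      if (X(i, j - 1) + go > best) { best = X(i, j - 1) + go; src = 1; }
      if (Y(i, j - 1) + ge > best) { best = Y(i, j - 1) + ge; src = 2; }
      Y(i, j) = best;
      tb.at(2, i, j) = src;
    }
  }

  double score = M(n, m);
  int state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  int i = n, j = m;
  std::vector<int> ra, rb;
  while (i > 0 || j > 0) {
    signed char prev = tb.at(state, i, j);
    if (state == 0) {
      ra.push_back(i); rb.push_back(j); --i; --j;
    } else if (state == 1) {
      ra.push_back(i); rb.push_back(0); --i;
    } else {
      ra.push_back(0); rb.push_back(j); --j;
    }
    state = prev;
  }
  out_a.assign(ra.rbegin(), ra.rend());
  out_b.assign(rb.rbegin(), rb.rend());
  return score;
}

//' @noRd
// [[Rcpp::export(name = ".gotoh_pair")]]
List gotoh_pair(IntegerVector a, IntegerVector b, NumericMatrix S,
                double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  NumericMatrix sc(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      sc(i, j) = S(a[i] - 1, b[j] - 1);
  std::vector<int> ia, ib;
  double score = gotoh_core(sc, gap_open, gap_extend, ia, ib);
  return List::create(_["score"] = score,
                      _["a"] = IntegerVector(ia.begin(), ia.end()),
                      _["b"] = IntegerVector(ib.begin(), ib.end()));
}

//' @noRd
// [[Rcpp::export(name = ".gotoh_profile")]]
List gotoh_profile(NumericMatrix FA, NumericMatrix FB, NumericMatrix S13,
                   double gap_open, double gap_extend) {
  // FA: LA x 13 column letter frequencies (letters 1..12, 13 = gap);
  // cell score = fA' S13 fB.
  const int n = FA.nrow(), m = FB.nrow(), K = FA.ncol();
  // Precompute PA = FA * S13  (n x 13)
  NumericMatrix PA(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int l = 0; l < K; ++l) s += FA(i, l) * S13(l, k);
      PA(i, k) = s;
    }
  NumericMatrix sc(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += PA(i, k) * FB(j, k);
      sc(i, j) = s;
    }
  std::vector<int> ia, ib;
  double score = gotoh_core(sc, gap_open, gap_extend, ia, ib);
  return List::create(_["score"] = score,
                      _["a"] = IntegerVector(ia.begin(), ia.end()),
                      _["b"] = IntegerVector(ib.begin(), ib.end()));
}
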