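#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming over a precomputed column-pair score matrix.
// Gap cost: open + extend charged on the first gap residue, extend thereafter.
// Three-state DP (M = match/mismatch, X = gap in columns ("up"), Y = gap in
// rows ("left")); traceback ties broken diagonal > up > left, and gap openings
// preferred over extensions so gaps close as early as possible.
//
// S[i][j] scores pairing row-position i with column-position j (1-based on the
// R side). local = TRUE gives Smith-Waterman (floor at 0, best-cell start);
// local = FALSE gives Needleman-Wunsch with end gaps charged.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".dp_align_cpp")]]
List dp_align_cpp(NumericMatrix S, double gap_open, double gap_extend,
                  bool local) {
  const int n = S.nrow(), m = S.ncol();
  const double g1 = gap_open + gap_extend;  // first gap residue
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG_INF; X(i, j) = NEG_INF; Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = local ? 0.0 : -(g1 + (i - 1) * gap_extend);
  for (int j = 1; j <= m; ++j) Y(0, j) = local ? 0.0 : -(g1 + (j - 1) * gap_extend);
  if (local) {
    for (int i = 1; i <= n; ++i) M(i, 0) = 0.0;
    for (int j = 1; j <= m; ++j) M(0, j) = 0.0;
  }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      double d = dm; if (dx > d) d = dx; if (dy > d) d = dy;
      if (local && d < 0.0) d = 0.0;
      M(i, j) = (d <= NEG_INF / 2) ? NEG_INF : d + S(i - 1, j - 1);
      double xo = M(i - 1, j) - g1, xe = X(i - 1, j) - gap_extend;
      X(i, j) = xo >= xe ? xo : xe;
      double yo = M(i, j - 1) - g1, ye = Y(i, j - 1) - gap_extend;
      Y(i, j) = yo >= ye ? yo : ye;
      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  std::vector<int> ai, aj;  // 1-based indices, 0 = gap
  int i, j, state;  // 0 = M, 1 = X (up), 2 = Y (left)
  double score;

  if (local) {
    score = best;
    if (best <= 0.0) {
      return List::create(_["score"] = 0.0,
                          _["a"] = IntegerVector(0), _["b"] = IntegerVector(0),
                          _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
                          _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER);
    }
    i = bi; j = bj; state = 0;  // local optimum always ends in a match state
    while (i > 0 && j > 0) {
      if (state == 0) {
        ai.push_back(i); aj.push_back(j);
        double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
        double d = dm; if (dx > d) d = dx; if (dy > d) d = dy;
        if (d <= 0.0) { --i; --j; break; }  // alignment starts here
        if (dm >= dx && dm >= dy) state = 0;
        else if (dx >= dy) state = 1;
        else state = 2;
        --i; --j;
      } else if (state == 1) {
        ai.push_back(i); aj.push_back(0);
        state = (M(i - 1, j) - g1 >= X(i - 1, j) - gap_extend) ? 0 : 1;
        --i;
      } else {
        ai.push_back(0); aj.push_back(j);
        state = (M(i, j - 1) - g1 >= Y(i, j - 1) - gap_extend) ? 0 : 2;
        --j;
      }
    }
  } else {
    double sm = M(n, m), sx = X(n, m), sy = Y(n, m);
    score = sm; state = 0;
    if (sx > score) { score = sx; state = 1; }
    if (sy > score) { score = sy; state = 2; }
    i = n; j = m;
    while (i > 0 || j > 0) {
      if (i == 0) { ai.push_back(0); aj.push_back(j); --j; continue; }
      if (j == 0) { ai.push_back(i); aj.push_back(0); --i; continue; }
      if (state == 0) {
        ai.push_back(i); aj.push_back(j);
        double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
        if (dm >= dx && dm >= dy) state = 0;
        else if (dx >= dy) state = 1;
        else state = 2;
        --i; --j;
      } else if (state == 1) {
        ai.push_back(i); aj.push_back(0);
        state = (M(i - 1, j) - g1 >= X(i - 1, j) - gap_extend) ? 0 : 1;
        --i;
      } else {
        ai.push_back(0); aj.push_back(j);
        state = (M(i, j - 1) - g1 >= Y(i, j - 1) - gap_extend) ? 0 : 2;
        --j;
      }
    }
  }

  std::reverse(ai.begin(), ai.end());
  std::reverse(aj.begin(), aj.end());
  IntegerVector av(ai.begin(), ai.end()), bv(aj.begin(), aj.end());
  int as = NA_INTEGER, ae = NA_INTEGER, bs = NA_INTEGER, be = NA_INTEGER;
  for (int k = 0; k < av.size(); ++k) {
    if (av[k] > 0) { if (as == NA_INTEGER) as = av[k]; ae = av[k]; }
    if (bv[k] > 0) { if (bs == NA_INTEGER) bs = bv[k]; be = bv[k]; }
  }
  return List::create(_["score"] = score, _["a"] = av, _["b"] = bv,
                      _["a_start"] = as, _["a_end"] = ae,
                      _["b_start"] = bs, _["b_end"] = be);
}
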