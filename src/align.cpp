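#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) over a precomputed position-score
// matrix S (n x m): S(i, j) is the score for matching position i of the
// first object with position j of the second.  A gap of length k scores
// gap_open + k * gap_extend; both penalties must be <= 0.
//
// Three states: M (match, "diagonal"), Ix (gap in the second object,
// consumes the first, "up"), Iy (gap in the first, "left").  Ties in the
// traceback prefer M > Ix > Iy so output is deterministic.
//
// local = true gives Smith-Waterman-style local alignment: paths start and
// end on a match state and the score is floored at 0 (empty alignment).

static const double NEG_INF = -1e100;

// [[Rcpp::export]]
List align_dp_cpp(NumericMatrix S, double gap_open, double gap_extend,
                  bool local) {
  const int n = S.nrow(), m = S.ncol();
  if (n < 1 || m < 1) stop("alignment requires non-empty inputs");

  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), Ix((n + 1) * W, NEG_INF),
      Iy((n + 1) * W, NEG_INF);
  // predecessor state per cell: 0 = M, 1 = Ix, 2 = Iy, 3 = start
  std::vector<signed char> pM((n + 1) * W, -1), pIx((n + 1) * W, -1),
      pIy((n + 1) * W, -1);

#define AT(i, j) ((i) * W + (j))

  M[AT(0, 0)] = 0.0;
  pM[AT(0, 0)] = 3;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      Ix[AT(i, 0)] = gap_open + i * gap_extend;
      pIx[AT(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Iy[AT(0, j)] = gap_open + j * gap_extend;
      pIy[AT(0, j)] = (j == 1) ? 0 : 2;
    }
  }

  double best_local = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: match i with j, preceded by any state at (i-1, j-1)
      double dM = M[AT(i - 1, j - 1)], dIx = Ix[AT(i - 1, j - 1)],
             dIy = Iy[AT(i - 1, j - 1)];
      double prev = dM;
      signed char ptr = 0;
      if (dIx > prev) { prev = dIx; ptr = 1; }
      if (dIy > prev) { prev = dIy; ptr = 2; }
      if (local && prev <= 0.0) { prev = 0.0; ptr = 3; }
      if (prev > NEG_INF / 2) {
        M[AT(i, j)] = prev + S(i - 1, j - 1);
        pM[AT(i, j)] = ptr;
      }

      // Ix: consume position i of the first object (gap in the second)
      double oM = M[AT(i - 1, j)] + gap_open + gap_extend;
      double oIx = Ix[AT(i - 1, j)] + gap_extend;
      double oIy = Iy[AT(i - 1, j)] + gap_open + gap_extend;
      double bx = oM;
      signed char px = 0;
      if (oIx > bx) { bx = oIx; px = 1; }
      if (oIy > bx) { bx = oIy; px = 2; }
      if (bx > NEG_INF / 2) { Ix[AT(i, j)] = bx; pIx[AT(i, j)] = px; }

      // Iy: consume position j of the second object (gap in the first)
      double lM = M[AT(i, j - 1)] + gap_open + gap_extend;
      double lIx = Ix[AT(i, j - 1)] + gap_open + gap_extend;
      double lIy = Iy[AT(i, j - 1)] + gap_extend;
      double by = lM;
      signed char py = 0;
      if (lIx > by) { by = lIx; py = 1; }
      if (lIy > by) { by = lIy; py = 2; }
      if (by > NEG_INF / 2) { Iy[AT(i, j)] = by; pIy[AT(i, j)] = py; }

      if (local && M[AT(i, j)] > best_local) {
        best_local = M[AT(i, j)];
        best_i = i;
        best_j = j;
      }
    }
  }

  double score;
  int ci, cj, cs;  // current cell and state
  std::vector<std::pair<int, int> > pairs;

  if (local) {
    score = best_local;
    if (best_i == 0) {  // empty local alignment
      IntegerMatrix ap(0, 2);
      return List::create(_["score"] = 0.0, _["pairs"] = ap);
    }
    ci = best_i; cj = best_j; cs = 0;
  } else {
    double sM = M[AT(n, m)], sIx = Ix[AT(n, m)], sIy = Iy[AT(n, m)];
    score = sM; cs = 0;
    if (sIx > score) { score = sIx; cs = 1; }
    if (sIy > score) { score = sIy; cs = 2; }
    ci = n; cj = m;
  }

  // traceback
  while (true) {
    if (cs == 0) {
      if (ci == 0 && cj == 0) break;  // global start corner
      pairs.push_back(std::make_pair(ci - 1, cj - 1));
      signed char p = pM[AT(ci, cj)];
      if (p == 3) break;  // local start
      ci -= 1; cj -= 1; cs = p;
    } else if (cs == 1) {
      signed char p = pIx[AT(ci, cj)];
      ci -= 1; cs = p;
    } else {
      signed char p = pIy[AT(ci, cj)];
      cj -= 1; cs = p;
    }
  }

  const int k = (int)pairs.size();
  IntegerMatrix ap(k, 2);
  for (int r = 0; r < k; ++r) {
    ap(r, 0) = pairs[k - 1 - r].first;   // 0-based, increasing
    ap(r, 1) = pairs[k - 1 - r].second;
  }
  return List::create(_["score"] = score, _["pairs"] = ap);
}
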