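// Affine-gap pairwise alignment DPs (local and global).
//
// Conventions shared with the R level and the test oracle:
//  - gap_open and gap_extend are negative; a gap of length k scores
//    gap_open + k * gap_extend (BLAST existence/extension convention).
//  - local traceback tie-break: prefer the diagonal predecessor, then the
//    vertical (gap in target), then the horizontal; the first optimum in
//    row-major scan order is reported.
//  - coordinates reported are 0-based half-open.

#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List cpp_align_local(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                     int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int open_cost = gap_open + gap_extend;
  std::vector<std::vector<int>> M(n + 1, std::vector<int>(m + 1, 0));
  std::vector<std::vector<int>> X(n + 1, std::vector<int>(m + 1, NEG)); // gap in b (consumes a)
  std::vector<std::vector<int>> Y(n + 1, std::vector<int>(m + 1, NEG)); // gap in a (consumes b)

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = sub(a[i - 1], b[j - 1]);
      int prev = M[i - 1][j - 1];
      if (X[i - 1][j - 1] > prev) prev = X[i - 1][j - 1];
      if (Y[i - 1][j - 1] > prev) prev = Y[i - 1][j - 1];
      if (prev < 0) prev = 0;
      int mv = prev + s;
      M[i][j] = mv > 0 ? mv : 0;

      int xo = M[i - 1][j] + open_cost;
      int xe = X[i - 1][j] == NEG ? NEG : X[i - 1][j] + gap_extend;
      X[i][j] = xo > xe ? xo : xe;

      int yo = M[i][j - 1] + open_cost;
      int ye = Y[i][j - 1] == NEG ? NEG : Y[i][j - 1] + gap_extend;
      Y[i][j] = yo > ye ? yo : ye;

      if (M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }

  int qs = 0, qe = 0, ts = 0, te = 0;
  if (best > 0) {
    qe = bi; te = bj;
    int i = bi, j = bj, state = 0; // 0 = M, 1 = X, 2 = Y
    while (true) {
      if (state == 0) {
        int s = sub(a[i - 1], b[j - 1]);
        int rem = M[i][j] - s;
        if (rem <= 0 && M[i - 1][j - 1] <= 0 && X[i - 1][j - 1] <= 0 &&
            Y[i - 1][j - 1] <= 0) {
          qs = i - 1; ts = j - 1; break;
        }
        if (M[i - 1][j - 1] == rem) { state = 0; }
        else if (X[i - 1][j - 1] == rem) { state = 1; }
        else { state = 2; }
        --i; --j;
        if (state == 0 && M[i][j] == 0) { qs = i; ts = j; break; }
      } else if (state == 1) {
        if (X[i][j] == M[i - 1][j] + open_cost) state = 0; // stay X otherwise
        --i;
        if (state == 0 && M[i][j] == 0) { qs = i; ts = j; break; }
      } else {
        if (Y[i][j] == M[i][j - 1] + open_cost) state = 0;
        --j;
        if (state == 0 && M[i][j] == 0) { qs = i; ts = j; break; }
      }
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["t_start"] = ts, _["t_end"] = te);
}

// [[Rcpp::export]]
int cpp_align_global(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                     int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int open_cost = gap_open + gap_extend;
  std::vector<int> Mp(m + 1, NEG), Xp(m + 1, NEG), Yp(m + 1, NEG);
  std::vector<int> Mc(m + 1), Xc(m + 1), Yc(m + 1);

  Mp[0] = 0;
  for (int j = 1; j <= m; ++j) Yp[j] = gap_open + j * gap_extend;

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = gap_open + i * gap_extend;
    for (int j = 1; j <= m; ++j) {
      int s = sub(a[i - 1], b[j - 1]);
      int prev = Mp[j - 1];
      if (Xp[j - 1] > prev) prev = Xp[j - 1];
      if (Yp[j - 1] > prev) prev = Yp[j - 1];
      Mc[j] = prev <= NEG ? NEG : prev + s;

      int xo = Mp[j] <= NEG ? NEG : Mp[j] + open_cost;
      int xe = Xp[j] <= NEG ? NEG : Xp[j] + gap_extend;
      Xc[j] = xo > xe ? xo : xe;

      int yo = Mc[j - 1] <= NEG ? NEG : Mc[j - 1] + open_cost;
      int ye = Yc[j - 1] <= NEG ? NEG : Yc[j - 1] + gap_extend;
      Yc[j] = yo > ye ? yo : ye;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  int best = Mp[m];
  if (Xp[m] > best) best = Xp[m];
  if (Yp[m] > best) best = Yp[m];
  return best;
}
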