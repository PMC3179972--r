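#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh three-state DP).
//
// Gap convention: a gap of length L costs gap_open + (L-1) * gap_extend,
// i.e. the opening charge covers the first gap residue.
//
// Ties are broken deterministically: among equal-scoring end cells the one
// reached first in row-major scan order wins (with state preference
// M > X > Y at a cell); during traceback the predecessor preference is
// diagonal (M) > up (X, gap in b) > left (Y, gap in a).

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  std::string alphabet, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30, EPS = 1e-9;
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> X((n + 1) * (m + 1), NEG);  // gap in b, consumes a
  std::vector<double> Y((n + 1) * (m + 1), NEG);  // gap in a, consumes b
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  char bstate = 'M';

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      double prev = M[at(i - 1, j - 1)];
      if (X[at(i - 1, j - 1)] > prev) prev = X[at(i - 1, j - 1)];
      if (Y[at(i - 1, j - 1)] > prev) prev = Y[at(i - 1, j - 1)];
      if (prev < 0.0) prev = 0.0;  // local: restart freely
      M[at(i, j)] = prev + s;

      const double open_x = M[at(i - 1, j)] - gap_open;
      const double ext_x = X[at(i - 1, j)] - gap_extend;
      X[at(i, j)] = open_x >= ext_x ? open_x : ext_x;

      const double open_y = M[at(i, j - 1)] - gap_open;
      const double ext_y = Y[at(i, j - 1)] - gap_extend;
      Y[at(i, j)] = open_y >= ext_y ? open_y : ext_y;

      if (M[at(i, j)] > best + EPS) { best = M[at(i, j)]; bi = i; bj = j; bstate = 'M'; }
      if (X[at(i, j)] > best + EPS) { best = X[at(i, j)]; bi = i; bj = j; bstate = 'X'; }
      if (Y[at(i, j)] > best + EPS) { best = Y[at(i, j)]; bi = i; bj = j; bstate = 'Y'; }
    }
  }

  std::string rev_a, rev_b;
  int i = bi, j = bj;
  char state = bstate;
  if (best > EPS) {
    for (;;) {
      if (state == 'M') {
        const double s = sub(a[i - 1] - 1, b[j - 1] - 1);
        const double prev = M[at(i, j)] - s;
        rev_a.push_back(alphabet[a[i - 1] - 1]);
        rev_b.push_back(alphabet[b[j - 1] - 1]);
        --i; --j;
        if (prev <= EPS) break;  // fresh local start
        if (std::abs(M[at(i, j)] - prev) <= EPS) state = 'M';
        else if (std::abs(X[at(i, j)] - prev) <= EPS) state = 'X';
        else state = 'Y';
      } else if (state == 'X') {
        rev_a.push_back(alphabet[a[i - 1] - 1]);
        rev_b.push_back('-');
        const double open_v = M[at(i - 1, j)] - gap_open;
        state = (std::abs(X[at(i, j)] - open_v) <= EPS) ? 'M' : 'X';
        --i;
      } else {
        rev_a.push_back('-');
        rev_b.push_back(alphabet[b[j - 1] - 1]);
        const double open_v = M[at(i, j - 1)] - gap_open;
        state = (std::abs(Y[at(i, j)] - open_v) <= EPS) ? 'M' : 'Y';
        --j;
      }
    }
  }

  std::string al_a(rev_a.rbegin(), rev_a.rend());
  std::string al_b(rev_b.rbegin(), rev_b.rend());
  return List::create(_["score"] = best,
                      _["aligned_a"] = al_a,
                      _["aligned_b"] = al_b,
                      _["start_a"] = i + 1, _["start_b"] = j + 1,
                      _["end_a"] = bi, _["end_b"] = bj);
}
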