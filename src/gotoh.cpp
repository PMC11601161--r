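#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh three-state recurrence) over a
// precomputed pair-score matrix S (n x m, bits). Gap model: a gap of length
// len costs gopen + (len - 1) * gext. Terminal gaps are free (local
// alignment starts and ends on an aligned column).
//
// Traceback tie order: diagonal, then gap-in-target (unaligned query
// residues), then gap-in-query.
//
// [[Rcpp::export]]
List gotoh_align(NumericMatrix S, double gopen, double gext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e100;
  // DP rows are (m + 1) wide; index [i][j] means i residues of Q and j of T.
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG); // gap in query (consumes T)
  std::vector<double> F((n + 1) * (m + 1), NEG); // gap in target (consumes Q)
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int d = at(i - 1, j - 1);
      double prev = 0.0; // start a fresh local alignment
      if (H[d] > prev) prev = H[d];
      if (F[d] > prev) prev = F[d];
      if (E[d] > prev) prev = E[d];
      H[at(i, j)] = S(i - 1, j - 1) + prev;

      const int up = at(i - 1, j), lf = at(i, j - 1);
      double e = H[lf] - gopen;
      if (E[lf] - gext > e) e = E[lf] - gext;
      if (F[lf] - gopen > e) e = F[lf] - gopen;
      E[at(i, j)] = e;

      double f = H[up] - gopen;
      if (F[up] - gext > f) f = F[up] - gext;
      if (E[up] - gopen > f) f = E[up] - gopen;
      F[at(i, j)] = f;

      if (H[at(i, j)] > best) {
        best = H[at(i, j)];
        bi = i; bj = j;
      }
    }
  }

  std::vector<int> qcols, tcols;
  if (best > 0.0) {
    int i = bi, j = bj;
    char state = 'H';
    const double tol = 1e-9;
    while (i > 0 && j > 0) {
      if (state == 'H') {
        qcols.push_back(i);
        tcols.push_back(j);
        const int d = at(i - 1, j - 1);
        double prev = H[at(i, j)] - S(i - 1, j - 1);
        if (prev <= tol) break; // local alignment starts at this column
        // tie order: diagonal, gap-in-target (F), gap-in-query (E)
        if (std::abs(H[d] - prev) < tol) state = 'H';
        else if (std::abs(F[d] - prev) < tol) state = 'F';
        else if (std::abs(E[d] - prev) < tol) state = 'E';
        else break;
        --i; --j;
      } else if (state == 'F') { // gap consuming query residue i
        const int up = at(i - 1, j);
        double cur = F[at(i, j)];
        if (std::abs(H[up] - gopen - cur) < tol) state = 'H';
        else if (std::abs(F[up] - gext - cur) < tol) state = 'F';
        else state = 'E';
        --i;
      } else { // state == 'E': gap consuming target residue j
        const int lf = at(i, j - 1);
        double cur = E[at(i, j)];
        if (std::abs(H[lf] - gopen - cur) < tol) state = 'H';
        else if (std::abs(E[lf] - gext - cur) < tol) state = 'E';
        else state = 'F';
        --j;
      }
    }
    std::reverse(qcols.begin(), qcols.end());
    std::reverse(tcols.begin(), tcols.end());
  }
  return List::create(_["score"] = best,
                      _["q_cols"] = wrap(qcols),
                      _["t_cols"] = wrap(tcols));
}
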