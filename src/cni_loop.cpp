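#include <Rcpp.h>
using namespace Rcpp;

// NODF scores for replacements of one row of a binary matrix.
//
// A:    R x C binary incidence matrix
// i1:   1-based index of the focal row
// Bmat: n_rand x C matrix of degree-preserving replacement rows
// Or0:  R x R row-overlap matrix  (A  A^T) of the observed matrix
// Oc0:  C x C column-overlap matrix (A^T A)
//
// Host marginals are unchanged by a degree-preserving row swap, so the
// row-pair sum is updated only on pairs involving the focal row; the
// column part is re-evaluated per draw with the rank-2 overlap
// correction applied on the fly. Column overlaps are read along
// columns (the matrix is symmetric) for contiguous access, and the
// divisions by the pair minimum are replaced by a reciprocal table
// (the minimum is an integer degree).
// [[Rcpp::export]]
NumericVector cni_nodf_draws(const IntegerMatrix& A, const int i1,
                             const IntegerMatrix& Bmat,
                             const IntegerMatrix& Or0,
                             const IntegerMatrix& Oc0) {
  const int R = A.nrow(), C = A.ncol(), n_rand = Bmat.nrow();
  const int i = i1 - 1;
  const double n_pairs = R * (R - 1) / 2.0 + C * (C - 1) / 2.0;
  const int* Ap = INTEGER(A);
  const int* Ocp = INTEGER(Oc0);

  std::vector<int> k(R, 0), d0(C, 0);
  for (int c = 0; c < C; ++c) {
    const int* col = Ap + (size_t)c * R;
    for (int r = 0; r < R; ++r) {
      k[r] += col[r];
      d0[c] += col[r];
    }
  }
  const int maxdeg = std::max(R, C);
  std::vector<double> inv(maxdeg + 1, 0.0);
  for (int j = 1; j <= maxdeg; ++j) inv[j] = 1.0 / j;

  // row-pair sum of the observed matrix, and the focal row's share
  double base_row = 0, obs_i = 0;
  for (int r = 0; r < R - 1; ++r) {
    for (int s = r + 1; s < R; ++s) {
      if (k[r] != k[s]) {
        int km = std::min(k[r], k[s]);
        if (km > 0) {
          double term = 100.0 * Or0(r, s) * inv[km];
          base_row += term;
          if (r == i || s == i) obs_i += term;
        }
      }
    }
  }

  NumericVector out(n_rand);
  std::vector<int> d2(C), a(C), b(C), ov(R), supp;
  supp.reserve(C);
  for (int c = 0; c < C; ++c) a[c] = A(i, c);
  const int ki = k[i];

  for (int t = 0; t < n_rand; ++t) {
    supp.clear();
    for (int c = 0; c < C; ++c) {
      b[c] = Bmat(t, c);
      d2[c] = d0[c] - a[c] + b[c];
      if (b[c]) supp.push_back(c);
    }
    // overlaps of the replacement row with every other row, built
    // column-slice by column-slice over the row's support
    std::fill(ov.begin(), ov.end(), 0);
    for (int s : supp) {
      const int* col = Ap + (size_t)s * R;
      for (int r = 0; r < R; ++r) ov[r] += col[r];
    }
    double new_i = 0;
    for (int r = 0; r < R; ++r) {
      if (r == i || k[r] == ki) continue;
      int km = std::min(k[r], ki);
      if (km > 0) new_i += 100.0 * ov[r] * inv[km];
    }
    // column pairs; Oc0 is symmetric so read its column u contiguously
    double col_sum = 0;
    for (int u = 0; u < C - 1; ++u) {
      const int du = d2[u], au = a[u], bu = b[u];
      const int* ocu = Ocp + (size_t)u * C;
      for (int v = u + 1; v < C; ++v) {
        const int dv = d2[v];
        if (du != dv) {
          const int dm = du < dv ? du : dv;
          if (dm > 0) {
            const int o = ocu[v] - au * a[v] + bu * b[v];
            col_sum += 100.0 * o * inv[dm];
          }
        }
      }
    }
    out[t] = (base_row - obs_i + new_i + col_sum) / n_pairs;
  }
  return out;
}
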