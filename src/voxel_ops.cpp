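#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labeling, 26-connectivity, iterative flood fill.
// mask is a logical vector in column-major (i fastest) order with dims (nx,ny,nz).
// Returns an integer vector of the same length: 0 outside, 1..K component labels.
// [[Rcpp::export(name = ".cc_label_26")]]
IntegerVector cc_label_26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      const int k = (int)(v / ((R_xlen_t)nx * ny));
      const int rem = (int)(v % ((R_xlen_t)nx * ny));
      const int j = rem / nx;
      const int i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            const R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (mask[w] && labels[w] == 0) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// For each row of `from` (points in mm, columns x,y,z), the minimum Euclidean
// distance to any row of `to`. Brute force; exactness over speed by contract.
// [[Rcpp::export(name = ".nn_min_dist")]]
NumericVector nn_min_dist(NumericMatrix from, NumericMatrix to) {
  const int nf = from.nrow(), nt = to.nrow();
  if (from.ncol() != 3 || to.ncol() != 3) stop("point matrices must have 3 columns");
  if (nt == 0) stop("empty target point set");
  NumericVector out(nf);
  for (int a = 0; a < nf; ++a) {
    const double x = from(a, 0), y = from(a, 1), z = from(a, 2);
    double best = R_PosInf;
    for (int b = 0; b < nt; ++b) {
      const double dx = x - to(b, 0), dy = y - to(b, 1), dz = z - to(b, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}
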