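#include <Rcpp.h>
#include <vector>

// 3-D connected-component labelling of a binary lattice with 26-connectivity.
// Returns an integer array of the same shape: 0 for background, 1..K for the
// components in order of first (column-major) encounter.
// [[Rcpp::export(name = ".cc_label_26")]]
Rcpp::IntegerVector cc_label_26(Rcpp::LogicalVector mask,
                                Rcpp::IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) Rcpp::stop("mask length does not match dims");
  Rcpp::IntegerVector lab(n, 0);

  // precompute the 26 neighbour offsets as (dx, dy, dz)
  int dxs[26], dys[26], dzs[26], m = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        dxs[m] = dx; dys[m] = dy; dzs[m] = dz; ++m;
      }

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int q = 0; q < 26; ++q) {
        int xx = x + dxs[q], yy = y + dys[q], zz = z + dzs[q];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] == TRUE && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
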