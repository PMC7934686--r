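// 3D connected-component labeling with 6/18/26-connectivity.
// Components are numbered in order of first encounter in linear scan order
// (x fastest), which makes labeling deterministic.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != mask.size()) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        off.push_back(dx); off.push_back(dy); off.push_back(dz);
      }

  IntegerVector labels(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t idx = 0; idx < mask.size(); ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++next;
    labels[idx] = next;
    stack.clear();
    stack.push_back((int)idx);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cz = cur / (nx * ny);
      int rem = cur % (nx * ny);
      int cy = rem / nx;
      int cx = rem % nx;
      for (size_t k = 0; k < off.size(); k += 3) {
        int x = cx + off[k], y = cy + off[k + 1], z = cz + off[k + 2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int nidx = x + nx * (y + ny * z);
        if (mask[nidx] && labels[nidx] == 0) {
          labels[nidx] = next;
          stack.push_back(nidx);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
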