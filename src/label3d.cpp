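#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected foreground components of a 3D logical array.
// Index order matches R arrays: dim = (nz, ny, nx), z fastest.
// connectivity: 6 (faces) or 26 (faces + edges + corners).
// [[Rcpp::export]]
IntegerVector label_components_3d_cpp(LogicalVector mask, IntegerVector dims,
                                      int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);

  // neighbour offsets
  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        if (az == 0 && ay == 0 && ax == 0) continue;
        int manhattan = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (connectivity == 6 && manhattan != 1) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int nnb = (int)dz.size();

  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++current;
    labels[i] = current;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int vz = (int)(v % nz);
      int vy = (int)((v / nz) % ny);
      int vx = (int)(v / ((R_xlen_t)nz * ny));
      for (int j = 0; j < nnb; ++j) {
        int z = vz + dz[j], y = vy + dy[j], x = vx + dx[j];
        if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
        R_xlen_t w = (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
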