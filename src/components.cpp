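#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of a 3D logical volume (x-y-t) by iterative
// flood fill. connectivity = 6 (face neighbors) or 26 (face+edge+corner).
// Returns an integer volume of the same shape: 0 = inactive, 1..n = label.
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
  if (dims.size() != 3) stop("`dims` must have length 3");
  const R_xlen_t nx = dims[0], ny = dims[1], nt = dims[2];
  const R_xlen_t n = nx * ny * nt;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  // neighbor offsets in (dx, dy, dt)
  std::vector<int> dxs, dys, dts;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dt = -1; dt <= 1; ++dt) {
        if (dx == 0 && dy == 0 && dt == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dt);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dts.push_back(dt);
      }
  const size_t nn = dxs.size();

  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++current;
    labels[i] = current;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      R_xlen_t t = v / (nx * ny);
      R_xlen_t rem = v - t * nx * ny;
      R_xlen_t y = rem / nx;
      R_xlen_t x = rem - y * nx;
      for (size_t k = 0; k < nn; ++k) {
        R_xlen_t xx = x + dxs[k], yy = y + dys[k], tt = t + dts[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || tt < 0 || tt >= nt)
          continue;
        R_xlen_t w = xx + nx * (yy + ny * tt);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}

// Per-component summaries in one pass: voxel count, first/last frame and
// bounding box. Footprint areas (unique x-y columns per component) are
// computed on the R side from the sparse active-voxel indices.
// [[Rcpp::export(name = ".component_stats")]]
List component_stats(IntegerVector labels, IntegerVector dims, int n_components) {
  const R_xlen_t nx = dims[0], ny = dims[1], nt = dims[2];
  const R_xlen_t n = nx * ny * nt;
  if (labels.size() != n) stop("labels length does not match dims");

  IntegerVector nvox(n_components, 0), t0(n_components, 0), t1(n_components, 0),
      x0(n_components, 0), x1(n_components, 0), y0(n_components, 0),
      y1(n_components, 0);
  std::vector<bool> seen(n_components, false);

  for (R_xlen_t i = 0; i < n; ++i) {
    int lab = labels[i];
    if (lab == 0) continue;
    int c = lab - 1;
    R_xlen_t t = i / (nx * ny);
    R_xlen_t rem = i - t * nx * ny;
    R_xlen_t y = rem / nx;
    R_xlen_t x = rem - y * nx;
    if (!seen[c]) {
      seen[c] = true;
      t0[c] = t1[c] = (int)t;
      x0[c] = x1[c] = (int)x;
      y0[c] = y1[c] = (int)y;
    } else {
      if (t < t0[c]) t0[c] = (int)t;
      if (t > t1[c]) t1[c] = (int)t;
      if (x < x0[c]) x0[c] = (int)x;
      if (x > x1[c]) x1[c] = (int)x;
      if (y < y0[c]) y0[c] = (int)y;
      if (y > y1[c]) y1[c] = (int)y;
    }
    nvox[c]++;
  }
  return List::create(_["n_voxels"] = nvox, _["t0"] = t0, _["t1"] = t1,
                      _["x0"] = x0, _["x1"] = x1, _["y0"] = y0, _["y1"] = y1);
}
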