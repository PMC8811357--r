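#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labeling of a 3-D logical array.
// Labels are assigned in column-major scan order of the first voxel reached,
// so the labeling is deterministic for a given mask.
// [[Rcpp::export]]
IntegerVector cpp_label_26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}

// Longest pairwise distance (Feret diameter) between points (rows of pts).
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow(), d = pts.ncol();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double t = pts(i, k) - pts(j, k);
        s += t * t;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}

// Onion-peel inpainting of one axial slice: masked pixels are processed
// shell-by-shell inward from the unmasked set; each receives the mean of its
// 3 nearest (physical in-plane distance; ties by column-major scan order)
// currently-unmasked pixels and immediately becomes available as a source.
// [[Rcpp::export]]
NumericMatrix cpp_inpaint_slice(NumericMatrix img, LogicalMatrix mask,
                                double dx, double dy) {
  const int nx = img.nrow(), ny = img.ncol();
  NumericMatrix out = clone(img);
  LogicalMatrix open = clone(mask);  // true = still needs filling
  long remaining = 0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (open(i, j)) ++remaining;
  if (remaining == 0) return out;
  if (remaining == (long)nx * ny)
    stop("slice entirely masked");

  const double ratio = std::max(dx, dy) / std::min(dx, dy);
  while (remaining > 0) {
    // current shell: open pixels with at least one non-open 8-neighbour
    std::vector<std::pair<int,int> > shell;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!open(i, j)) continue;
        bool border = false;
        for (int b = -1; b <= 1 && !border; ++b)
          for (int a = -1; a <= 1 && !border; ++a) {
            if (!a && !b) continue;
            int ii = i + a, jj = j + b;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
            if (!open(ii, jj)) border = true;
          }
        if (border) shell.push_back(std::make_pair(i, j));
      }
    if (shell.empty()) break;  // unreachable in practice
    for (size_t s = 0; s < shell.size(); ++s) {
      int i = shell[s].first, j = shell[s].second;
      // expand a square window until >= 3 sources, then widen once to cover
      // anisotropic pitch before ranking by physical distance
      int w = 1, found = 0;
      int wmax = std::max(nx, ny);
      while (found < 3 && w <= wmax) {
        found = 0;
        for (int b = -w; b <= w; ++b)
          for (int a = -w; a <= w; ++a) {
            int ii = i + a, jj = j + b;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
            if (!open(ii, jj)) ++found;
          }
        if (found < 3) ++w;
      }
      int wf = std::min((int)std::ceil(w * ratio) + 1, wmax);
      // gather candidates in column-major scan order of the window
      double d1 = R_PosInf, d2 = R_PosInf, d3 = R_PosInf;
      double v1 = 0, v2 = 0, v3 = 0;
      for (int jj = std::max(0, j - wf); jj <= std::min(ny - 1, j + wf); ++jj)
        for (int ii = std::max(0, i - wf); ii <= std::min(nx - 1, i + wf); ++ii) {
          if (open(ii, jj)) continue;
          double ddx = (ii - i) * dx, ddy = (jj - j) * dy;
          double d = ddx * ddx + ddy * ddy;
          if (d < d1) {
            d3 = d2; v3 = v2; d2 = d1; v2 = v1; d1 = d; v1 = out(ii, jj);
          } else if (d < d2) {
            d3 = d2; v3 = v2; d2 = d; v2 = out(ii, jj);
          } else if (d < d3) {
            d3 = d; v3 = out(ii, jj);
          }
        }
      int k = (d3 < R_PosInf) ? 3 : (d2 < R_PosInf ? 2 : 1);
      out(i, j) = (k == 3) ? (v1 + v2 + v3) / 3.0 : (k == 2 ? (v1 + v2) / 2.0 : v1);
      open(i, j) = false;
      --remaining;
    }
  }
  return out;
}
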