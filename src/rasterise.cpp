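#include <Rcpp.h>
using namespace Rcpp;

// Rasterise an epithelium as the anisotropic nearest-seed partition of the
// pixel grid. Each seed i carries a unit radial direction (rx, ry) and a
// stretch factor k >= 1; the effective squared distance from pixel p to seed
// s is (d.r / k)^2 + (d.t)^2 with d = p - s, so the seed's cell is the
// Voronoi cell stretched by k along the radial axis. Pixels inside the wound
// disc get label 0. Coordinates are 0-based pixel centres (x = column,
// y = row).
//
// A uniform bucket grid accelerates the search: seeds are binned at roughly
// one mean spacing per bucket and each pixel scans a +/-3 bucket window,
// falling back to a full scan if the window holds no seed.

// [[Rcpp::export]]
IntegerMatrix rasterise_cells(NumericVector seed_x, NumericVector seed_y,
                              NumericVector stretch, NumericVector dir_x,
                              NumericVector dir_y, IntegerVector labels,
                              int nx, int ny, double wound_cx, double wound_cy,
                              double wound_r_px) {
  const int ns = seed_x.size();
  if (ns == 0) stop("rasterise_cells: no seeds");
  IntegerMatrix out(ny, nx);

  // bucket grid
  double spacing = std::sqrt((double)nx * ny / ns);
  double bsize = std::max(4.0, spacing);
  int bx = std::max(1, (int)std::ceil(nx / bsize));
  int by = std::max(1, (int)std::ceil(ny / bsize));
  std::vector<std::vector<int> > buckets((size_t)bx * by);
  for (int i = 0; i < ns; i++) {
    int cx = std::min(bx - 1, std::max(0, (int)(seed_x[i] / bsize)));
    int cy = std::min(by - 1, std::max(0, (int)(seed_y[i] / bsize)));
    buckets[(size_t)cy * bx + cx].push_back(i);
  }

  const double wr2 = wound_r_px > 0 ? wound_r_px * wound_r_px : -1.0;
  for (int row = 0; row < ny; row++) {
    double py = row;
    for (int col = 0; col < nx; col++) {
      double px = col;
      if (wr2 > 0) {
        double wdx = px - wound_cx, wdy = py - wound_cy;
        if (wdx * wdx + wdy * wdy <= wr2) { out(row, col) = 0; continue; }
      }
      int cx = std::min(bx - 1, std::max(0, (int)(px / bsize)));
      int cy = std::min(by - 1, std::max(0, (int)(py / bsize)));
      double best = R_PosInf; int besti = -1;
      for (int gy = std::max(0, cy - 3); gy <= std::min(by - 1, cy + 3); gy++) {
        for (int gx = std::max(0, cx - 3); gx <= std::min(bx - 1, cx + 3); gx++) {
          const std::vector<int>& b = buckets[(size_t)gy * bx + gx];
          for (size_t k = 0; k < b.size(); k++) {
            int i = b[k];
            double dx = px - seed_x[i], dy = py - seed_y[i];
            double dr = (dx * dir_x[i] + dy * dir_y[i]) / stretch[i];
            double dt = -dx * dir_y[i] + dy * dir_x[i];
            double d2 = dr * dr + dt * dt;
            if (d2 < best) { best = d2; besti = i; }
          }
        }
      }
      if (besti < 0) {  // window empty: full scan
        for (int i = 0; i < ns; i++) {
          double dx = px - seed_x[i], dy = py - seed_y[i];
          double dr = (dx * dir_x[i] + dy * dir_y[i]) / stretch[i];
          double dt = -dx * dir_y[i] + dy * dir_x[i];
          double d2 = dr * dr + dt * dt;
          if (d2 < best) { best = d2; besti = i; }
        }
      }
      out(row, col) = labels[besti];
    }
  }
  return out;
}

// Rasterise cells through a radial warp. The rendered image at pixel p
// (radius s from the warp centre) shows the reference-space tessellation at
// radius u(s): ref = centre + (u(s)/s) * (p - centre), where u is supplied
// as a lookup table on a uniform radius grid (pixel units, spacing s_step,
// starting at s = 0). Labels are the nearest reference seed (plain
// Euclidean; the reference configuration is isotropic). Pixels with
// s <= wound_r_px get label 0.

// [[Rcpp::export]]
IntegerMatrix rasterise_warped(NumericVector seed_x, NumericVector seed_y,
                               IntegerVector labels, int nx, int ny,
                               double cx, double cy, double wound_r_px,
                               NumericVector u_table, double s_step) {
  const int ns = seed_x.size();
  if (ns == 0) stop("rasterise_warped: no seeds");
  IntegerMatrix out(ny, nx);

  double spacing = std::sqrt((double)nx * ny / ns);
  double bsize = std::max(4.0, spacing);
  int bx = std::max(1, (int)std::ceil(2.0 * nx / bsize));  // u can exceed nx
  int by = std::max(1, (int)std::ceil(2.0 * ny / bsize));
  std::vector<std::vector<int> > buckets((size_t)bx * by);
  for (int i = 0; i < ns; i++) {
    int gx = std::min(bx - 1, std::max(0, (int)(seed_x[i] / bsize)));
    int gy = std::min(by - 1, std::max(0, (int)(seed_y[i] / bsize)));
    buckets[(size_t)gy * bx + gx].push_back(i);
  }
  const int ntab = u_table.size();
  for (int row = 0; row < ny; row++) {
    for (int col = 0; col < nx; col++) {
      double dx = col - cx, dy = row - cy;
      double s = std::sqrt(dx * dx + dy * dy);
      if (wound_r_px > 0 && s <= wound_r_px) { out(row, col) = 0; continue; }
      double u;
      if (s < 1e-9) u = 0.0;
      else {
        double fi = s / s_step;
        int i0 = (int)fi;
        if (i0 >= ntab - 1) u = u_table[ntab - 1] + (fi - (ntab - 1)) * s_step;
        else u = u_table[i0] + (fi - i0) * (u_table[i0 + 1] - u_table[i0]);
      }
      double scale = (s < 1e-9) ? 1.0 : u / s;
      double px = cx + scale * dx, py = cy + scale * dy;
      int gx = std::min(bx - 1, std::max(0, (int)(px / bsize)));
      int gy = std::min(by - 1, std::max(0, (int)(py / bsize)));
      double best = R_PosInf; int besti = -1;
      for (int yy = std::max(0, gy - 3); yy <= std::min(by - 1, gy + 3); yy++) {
        for (int xx = std::max(0, gx - 3); xx <= std::min(bx - 1, gx + 3); xx++) {
          const std::vector<int>& b = buckets[(size_t)yy * bx + xx];
          for (size_t k = 0; k < b.size(); k++) {
            int i = b[k];
            double ddx = px - seed_x[i], ddy = py - seed_y[i];
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 < best) { best = d2; besti = i; }
          }
        }
      }
      if (besti < 0) {
        for (int i = 0; i < ns; i++) {
          double ddx = px - seed_x[i], ddy = py - seed_y[i];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 < best) { best = d2; besti = i; }
        }
      }
      out(row, col) = labels[besti];
    }
  }
  return out;
}
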