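#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parallel-beam system-matrix triplets by Siddon-style ray marching.
//
// The image occupies [-n_cols*h/2, n_cols*h/2] x [-n_rows*h/2, n_rows*h/2],
// pixel (r, c) (0-based, row 0 at top) covering
//   x in [xmin + c*h, xmin + (c+1)*h), y in (ymax - (r+1)*h, ymax - r*h].
// A view at angle theta (degrees) measures line integrals over lines
//   { p : p . (cos t, sin t) = s },  s = bin centre,
// marched along direction d = (-sin t, cos t). The weight a_ij is the exact
// intersection length of the bin's central ray with pixel i. Pixel
// membership of each segment is decided by its midpoint, which makes
// boundary-running (axis-aligned) rays fall consistently into the half-open
// pixel on the positive side.
//
// Rays are ordered view-major: ray index = view * n_bins + bin (0-based).
// [[Rcpp::export]]
List siddon_triplets(int n_rows, int n_cols, double h,
                     NumericVector s_centers, NumericVector angles_deg) {
  const double xmin = -0.5 * n_cols * h, ymax = 0.5 * n_rows * h;
  const double ymin = -ymax, xmax = -xmin;
  const int nb = s_centers.size(), nv = angles_deg.size();
  std::vector<int> ri, ci;
  std::vector<double> vv;
  ri.reserve((size_t)nv * nb * (n_rows + n_cols));
  ci.reserve(ri.capacity());
  vv.reserve(ri.capacity());
  const double eps = 1e-12;

  for (int a = 0; a < nv; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ux = std::cos(th), uy = std::sin(th);   // detector normal
    double dx = -uy, dy = ux;                            // ray direction
    // snap axis-aligned directions exactly so boundary-running rays use the
    // same half-open pixel convention as the dense-oracle route
    if (std::fabs(dx) < eps) dx = 0.0;
    if (std::fabs(dy) < eps) dy = 0.0;
    for (int b = 0; b < nb; ++b) {
      const double s = s_centers[b];
      const double px = s * ux, py = s * uy;             // point on the ray
      // slab clipping to the grid bounding box
      double tmin = -std::numeric_limits<double>::infinity();
      double tmax = std::numeric_limits<double>::infinity();
      if (std::fabs(dx) > eps) {
        double t1 = (xmin - px) / dx, t2 = (xmax - px) / dx;
        if (t1 > t2) std::swap(t1, t2);
        tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
      } else if (px < xmin || px >= xmax) continue;
      if (std::fabs(dy) > eps) {
        double t1 = (ymin - py) / dy, t2 = (ymax - py) / dy;
        if (t1 > t2) std::swap(t1, t2);
        tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
      } else if (py <= ymin || py > ymax) continue;
      if (tmin >= tmax) continue;

      const int ray = a * nb + b;
      // march from crossing to crossing
      double t = tmin;
      // next crossing parameters along each axis
      const double dtx = (std::fabs(dx) > eps) ? h / std::fabs(dx)
                         : std::numeric_limits<double>::infinity();
      const double dty = (std::fabs(dy) > eps) ? h / std::fabs(dy)
                         : std::numeric_limits<double>::infinity();
      double tx, ty;
      if (std::fabs(dx) > eps) {
        double xg = (px + t * dx - xmin) / h;
        tx = t + ((dx > 0) ? (std::ceil(xg + 1e-9) - xg)
                           : (xg - std::floor(xg - 1e-9))) * h / std::fabs(dx);
      } else tx = std::numeric_limits<double>::infinity();
      if (std::fabs(dy) > eps) {
        double yg = (py + t * dy - ymin) / h;
        ty = t + ((dy > 0) ? (std::ceil(yg + 1e-9) - yg)
                           : (yg - std::floor(yg - 1e-9))) * h / std::fabs(dy);
      } else ty = std::numeric_limits<double>::infinity();

      while (t < tmax - eps) {
        double tn = std::min(std::min(tx, ty), tmax);
        if (tn > t + eps) {
          const double tm = 0.5 * (t + tn);
          const double mx = px + tm * dx, my = py + tm * dy;
          int c = (int)std::floor((mx - xmin) / h);
          int r = (int)std::floor((ymax - my) / h);
          if (r >= 0 && r < n_rows && c >= 0 && c < n_cols) {
            ri.push_back(ray);
            ci.push_back(r * n_cols + c);
            vv.push_back(tn - t);
          }
        }
        t = tn;
        if (tx <= ty) tx += dtx; else ty += dty;
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                      _["x"] = wrap(vv),
                      _["n_rays"] = nv * nb,
                      _["n_pixels"] = n_rows * n_cols);
}
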