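#include <Rcpp.h>
using namespace Rcpp;

// Nearest-voxel lookup of a 2D foreground plane stored as [x, y].
// Coordinates are continuous, 0-based, voxel-centered.
static inline bool inside(const LogicalMatrix &plane, double x, double y) {
  int ix = (int)std::lround(x), iy = (int)std::lround(y);
  if (ix < 0 || iy < 0 || ix >= plane.nrow() || iy >= plane.ncol()) return false;
  return plane(ix, iy) == TRUE;
}

// March a ray from (ox, oy) along each angle until the first background
// crossing; the crossing position is taken at the midpoint of the last
// inside / first outside step pair (linear interpolation of a binary edge).
// [[Rcpp::export]]
NumericVector cpp_ray_cast(LogicalMatrix plane, double ox, double oy,
                           NumericVector angles, double step = 0.25) {
  if (!inside(plane, ox, oy))
    stop("ray-cast origin (%.2f, %.2f) is outside the foreground", ox, oy);
  // longest possible chord bounds the march
  double tmax = std::sqrt((double)plane.nrow() * plane.nrow() +
                          (double)plane.ncol() * plane.ncol()) + 1.0;
  int n = angles.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double dx = std::cos(angles[k]), dy = std::sin(angles[k]);
    double tin = 0.0, t = step;
    while (t <= tmax) {
      if (!inside(plane, ox + t * dx, oy + t * dy)) break;
      tin = t;
      t += step;
    }
    out[k] = tin + step / 2.0;
  }
  return out;
}

// Number of 4-connected foreground components of a 2D plane.
// [[Rcpp::export]]
int cpp_n_components(LogicalMatrix plane) {
  int nx = plane.nrow(), ny = plane.ncol();
  std::vector<char> seen(nx * ny, 0);
  std::vector<int> stack;
  int ncomp = 0;
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int id = i + j * nx;
    if (!plane(i, j) || seen[id]) continue;
    ++ncomp;
    stack.push_back(id);
    seen[id] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int ci = cur % nx, cj = cur / nx;
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int q = 0; q < 4; ++q) {
        int ni = ci + di[q], nj = cj + dj[q];
        if (ni < 0 || nj < 0 || ni >= nx || nj >= ny) continue;
        int nid = ni + nj * nx;
        if (plane(ni, nj) && !seen[nid]) { seen[nid] = 1; stack.push_back(nid); }
      }
    }
  }
  return ncomp;
}
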