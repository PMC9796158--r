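#include <Rcpp.h>
using namespace Rcpp;

// Rasterize a TIN: for every triangle, fill the grid cells whose centres
// fall inside it with the barycentric (planar) interpolation of the
// vertex elevations. Cells outside every triangle stay NA.
//
// Grid convention: cell (r, c), 1-based from the top-left; centre at
// x = xmin + (c - 0.5) * res, y = ymax - (r - 0.5) * res.
// [[Rcpp::export(name = ".tin_rasterize")]]
NumericMatrix tin_rasterize(IntegerMatrix tri, NumericVector x,
                            NumericVector y, NumericVector z,
                            int nrow, int ncol, double xmin, double ymax,
                            double res) {
  NumericMatrix out(nrow, ncol);
  std::fill(out.begin(), out.end(), NA_REAL);
  const double eps = 1e-9;
  for (int t = 0; t < tri.nrow(); ++t) {
    int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
    double x1 = x[a], y1 = y[a], x2 = x[b], y2 = y[b], x3 = x[c], y3 = y[c];
    double det = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
    if (std::fabs(det) < 1e-300) continue; // degenerate sliver
    double lox = std::min(x1, std::min(x2, x3)), hix = std::max(x1, std::max(x2, x3));
    double loy = std::min(y1, std::min(y2, y3)), hiy = std::max(y1, std::max(y2, y3));
    int c0 = std::max(0, (int)std::floor((lox - xmin) / res - 0.5));
    int c1 = std::min(ncol - 1, (int)std::ceil((hix - xmin) / res - 0.5));
    int r0 = std::max(0, (int)std::floor((ymax - hiy) / res - 0.5));
    int r1 = std::min(nrow - 1, (int)std::ceil((ymax - loy) / res - 0.5));
    for (int r = r0; r <= r1; ++r) {
      double py = ymax - (r + 0.5) * res;
      for (int cc = c0; cc <= c1; ++cc) {
        double px = xmin + (cc + 0.5) * res;
        double l1 = ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det;
        double l2 = ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det;
        double l3 = 1.0 - l1 - l2;
        if (l1 < -eps || l2 < -eps || l3 < -eps) continue;
        out(r, cc) = l1 * z[a] + l2 * z[b] + l3 * z[c];
      }
    }
  }
  return out;
}
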