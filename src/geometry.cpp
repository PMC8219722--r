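#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// crossing-number point-in-polygon test; boundary points count as inside
// (a half-open rule on edges — consistent, so raster areas are unbiased)
static inline bool pip(double px, double py,
                       const NumericVector& vx, const NumericVector& vy) {
  int n = vx.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export(name = ".pointsInPolygonCpp")]]
LogicalVector pointsInPolygonCpp(NumericVector px, NumericVector py,
                                 NumericVector vx, NumericVector vy) {
  int n = px.size();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = pip(px[i], py[i], vx, vy);
  return out;
}

// Polygon area by counting grid-cell centres inside the bounding box.
// Independent of the shoelace formula on purpose: it is the rasterisation
// oracle the analytic area is validated against. Cell centres are
// classified row by row from the sorted edge crossings (scanline), which
// is exactly the per-cell crossing-number test, just not re-evaluated per
// cell.
// [[Rcpp::export(name = ".rasterPolygonAreaCpp")]]
double rasterPolygonAreaCpp(NumericVector vx, NumericVector vy, int nGrid) {
  double xmin = min(vx), xmax = max(vx), ymin = min(vy), ymax = max(vy);
  double w = xmax - xmin, h = ymax - ymin;
  if (w <= 0 || h <= 0 || nGrid < 2) return 0.0;
  int nx = (int)std::ceil(std::sqrt((double)nGrid * w / h));
  int ny = (int)std::ceil((double)nGrid / nx);
  double dx = w / nx, dy = h / ny;
  int n = vx.size();
  long long cnt = 0;
  std::vector<double> xs;
  for (int j = 0; j < ny; j++) {
    double cy = ymin + (j + 0.5) * dy;
    xs.clear();
    for (int i = 0, k = n - 1; i < n; k = i++) {
      if ((vy[i] > cy) != (vy[k] > cy))
        xs.push_back((vx[k] - vx[i]) * (cy - vy[i]) / (vy[k] - vy[i]) + vx[i]);
    }
    std::sort(xs.begin(), xs.end());
    for (size_t p = 0; p + 1 < xs.size(); p += 2) {
      // cell centres cx = xmin + (i + 0.5) dx strictly inside (xs[p], xs[p+1])
      double u1 = (xs[p]     - xmin) / dx - 0.5;
      double u2 = (xs[p + 1] - xmin) / dx - 0.5;
      long long lo = (long long)std::ceil(u1);
      long long hi = (long long)std::floor(u2);
      if (lo < 0) lo = 0;
      if (hi > nx - 1) hi = nx - 1;
      if (hi >= lo) cnt += hi - lo + 1;
    }
  }
  return (double)cnt * dx * dy;
}

// 8-connected component labelling of a binary matrix (stack flood fill).
// Labels are assigned in column-major scan order, so output is deterministic.
// [[Rcpp::export(name = ".label8Cpp")]]
IntegerMatrix label8Cpp(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      if (!m(r, c) || lab(r, c) != 0) continue;
      next++;
      stack.push_back(c * nr + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; dc++) {
          for (int dr = -1; dr <= 1; dr++) {
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (m(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(c2 * nr + r2);
            }
          }
        }
      }
    }
  }
  return lab;
}

// max pairwise distance within a point set (Feret diameter), used for
// scale-line length; convex hull would be faster but n is small here
// [[Rcpp::export(name = ".feretDiameterCpp")]]
double feretDiameterCpp(NumericVector x, NumericVector y) {
  int n = x.size();
  double best = 0.0;
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}

// directed+symmetric Hausdorff distance between two point sets
// [[Rcpp::export(name = ".hausdorffCpp")]]
double hausdorffCpp(NumericVector ax, NumericVector ay,
                    NumericVector bx, NumericVector by) {
  int na = ax.size(), nb = bx.size();
  double hAB = 0.0, hBA = 0.0;
  std::vector<double> minB(nb, R_PosInf);
  for (int i = 0; i < na; i++) {
    double m = R_PosInf;
    for (int j = 0; j < nb; j++) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < m) m = d2;
      if (d2 < minB[j]) minB[j] = d2;
    }
    if (m > hAB) hAB = m;
  }
  for (int j = 0; j < nb; j++) if (minB[j] > hBA) hBA = minB[j];
  return std::sqrt(std::max(hAB, hBA));
}
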