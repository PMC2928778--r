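#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 4-point cosine regularized delta (support |r| < 2, mesh-width units)
static inline double phi4(double r) {
  double a = std::fabs(r);
  if (a >= 2.0) return 0.0;
  return 0.25 * (1.0 + std::cos(M_PI * r / 2.0));
}

static inline int wrap(int i, int n) {
  int m = i % n;
  return m < 0 ? m + n : m;
}

// [[Rcpp::export]]
double delta_weight_cpp(double r) { return phi4(r); }

// Spread per-point scalar values onto an n x n periodic grid.
// Node i (1-based in R) sits at x = (i-1)*h. Contribution val * phi*phi / h^2.
// [[Rcpp::export]]
NumericMatrix spread_scalar_cpp(NumericVector px, NumericVector py,
                                NumericVector val, int n, double h) {
  NumericMatrix out(n, n);
  const double inv_h2 = 1.0 / (h * h);
  const int m = px.size();
  for (int l = 0; l < m; ++l) {
    double gx = px[l] / h, gy = py[l] / h;
    int ix0 = (int)std::floor(gx), iy0 = (int)std::floor(gy);
    double wx[4], wy[4];
    for (int a = 0; a < 4; ++a) {
      wx[a] = phi4((ix0 - 1 + a) - gx);
      wy[a] = phi4((iy0 - 1 + a) - gy);
    }
    double c = val[l] * inv_h2;
    for (int a = 0; a < 4; ++a) {
      int ii = wrap(ix0 - 1 + a, n);
      double cwx = c * wx[a];
      if (cwx == 0.0) continue;
      for (int b = 0; b < 4; ++b) {
        int jj = wrap(iy0 - 1 + b, n);
        out(ii, jj) += cwx * wy[b];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List spread_vector_cpp(NumericVector px, NumericVector py,
                       NumericVector fx, NumericVector fy, int n, double h) {
  NumericMatrix ox(n, n), oy(n, n);
  const double inv_h2 = 1.0 / (h * h);
  const int m = px.size();
  for (int l = 0; l < m; ++l) {
    double gx = px[l] / h, gy = py[l] / h;
    int ix0 = (int)std::floor(gx), iy0 = (int)std::floor(gy);
    double wx[4], wy[4];
    for (int a = 0; a < 4; ++a) {
      wx[a] = phi4((ix0 - 1 + a) - gx);
      wy[a] = phi4((iy0 - 1 + a) - gy);
    }
    double cx = fx[l] * inv_h2, cy = fy[l] * inv_h2;
    for (int a = 0; a < 4; ++a) {
      int ii = wrap(ix0 - 1 + a, n);
      if (wx[a] == 0.0) continue;
      for (int b = 0; b < 4; ++b) {
        int jj = wrap(iy0 - 1 + b, n);
        double w = wx[a] * wy[b];
        ox(ii, jj) += cx * w;
        oy(ii, jj) += cy * w;
      }
    }
  }
  return List::create(_["fx"] = ox, _["fy"] = oy);
}

// Interpolate two grid fields at point positions (delta-weighted average).
// [[Rcpp::export]]
NumericMatrix interp_vector_cpp(NumericMatrix u, NumericMatrix v,
                                NumericVector px, NumericVector py, double h) {
  const int n = u.nrow();
  const int m = px.size();
  NumericMatrix out(m, 2);
  for (int l = 0; l < m; ++l) {
    double gx = px[l] / h, gy = py[l] / h;
    int ix0 = (int)std::floor(gx), iy0 = (int)std::floor(gy);
    double wx[4], wy[4];
    for (int a = 0; a < 4; ++a) {
      wx[a] = phi4((ix0 - 1 + a) - gx);
      wy[a] = phi4((iy0 - 1 + a) - gy);
    }
    double su = 0.0, sv = 0.0;
    for (int a = 0; a < 4; ++a) {
      if (wx[a] == 0.0) continue;
      int ii = wrap(ix0 - 1 + a, n);
      for (int b = 0; b < 4; ++b) {
        int jj = wrap(iy0 - 1 + b, n);
        double w = wx[a] * wy[b];
        su += w * u(ii, jj);
        sv += w * v(ii, jj);
      }
    }
    out(l, 0) = su;
    out(l, 1) = sv;
  }
  return out;
}

// Even-odd point-in-polygon test for a batch of query points.
// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericVector qx, NumericVector qy,
                                    NumericVector polx, NumericVector poly) {
  const int nq = qx.size(), np = polx.size();
  LogicalVector out(nq);
  for (int q = 0; q < nq; ++q) {
    bool inside = false;
    double x = qx[q], y = qy[q];
    for (int i = 0, j = np - 1; i < np; j = i++) {
      if (((poly[i] > y) != (poly[j] > y)) &&
          (x < (polx[j] - polx[i]) * (y - poly[i]) / (poly[j] - poly[i]) + polx[i]))
        inside = !inside;
    }
    out[q] = inside;
  }
  return out;
}

// Scanline-fill a polygon into an existing integer mask (modified in place).
// Mask cell (i,j) (1-based from R) is centred at (x0 + (i-1)*hm, y0 + (j-1)*hm).
// [[Rcpp::export]]
void rasterize_polygon_cpp(IntegerMatrix mask, NumericVector polx,
                           NumericVector poly, double x0, double y0, double hm) {
  const int nx = mask.nrow(), ny = mask.ncol(), np = polx.size();
  double ymin = *std::min_element(poly.begin(), poly.end());
  double ymax = *std::max_element(poly.begin(), poly.end());
  int j0 = std::max(0, (int)std::ceil((ymin - y0) / hm));
  int j1 = std::min(ny - 1, (int)std::floor((ymax - y0) / hm));
  std::vector<double> xs;
  for (int j = j0; j <= j1; ++j) {
    double yc = y0 + j * hm;
    xs.clear();
    for (int i = 0, k = np - 1; i < np; k = i++) {
      double y1 = poly[k], y2 = poly[i];
      if ((y1 > yc) != (y2 > yc)) {
        double t = (yc - y1) / (y2 - y1);
        xs.push_back(polx[k] + t * (polx[i] - polx[k]));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t p = 0; p + 1 < xs.size(); p += 2) {
      int ia = std::max(0, (int)std::ceil((xs[p] - x0) / hm));
      int ib = std::min(nx - 1, (int)std::floor((xs[p + 1] - x0) / hm));
      for (int i = ia; i <= ib; ++i) mask(i, j) = 1;
    }
  }
}

// Label free (0) cells connected to the mask border as exterior (2);
// remaining free cells are enclosed (lumen). 4-connectivity, non-periodic.
// [[Rcpp::export]]
IntegerMatrix flood_exterior_cpp(IntegerMatrix mask) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab = clone(mask);
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nx; ++i) {
    if (lab(i, 0) == 0) { lab(i, 0) = 2; q.push(std::make_pair(i, 0)); }
    if (lab(i, ny - 1) == 0) { lab(i, ny - 1) = 2; q.push(std::make_pair(i, ny - 1)); }
  }
  for (int j = 0; j < ny; ++j) {
    if (lab(0, j) == 0) { lab(0, j) = 2; q.push(std::make_pair(0, j)); }
    if (lab(nx - 1, j) == 0) { lab(nx - 1, j) = 2; q.push(std::make_pair(nx - 1, j)); }
  }
  const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    std::pair<int, int> c = q.front(); q.pop();
    for (int d = 0; d < 4; ++d) {
      int i = c.first + di[d], j = c.second + dj[d];
      if (i < 0 || i >= nx || j < 0 || j >= ny) continue;
      if (lab(i, j) == 0) { lab(i, j) = 2; q.push(std::make_pair(i, j)); }
    }
  }
  return lab;
}

static inline double cross3(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static bool seg_intersect(double p1x, double p1y, double p2x, double p2y,
                          double q1x, double q1y, double q2x, double q2y) {
  double d1 = cross3(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = cross3(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = cross3(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = cross3(p1x, p1y, p2x, p2y, q2x, q2y);
  return ((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0));
}

// First pair of non-adjacent edges (1-based start indices) that properly
// cross, or an empty vector.
// [[Rcpp::export]]
IntegerVector first_self_intersection_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j2 == i) continue;
      if (seg_intersect(x[i], y[i], x[i2], y[i2], x[j], y[j], x[j2], y[j2]))
        return IntegerVector::create(i + 1, j + 1);
    }
  }
  return IntegerVector(0);
}

// True if the closed polygon has a proper self-intersection between
// any two non-adjacent edges.
// [[Rcpp::export]]
bool polygon_self_intersects_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 4) return false;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j2 == i) continue;  // adjacent around the wrap
      if (seg_intersect(x[i], y[i], x[i2], y[i2], x[j], y[j], x[j2], y[j2]))
        return true;
    }
  }
  return false;
}
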