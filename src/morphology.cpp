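#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Pixel-level primitives backing the electron-microscopy morphometry
// pipeline. All matrices are row/col indexed (origin top-left); images are
// integer grey levels, masks are logical, distances are double.

// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(const IntegerMatrix& img, const int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  const int w = 2 * radius + 1;
  std::vector<int> buf(w * w);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;  // clamp at edges
        for (int di = -radius; di <= radius; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          buf[k++] = img(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

// Disk structuring element morphology; erosion treats outside as background.
// [[Rcpp::export]]
LogicalMatrix cpp_morph_disk(const LogicalMatrix& mask, const int radius,
                             const bool dilate) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::pair<int, int> > se;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      if (di * di + dj * dj <= radius * radius) se.push_back(std::make_pair(di, dj));
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool hit = dilate ? false : true;
      for (size_t s = 0; s < se.size(); ++s) {
        const int ii = i + se[s].first, jj = j + se[s].second;
        bool v = false;
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) v = mask(ii, jj);
        if (dilate) { if (v) { hit = true; break; } }
        else        { if (!v) { hit = false; break; } }
      }
      out(i, j) = hit;
    }
  }
  return out;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher squared
// distance, two separable passes). Distance to the nearest false pixel;
// pixels outside the image do not count as background.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_distance_transform(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {           // pass 1: along rows (per column)
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {           // pass 2: along columns (per row)
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = std::sqrt(d[j]);
  }
  return out;
}

// Separable square-window maximum filter (half-width = radius).
// [[Rcpp::export]]
NumericMatrix cpp_window_max(const NumericMatrix& x, const int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = -std::numeric_limits<double>::infinity();
      const int lo = std::max(0, i - radius), hi = std::min(nr - 1, i + radius);
      for (int ii = lo; ii <= hi; ++ii) m = std::max(m, x(ii, j));
      tmp(i, j) = m;
    }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double m = -std::numeric_limits<double>::infinity();
      const int lo = std::max(0, j - radius), hi = std::min(nc - 1, j + radius);
      for (int jj = lo; jj <= hi; ++jj) m = std::max(m, tmp(i, jj));
      out(i, j) = m;
    }
  return out;
}

// Connected-component labelling, 8-connectivity, deterministic raster order.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = pi + di, jj = pj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * nr);
            }
          }
      }
    }
  return lab;
}

struct QNode {
  double h;
  long seq;
  int idx;
  int label;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.h != b.h) return a.h > b.h;   // lower height floods first
    return a.seq > b.seq;               // FIFO tie-break => deterministic
  }
};

// Marker-based watershed (priority flood, 8-connectivity, no watershed
// lines: every masked pixel joins the first basin that reaches it).
// height is typically the negated distance transform.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& height,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  const int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  long seq = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        QNode n; n.h = height(i, j); n.seq = seq++; n.idx = i + j * nr;
        n.label = markers(i, j);
        pq.push(n);
      }
  while (!pq.empty()) {
    const QNode n = pq.top(); pq.pop();
    const int pi = n.idx % nr, pj = n.idx / nr;
    if (lab(pi, pj)) continue;
    lab(pi, pj) = n.label;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        const int ii = pi + di, jj = pj + dj;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (mask(ii, jj) && !lab(ii, jj)) {
          QNode m; m.h = height(ii, jj); m.seq = seq++; m.idx = ii + jj * nr;
          m.label = n.label;
          pq.push(m);
        }
      }
  }
  return lab;
}

// ---- Welzl's minimum enclosing circle (expected linear time) -------------

struct Circ { double x, y, r2; };

static inline bool in_circ(const Circ& c, double px, double py) {
  const double dx = px - c.x, dy = py - c.y;
  return dx * dx + dy * dy <= c.r2 * (1.0 + 1e-12) + 1e-12;
}
static Circ circ2(double ax, double ay, double bx, double by) {
  Circ c;
  c.x = 0.5 * (ax + bx);
  c.y = 0.5 * (ay + by);
  const double dx = ax - c.x, dy = ay - c.y;
  c.r2 = dx * dx + dy * dy;
  return c;
}
static Circ circ3(double ax, double ay, double bx, double by,
                  double cx, double cy) {
  const double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  Circ c;
  if (std::fabs(d) < 1e-14) {  // collinear: fall back to widest pair
    Circ c1 = circ2(ax, ay, bx, by), c2 = circ2(ax, ay, cx, cy),
         c3 = circ2(bx, by, cx, cy);
    c = c1;
    if (c2.r2 > c.r2) c = c2;
    if (c3.r2 > c.r2) c = c3;
    return c;
  }
  const double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
               cc2 = cx * cx + cy * cy;
  c.x = (a2 * (by - cy) + b2 * (cy - ay) + cc2 * (ay - by)) / d;
  c.y = (a2 * (cx - bx) + b2 * (ax - cx) + cc2 * (bx - ax)) / d;
  const double dx = ax - c.x, dy = ay - c.y;
  c.r2 = dx * dx + dy * dy;
  return c;
}

// [[Rcpp::export]]
NumericVector cpp_min_enclosing_circle(const NumericMatrix& pts) {
  const int n = pts.nrow();
  if (n == 0) stop("empty point set");
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = pts(i, 0); py[i] = pts(i, 1); }
  // deterministic LCG shuffle keeps the expected-linear behaviour
  unsigned long s = 88172645463325252ULL;
  for (int i = n - 1; i > 0; --i) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    const int k = (int)(s % (unsigned long)(i + 1));
    std::swap(px[i], px[k]);
    std::swap(py[i], py[k]);
  }
  Circ c; c.x = px[0]; c.y = py[0]; c.r2 = 0.0;
  for (int i = 1; i < n; ++i) {
    if (in_circ(c, px[i], py[i])) continue;
    c.x = px[i]; c.y = py[i]; c.r2 = 0.0;
    for (int j = 0; j < i; ++j) {
      if (in_circ(c, px[j], py[j])) continue;
      c = circ2(px[i], py[i], px[j], py[j]);
      for (int k = 0; k < j; ++k) {
        if (in_circ(c, px[k], py[k])) continue;
        c = circ3(px[i], py[i], px[j], py[j], px[k], py[k]);
      }
    }
  }
  return NumericVector::create(c.x, c.y, std::sqrt(c.r2));
}
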