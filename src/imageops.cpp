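// Low-level raster operations used by the morphometry, segmentation and
// break-profile code. All matrices are column-major (R layout), logical masks
// are passed as LogicalMatrix, images as NumericMatrix. 8-connectivity is the
// foreground convention throughout; hole filling uses 4-connected background
// (the dual of 8-connected foreground).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

// 1D squared distance transform of sampled function f, result into d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from every pixel to the nearest FALSE pixel.
// Foreground pixels with no background anywhere get Inf. A large finite
// sentinel (> any attainable squared distance) stands in for infinity inside
// the 1D transforms, which cannot handle true Inf samples.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  const double LARGE = 4.0 * ((double)nr * nr + (double)nc * nc) + 1.0;
  bool any_bg = false;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      out(i, j) = mask(i, j) ? LARGE : 0.0;
      if (!mask(i, j)) any_bg = true;
    }
  if (!any_bg) {
    std::fill(out.begin(), out.end(), INF);
    return out;
  }
  std::vector<double> f, d;
  // transform along columns (vertical distances)
  f.resize(nr); d.resize(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = out(i, j);
    dt1d(f, d);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // transform along rows (combine with horizontal offsets)
  f.resize(nc); d.resize(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    dt1d(f, d);
    for (int j = 0; j < nc; ++j) out(i, j) = std::min(d[j], LARGE);
  }
  return out;
}

// ---- Zhang-Suen thinning (skeletonization) ----

static inline int at(const std::vector<int>& m, int nr, int nc, int i, int j) {
  if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
  return m[i + (size_t)j * nr];
}

// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> m((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m[i + (size_t)j * nr] = mask(i, j) ? 1 : 0;
  bool changed = true;
  std::vector<std::pair<int,int> > del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!at(m, nr, nc, i, j)) continue;
          // neighbours P2..P9 clockwise starting north
          int p2 = at(m, nr, nc, i - 1, j);
          int p3 = at(m, nr, nc, i - 1, j + 1);
          int p4 = at(m, nr, nc, i,     j + 1);
          int p5 = at(m, nr, nc, i + 1, j + 1);
          int p6 = at(m, nr, nc, i + 1, j);
          int p7 = at(m, nr, nc, i + 1, j - 1);
          int p8 = at(m, nr, nc, i,     j - 1);
          int p9 = at(m, nr, nc, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t k = 0; k < del.size(); ++k)
        m[del[k].first + (size_t)del[k].second * nr] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m[i + (size_t)j * nr] != 0;
  return out;
}

// ---- connected components, 8-connected ----

// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<int> q;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      ++next;
      lab(i0, j0) = next;
      q.push(i0 + j0 * nr);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int i = idx % nr, j = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(ii + jj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---- hole filling: background 4-connected to the border stays background ----

// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside((size_t)nr * nc, 0);
  std::queue<int> q;
  for (int i = 0; i < nr; ++i) {
    if (!mask(i, 0))      { outside[i] = 1; q.push(i); }
    if (!mask(i, nc - 1)) { outside[i + (size_t)(nc - 1) * nr] = 1; q.push(i + (nc - 1) * nr); }
  }
  for (int j = 0; j < nc; ++j) {
    if (!mask(0, j))      { outside[(size_t)j * nr] = 1; q.push(j * nr); }
    if (!mask(nr - 1, j)) { outside[nr - 1 + (size_t)j * nr] = 1; q.push(nr - 1 + j * nr); }
  }
  int di4[4] = {-1, 1, 0, 0};
  int dj4[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int i = idx % nr, j = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int ii = i + di4[k], jj = j + dj4[k];
      if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
      size_t id2 = ii + (size_t)jj * nr;
      if (!mask(ii, jj) && !outside[id2]) { outside[id2] = 1; q.push((int)id2); }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !outside[i + (size_t)j * nr];
  return out;
}

// ---- disc dilation / erosion ----

// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disc(const LogicalMatrix& mask, double radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  int r = (int)std::floor(radius);
  std::vector<std::pair<int,int> > offs;
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj)
      if (di * di + dj * dj <= radius * radius) offs.push_back(std::make_pair(di, dj));
  LogicalMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), false);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      for (size_t k = 0; k < offs.size(); ++k) {
        int ii = i + offs[k].first, jj = j + offs[k].second;
        if (ii >= 0 && jj >= 0 && ii < nr && jj < nc) out(ii, jj) = true;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_erode_disc(const LogicalMatrix& mask, double radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  int r = (int)std::floor(radius);
  std::vector<std::pair<int,int> > offs;
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj)
      if (di * di + dj * dj <= radius * radius) offs.push_back(std::make_pair(di, dj));
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool keep = mask(i, j);
      if (keep) {
        for (size_t k = 0; k < offs.size(); ++k) {
          int ii = i + offs[k].first, jj = j + offs[k].second;
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc || !mask(ii, jj)) { keep = false; break; }
        }
      }
      out(i, j) = keep;
    }
  }
  return out;
}

// ---- geodesic distance on the mask's 8-connected pixel graph ----
// Dijkstra with step weights 1 (axial) and sqrt(2) (diagonal), in pixels.
// sources are 0-based linear indices (column-major). Unreachable or
// off-mask pixels get Inf.

// [[Rcpp::export]]
NumericMatrix cpp_geodesic(const LogicalMatrix& mask, const IntegerVector& sources) {
  int nr = mask.nrow(), nc = mask.ncol();
  size_t n = (size_t)nr * nc;
  std::vector<double> dist(n, INF);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k];
    if (s < 0 || (size_t)s >= n) stop("source index out of range");
    if (!mask(s % nr, s / nr)) stop("source pixel not on the mask");
    dist[s] = 0.0;
    pq.push(std::make_pair(0.0, s));
  }
  const double SQ2 = std::sqrt(2.0);
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; int idx = top.second;
    if (d > dist[idx]) continue;
    int i = idx % nr, j = idx / nr;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        if (!mask(ii, jj)) continue;
        double w = (di != 0 && dj != 0) ? SQ2 : 1.0;
        size_t id2 = ii + (size_t)jj * nr;
        if (d + w < dist[id2]) {
          dist[id2] = d + w;
          pq.push(std::make_pair(d + w, (int)id2));
        }
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (size_t k = 0; k < n; ++k) out[k] = dist[k];
  return out;
}

// ---- Canny support: non-maximum suppression and hysteresis ----

// Gradient magnitude thinning: keep pixels that are local maxima along the
// quantized gradient direction (classic 4-sector scheme).
// [[Rcpp::export]]
LogicalMatrix cpp_nms(const NumericMatrix& mag, const NumericMatrix& gx,
                      const NumericMatrix& gy) {
  int nr = mag.nrow(), nc = mag.ncol();
  LogicalMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), false);
  for (int j = 1; j < nc - 1; ++j) {
    for (int i = 1; i < nr - 1; ++i) {
      double m = mag(i, j);
      if (m <= 0) continue;
      double ang = std::atan2(gy(i, j), gx(i, j)); // gx: column dir, gy: row dir
      if (ang < 0) ang += M_PI;
      double m1, m2;
      if (ang < M_PI / 8 || ang >= 7 * M_PI / 8) {        // horizontal gradient
        m1 = mag(i, j - 1); m2 = mag(i, j + 1);
      } else if (ang < 3 * M_PI / 8) {                    // diagonal
        m1 = mag(i - 1, j - 1); m2 = mag(i + 1, j + 1);
      } else if (ang < 5 * M_PI / 8) {                    // vertical gradient
        m1 = mag(i - 1, j); m2 = mag(i + 1, j);
      } else {                                            // anti-diagonal
        m1 = mag(i - 1, j + 1); m2 = mag(i + 1, j - 1);
      }
      if (m >= m1 && m >= m2) out(i, j) = true;
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_hysteresis(const NumericMatrix& mag, const LogicalMatrix& cand,
                             double low, double high) {
  int nr = mag.nrow(), nc = mag.ncol();
  LogicalMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), false);
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (cand(i, j) && mag(i, j) >= high) { out(i, j) = true; q.push(i + j * nr); }
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int i = idx % nr, j = idx / nr;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int ii = i + di, jj = j + dj;
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        if (cand(ii, jj) && !out(ii, jj) && mag(ii, jj) >= low) {
          out(ii, jj) = true;
          q.push(ii + jj * nr);
        }
      }
    }
  }
  return out;
}
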