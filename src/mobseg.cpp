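#include <Rcpp.h>
#include <vector>
#include <utility>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Mirror-without-edge-repeat index fold (numpy 'reflect'): -1 -> 1, n -> n-2.
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n - 2;
  int m = i % period;
  if (m < 0) m += period;
  if (m >= n) m = period - m;
  return m;
}

// [[Rcpp::export]]
NumericMatrix cpp_extract_patch(const NumericMatrix& img, int cy, int cx, int p) {
  // cy, cx are 1-based; patch center sits at patch position (p %/% 2) 0-based.
  int H = img.nrow(), W = img.ncol();
  int top = (cy - 1) - p / 2;
  int left = (cx - 1) - p / 2;
  NumericMatrix out(p, p);
  for (int j = 0; j < p; ++j) {
    int sc = reflect_index(left + j, W);
    for (int i = 0; i < p; ++i) {
      out(i, j) = img(reflect_index(top + i, H), sc);
    }
  }
  return out;
}

// Overlap weights for exact area-average resampling of p source pixels onto d
// output cells. Each source pixel [j, j+1) distributes its value over the
// output cells [k*p/d, (k+1)*p/d) it intersects, weight = overlap / (p/d).
static std::vector< std::vector< std::pair<int, double> > > area_weights(int p, int d) {
  std::vector< std::vector< std::pair<int, double> > > w(p);
  double scale = (double)p / (double)d;
  for (int j = 0; j < p; ++j) {
    int k0 = (int)std::floor(j / scale);
    int k1 = (int)std::floor((j + 1.0 - 1e-12) / scale);
    if (k1 >= d) k1 = d - 1;
    for (int k = k0; k <= k1; ++k) {
      double lo = std::max((double)j, k * scale);
      double hi = std::min((double)j + 1.0, (k + 1) * scale);
      if (hi > lo) w[j].push_back(std::make_pair(k, (hi - lo) / scale));
    }
  }
  return w;
}

// [[Rcpp::export]]
NumericMatrix cpp_downsample_area(const NumericMatrix& patch, int d) {
  int p = patch.nrow();
  std::vector< std::vector< std::pair<int, double> > > w = area_weights(p, d);
  NumericMatrix out(d, d);
  for (int j = 0; j < p; ++j) {
    for (size_t b = 0; b < w[j].size(); ++b) {
      int kc = w[j][b].first;
      double wc = w[j][b].second;
      for (int i = 0; i < p; ++i) {
        double v = patch(i, j) * wc;
        for (size_t a = 0; a < w[i].size(); ++a) {
          out(w[i][a].first, kc) += v * w[i][a].second;
        }
      }
    }
  }
  // per output cell the weights sum to 1 along each axis, so the
  // accumulated value is already the exact area-weighted mean
  return out;
}

// Extract n patches of side p centered at (cy, cx) (1-based), reflect-padded,
// area-downsampled to d x d, returned as an n x (d*d) matrix (row = patch,
// columns in R column-major order of the d x d patch).
// [[Rcpp::export]]
NumericMatrix cpp_extract_features(const NumericMatrix& img,
                                   const IntegerVector& cy,
                                   const IntegerVector& cx,
                                   int p, int d) {
  int H = img.nrow(), W = img.ncol();
  int n = cy.size();
  std::vector< std::vector< std::pair<int, double> > > w = area_weights(p, d);
  NumericMatrix out(n, d * d);
  std::vector<double> acc(d * d);
  for (int s = 0; s < n; ++s) {
    int top = (cy[s] - 1) - p / 2;
    int left = (cx[s] - 1) - p / 2;
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      int sc = reflect_index(left + j, W);
      for (size_t b = 0; b < w[j].size(); ++b) {
        int kc = w[j][b].first * d;
        double wc = w[j][b].second;
        for (int i = 0; i < p; ++i) {
          double v = img(reflect_index(top + i, H), sc) * wc;
          for (size_t a = 0; a < w[i].size(); ++a) {
            acc[kc + w[i][a].first] += v * w[i][a].second;
          }
        }
      }
    }
    for (int k = 0; k < d * d; ++k) out(s, k) = acc[k];
  }
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), exact.
static void dt1d(const std::vector<double>& f, std::vector<double>& dout, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    dout[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest nonzero pixel of mask.
// Pixels of the mask itself get 0; an all-zero mask gets Inf everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  // a finite sentinel larger than any attainable squared distance keeps the
  // parabola intersections in dt1d well defined
  const double BIG = (double)H * H + (double)W * W + 1.0;
  NumericMatrix dist(H, W);
  std::vector<double> f(std::max(H, W)), dpass(std::max(H, W));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = mask(i, j) != 0 ? 0.0 : BIG;
    dt1d(f, dpass, H);
    for (int i = 0; i < H; ++i) dist(i, j) = dpass[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = dist(i, j);
    dt1d(f, dpass, W);
    for (int j = 0; j < W; ++j)
      dist(i, j) = dpass[j] >= BIG ? R_PosInf : dpass[j];
  }
  return dist;
}

// 8-connected component labelling of the nonzero pixels of mask.
// Returns an integer matrix: 0 background, components numbered from 1 in
// scan order of their first-encountered pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(j * H + i);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % H, cj = idx / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(nj * H + ni);
            }
          }
        }
      }
    }
  }
  return lab;
}
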