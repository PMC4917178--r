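// Low-level voxel kernels. All stacks are passed as numeric arrays with
// dim = c(ny, nx, nz); linear index = y + ny * (x + nx * z), 0-based here.
// Border handling is edge replication throughout (indices clamped).

#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static void get_dims(const RObject& x, int& ny, int& nx, int& nz) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  ny = d[0]; nx = d[1]; nz = d[2];
}

// Correlation along one axis of every z-slice: out(i) = sum_t k(t) * in(i + t - r).
// axis: 0 = y (rows), 1 = x (cols). Kernel length must be odd.
static void corr1d_slice(const double* in, double* out, int ny, int nx,
                         const double* k, int klen, int axis) {
  int r = klen / 2;
  if (axis == 0) {
    for (int x = 0; x < nx; ++x) {
      const double* col = in + (size_t)x * ny;
      double* ocol = out + (size_t)x * ny;
      for (int y = 0; y < ny; ++y) {
        double acc = 0.0;
        for (int t = 0; t < klen; ++t)
          acc += k[t] * col[clampi(y + t - r, 0, ny - 1)];
        ocol[y] = acc;
      }
    }
  } else {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int t = 0; t < klen; ++t)
          acc += k[t] * in[y + (size_t)ny * clampi(x + t - r, 0, nx - 1)];
        out[y + (size_t)ny * x] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_sep2d(NumericVector img, NumericVector ky, NumericVector kx) {
  int ny, nx, nz; get_dims(img, ny, nx, nz);
  if (ky.size() % 2 == 0 || kx.size() % 2 == 0) stop("kernel length must be odd");
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  std::vector<double> tmp((size_t)ny * nx);
  size_t sl = (size_t)ny * nx;
  for (int z = 0; z < nz; ++z) {
    const double* in = REAL(img) + sl * z;
    double* o = REAL(out) + sl * z;
    corr1d_slice(in, tmp.data(), ny, nx, REAL(ky), ky.size(), 0);
    corr1d_slice(tmp.data(), o, ny, nx, REAL(kx), kx.size(), 1);
  }
  return out;
}

// Separable correlation along one axis of the full 3D volume (axis 2 = z).
// [[Rcpp::export]]
NumericVector cpp_conv_axis3d(NumericVector img, NumericVector k, int axis) {
  int ny, nx, nz; get_dims(img, ny, nx, nz);
  if (k.size() % 2 == 0) stop("kernel length must be odd");
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  int klen = k.size(), r = klen / 2;
  const double* in = REAL(img);
  double* o = REAL(out);
  size_t sl = (size_t)ny * nx;
  if (axis == 2) {
    for (int z = 0; z < nz; ++z)
      for (size_t i = 0; i < sl; ++i) {
        double acc = 0.0;
        for (int t = 0; t < klen; ++t)
          acc += k[t] * in[sl * clampi(z + t - r, 0, nz - 1) + i];
        o[sl * z + i] = acc;
      }
  } else {
    std::vector<double> tmp(sl);
    for (int z = 0; z < nz; ++z) {
      corr1d_slice(in + sl * z, tmp.data(), ny, nx, REAL(k), klen, axis);
      std::copy(tmp.begin(), tmp.end(), o + sl * z);
    }
  }
  return out;
}

// Per-slice square-window median with edge replication.
// [[Rcpp::export]]
NumericVector cpp_median2d(NumericVector img, int win) {
  int ny, nx, nz; get_dims(img, ny, nx, nz);
  if (win % 2 == 0 || win < 1) stop("window must be odd and >= 1");
  int r = win / 2;
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  std::vector<double> buf((size_t)win * win);
  size_t sl = (size_t)ny * nx;
  for (int z = 0; z < nz; ++z) {
    const double* in = REAL(img) + sl * z;
    double* o = REAL(out) + sl * z;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int n = 0;
        for (int dx = -r; dx <= r; ++dx)
          for (int dy = -r; dy <= r; ++dy)
            buf[n++] = in[clampi(y + dy, 0, ny - 1) +
                          (size_t)ny * clampi(x + dx, 0, nx - 1)];
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
        o[y + (size_t)ny * x] = buf[n / 2];
      }
  }
  return out;
}

// One Perona-Malik step per slice: I += lam * sum_d g(|d|) d, 4-neighbour
// differences d, conductance g(s) = exp(-(s/kappa)^2), zero-flux borders
// (replication makes the boundary difference vanish).
// [[Rcpp::export]]
NumericVector cpp_pm_step(NumericVector img, double kappa, double lam) {
  int ny, nx, nz; get_dims(img, ny, nx, nz);
  NumericVector out(img.size());
  out.attr("dim") = img.attr("dim");
  double ik2 = 1.0 / (kappa * kappa);
  size_t sl = (size_t)ny * nx;
  for (int z = 0; z < nz; ++z) {
    const double* in = REAL(img) + sl * z;
    double* o = REAL(out) + sl * z;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double c = in[y + (size_t)ny * x], acc = 0.0;
        int yy[4] = {y - 1, y + 1, y, y};
        int xx[4] = {x, x, x - 1, x + 1};
        for (int j = 0; j < 4; ++j) {
          double d = in[clampi(yy[j], 0, ny - 1) +
                        (size_t)ny * clampi(xx[j], 0, nx - 1)] - c;
          acc += std::exp(-d * d * ik2) * d;
        }
        o[y + (size_t)ny * x] = c + lam * acc;
      }
  }
  return out;
}

// 26- (or 6-) connected components of a foreground mask; labels assigned in
// raster order of each component's first voxel (linear index order).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector bin, int connectivity) {
  int ny, nx, nz; get_dims(bin, ny, nx, nz);
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  size_t n = bin.size();
  IntegerVector lab(n);
  lab.attr("dim") = bin.attr("dim");
  const int* b = INTEGER(bin);
  int* L = INTEGER(lab);
  std::vector<int> stack;
  int next = 0;
  size_t sl = (size_t)ny * nx;
  for (size_t i = 0; i < n; ++i) {
    if (!b[i] || L[i]) continue;
    ++next;
    L[i] = next;
    stack.clear();
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (int)sl, rem = cur % (int)sl, x = rem / ny, y = rem % ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dz && !dx && !dy) continue;
            if (connectivity == 6 &&
                std::abs(dz) + std::abs(dx) + std::abs(dy) != 1) continue;
            int y2 = y + dy, x2 = x + dx, z2 = z + dz;
            if (y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx || z2 < 0 || z2 >= nz)
              continue;
            size_t j = y2 + (size_t)ny * x2 + sl * z2;
            if (b[j] && !L[j]) { L[j] = next; stack.push_back((int)j); }
          }
    }
  }
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), sample
// spacing w; f holds squared distances, updated in place along one axis.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb,
                 int n, double w) {
  const double INF = 1e30;
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w * w * q * q) - (f[p] + w * w * p * p)) /
          (2.0 * w * w * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Anisotropy-aware squared Euclidean distance (um^2) of foreground voxels to
// the nearest background voxel; voxels outside the array count as background.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, double wy, double wx, double wz) {
  int ny, nx, nz; get_dims(mask, ny, nx, nz);
  const double INF = 1e30;
  NumericVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  double* F = REAL(out);
  const int* m = INTEGER(mask);
  size_t sl = (size_t)ny * nx;
  for (size_t i = 0; i < (size_t)mask.size(); ++i) F[i] = m[i] ? INF : 0.0;

  int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      double* col = F + sl * z + (size_t)ny * x;
      std::copy(col, col + ny, f.begin());
      dt1d(f, d, v, zb, ny, wy);
      std::copy(f.begin(), f.begin() + ny, col);
    }
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = F[y + (size_t)ny * x + sl * z];
      dt1d(f, d, v, zb, nx, wx);
      for (int x = 0; x < nx; ++x) F[y + (size_t)ny * x + sl * z] = f[x];
    }
  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = F[y + (size_t)ny * x + sl * z];
      dt1d(f, d, v, zb, nz, wz);
      for (int z = 0; z < nz; ++z) F[y + (size_t)ny * x + sl * z] = f[z];
    }
  // clip half-voxel: outside-array background handled by border columns
  for (size_t i = 0; i < (size_t)mask.size(); ++i) if (!m[i]) F[i] = 0.0;
  return out;
}

// Voxels of `mask` that are >= all 26 neighbours of `img` within the mask.
// [[Rcpp::export]]
IntegerVector cpp_local_max26(NumericVector img, IntegerVector mask) {
  int ny, nx, nz; get_dims(img, ny, nx, nz);
  IntegerVector out(img.size());
  out.attr("dim") = img.attr("dim");
  const double* I = REAL(img);
  const int* m = INTEGER(mask);
  int* o = INTEGER(out);
  size_t sl = (size_t)ny * nx;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        size_t i = y + (size_t)ny * x + sl * z;
        if (!m[i]) continue;
        double c = I[i];
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; ++dz)
          for (int dx = -1; dx <= 1 && ok; ++dx)
            for (int dy = -1; dy <= 1 && ok; ++dy) {
              if (!dz && !dx && !dy) continue;
              int y2 = y + dy, x2 = x + dx, z2 = z + dz;
              if (y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx || z2 < 0 || z2 >= nz)
                continue;
              size_t j = y2 + (size_t)ny * x2 + sl * z2;
              if (m[j] && I[j] > c) ok = false;
            }
        if (ok) o[i] = 1;
      }
  return out;
}

struct WsNode {
  double pri; long order; int idx; int lab;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.pri != b.pri) return a.pri < b.pri;     // max-heap on priority
    return a.order > b.order;                     // FIFO on ties
  }
};

// Priority-flood watershed: flood `mask` from labelled `seeds`, descending
// the priority map (e.g. a distance transform). 26-connected growth.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector seeds,
                            IntegerVector mask) {
  int ny, nx, nz; get_dims(priority, ny, nx, nz);
  IntegerVector lab = clone(seeds);
  lab.attr("dim") = priority.attr("dim");
  const double* P = REAL(priority);
  const int* m = INTEGER(mask);
  int* L = INTEGER(lab);
  size_t sl = (size_t)ny * nx;
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> q;
  long ord = 0;
  size_t n = priority.size();
  for (size_t i = 0; i < n; ++i)
    if (L[i] > 0) q.push({P[i], ord++, (int)i, L[i]});
  while (!q.empty()) {
    WsNode nd = q.top(); q.pop();
    int z = nd.idx / (int)sl, rem = nd.idx % (int)sl, x = rem / ny, y = rem % ny;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          if (!dz && !dx && !dy) continue;
          int y2 = y + dy, x2 = x + dx, z2 = z + dz;
          if (y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx || z2 < 0 || z2 >= nz)
            continue;
          size_t j = y2 + (size_t)ny * x2 + sl * z2;
          if (m[j] && L[j] == 0) {
            L[j] = nd.lab;
            q.push({P[j], ord++, (int)j, nd.lab});
          }
        }
  }
  return lab;
}
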