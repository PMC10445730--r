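#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// All volumes are numeric 3D arrays indexed (z, y, x) in column-major R order:
// linear index = z + nz*y + nz*ny*x.

static inline int reflect_idx(int i, int n) {
  // reflect-101-style padding without repeating the edge twice ("reflect" in
  // scipy terms repeats the edge; we use symmetric half-sample reflection:
  // -1 -> 0, n -> n-1), which is the standard "reflect" boundary.
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// histogram-based path for integer-valued volumes in [0, 65535]: slide the
// window along z with a two-level (coarse >> 8, fine) histogram — far fewer
// operations than re-sorting 845-voxel windows
static void median_filter3d_hist(const NumericVector &vol, NumericVector &out,
                                 int nz, int ny, int nx,
                                 int rz, int ry, int rx) {
  const int half = ((2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1)) / 2 + 1;
  std::vector<int> coarse(256), fine(65536);
  std::vector<int> yy(2 * ry + 1), xx(2 * rx + 1);
  for (int x = 0; x < nx; ++x) {
    for (int i = -rx; i <= rx; ++i) xx[i + rx] = reflect_idx(x + i, nx);
    for (int y = 0; y < ny; ++y) {
      for (int i = -ry; i <= ry; ++i) yy[i + ry] = reflect_idx(y + i, ny);
      std::fill(coarse.begin(), coarse.end(), 0);
      std::fill(fine.begin(), fine.end(), 0);
      for (int d = -rz; d <= rz; ++d) {
        const int zz = reflect_idx(d, nz);
        for (int b : xx)
          for (int a : yy) {
            const int v = (int)vol[zz + (R_xlen_t)nz * (a + (R_xlen_t)ny * b)];
            ++coarse[v >> 8]; ++fine[v];
          }
      }
      for (int z = 0; z < nz; ++z) {
        if (z > 0) {
          const int z_out = reflect_idx(z - 1 - rz, nz);
          const int z_in = reflect_idx(z + rz, nz);
          for (int b : xx)
            for (int a : yy) {
              const R_xlen_t base = (R_xlen_t)nz * (a + (R_xlen_t)ny * b);
              const int vo = (int)vol[z_out + base];
              --coarse[vo >> 8]; --fine[vo];
              const int vi = (int)vol[z_in + base];
              ++coarse[vi >> 8]; ++fine[vi];
            }
        }
        int cum = 0, c = 0;
        while (cum + coarse[c] < half) cum += coarse[c++];
        int v = c << 8;
        while (cum + fine[v] < half) cum += fine[v++];
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = v;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector median_filter3d_cpp(NumericVector vol, IntegerVector dim,
                                  int kz, int ky, int kx) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  if (kz % 2 == 0 || ky % 2 == 0 || kx % 2 == 0 || kz < 1 || ky < 1 || kx < 1)
    stop("median kernel sizes must be odd and >= 1");
  const int rz = kz / 2, ry = ky / 2, rx = kx / 2;
  bool integral = true;
  for (R_xlen_t i = 0; i < vol.size(); ++i) {
    const double v = vol[i];
    if (v < 0 || v > 65535 || v != std::floor(v)) { integral = false; break; }
  }
  if (integral) {
    NumericVector out(vol.size());
    median_filter3d_hist(vol, out, nz, ny, nx, rz, ry, rx);
    out.attr("dim") = dim;
    return out;
  }
  NumericVector out(vol.size());
  const int wlen = kz * ky * kx;
  std::vector<double> window(wlen);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int m = 0;
        for (int dx = -rx; dx <= rx; ++dx) {
          const int xx = reflect_idx(x + dx, nx);
          for (int dy = -ry; dy <= ry; ++dy) {
            const int yy = reflect_idx(y + dy, ny);
            const R_xlen_t base = (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            for (int dz = -rz; dz <= rz; ++dz) {
              window[m++] = vol[reflect_idx(z + dz, nz) + base];
            }
          }
        }
        std::nth_element(window.begin(), window.begin() + wlen / 2,
                         window.begin() + wlen);
        double med = window[wlen / 2];
        if (wlen % 2 == 0) {
          double lo = *std::max_element(window.begin(), window.begin() + wlen / 2);
          med = 0.5 * (med + lo);
        }
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = med;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
LogicalVector dilate3d_box_cpp(LogicalVector mask, IntegerVector dim,
                               int kz, int ky, int kx) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  if (kz % 2 == 0 || ky % 2 == 0 || kx % 2 == 0 || kz < 1 || ky < 1 || kx < 1)
    stop("structuring element sizes must be odd and >= 1");
  const int rz = kz / 2, ry = ky / 2, rx = kx / 2;
  // separable: box dilation = 1D max along each axis in turn
  LogicalVector a = clone(mask), b(mask.size());
  // z axis
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) {
        bool v = false;
        for (int d = -rz; d <= rz && !v; ++d) {
          int zz = z + d;
          if (zz >= 0 && zz < nz && a[zz + base]) v = true;
        }
        b[z + base] = v;
      }
    }
  // y axis
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        bool v = false;
        for (int d = -ry; d <= ry && !v; ++d) {
          int yy = y + d;
          if (yy >= 0 && yy < ny && b[z + (R_xlen_t)nz * (yy + (R_xlen_t)ny * x)])
            v = true;
        }
        a[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = v;
      }
    }
  // x axis
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) {
        bool v = false;
        for (int d = -rx; d <= rx && !v; ++d) {
          int xx = x + d;
          if (xx >= 0 && xx < nx && a[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * xx)])
            v = true;
        }
        b[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = v;
      }
    }
  b.attr("dim") = dim;
  return b;
}

// [[Rcpp::export]]
NumericVector gauss_blur3d_cpp(NumericVector vol, IntegerVector dim,
                               double sz, double sy, double sx) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector a = clone(vol), b(vol.size());
  const double sig[3] = {sz, sy, sx};
  const int n[3] = {nz, ny, nx};
  NumericVector *src = &a, *dst = &b;
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sig[axis];
    if (s <= 0) continue;
    const int r = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + r];
    }
    for (auto &v : k) v /= ksum;
    const int len = n[axis];
    // iterate over all lines along `axis`
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          if ((axis == 0 && z > 0) || (axis == 1 && y > 0) || (axis == 2 && x > 0))
            continue; // only line starts
          for (int p = 0; p < len; ++p) {
            double acc = 0;
            for (int i = -r; i <= r; ++i) {
              int q = reflect_idx(p + i, len);
              int zz = z, yy = y, xx = x;
              if (axis == 0) zz = q; else if (axis == 1) yy = q; else xx = q;
              acc += k[i + r] * (*src)[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
            }
            int zz = z, yy = y, xx = x;
            if (axis == 0) zz = p; else if (axis == 1) yy = p; else xx = p;
            (*dst)[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] = acc;
          }
        }
    std::swap(src, dst);
  }
  NumericVector out = *src;
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim) {
  // 26-connected component labelling, BFS; labels 1..k in scan order
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t c = q.front(); q.pop();
      int z = c % nz, y = (c / nz) % ny, x = c / ((R_xlen_t)nz * ny);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// [[Rcpp::export]]
IntegerMatrix local_maxima3d_cpp(NumericVector vol, IntegerVector dim,
                                 double threshold, bool strict) {
  // returns 0-based (z,y,x) coordinates of 26-neighbourhood local maxima with
  // value >= threshold; strict: value > every neighbour; non-strict: >=
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> zs, ys, xs;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const double v = vol[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
        if (v < threshold) continue;
        bool is_max = true;
        for (int dx = -1; dx <= 1 && is_max; ++dx)
          for (int dy = -1; dy <= 1 && is_max; ++dy)
            for (int dz = -1; dz <= 1 && is_max; ++dz) {
              if (!dx && !dy && !dz) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                continue;
              const double w = vol[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
              if (strict ? (w >= v) : (w > v)) is_max = false;
            }
        if (is_max) { zs.push_back(z); ys.push_back(y); xs.push_back(x); }
      }
  IntegerMatrix out(zs.size(), 3);
  for (size_t i = 0; i < zs.size(); ++i) {
    out(i, 0) = zs[i]; out(i, 1) = ys[i]; out(i, 2) = xs[i];
  }
  colnames(out) = CharacterVector::create("z", "y", "x");
  return out;
}
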