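#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Trilinear / nearest-neighbour sampling of a 3-D lattice at positions given
// by an affine map from output indices to (continuous, 0-based) source
// indices.  map is 3x4: src = map[,1:3] %*% out_idx + map[,4].
// Out-of-lattice samples are clamped to the border (replicate padding).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector src_dim,
                                  IntegerVector out_dim, NumericMatrix map,
                                  bool nearest) {
  const int nx = src_dim[0], ny = src_dim[1], nz = src_dim[2];
  const int mx = out_dim[0], my = out_dim[1], mz = out_dim[2];
  NumericVector out(static_cast<R_xlen_t>(mx) * my * mz);
  const double *s = src.begin();
  double *o = out.begin();

  const double a11 = map(0, 0), a12 = map(0, 1), a13 = map(0, 2), b1 = map(0, 3);
  const double a21 = map(1, 0), a22 = map(1, 1), a23 = map(1, 2), b2 = map(1, 3);
  const double a31 = map(2, 0), a32 = map(2, 1), a33 = map(2, 2), b3 = map(2, 3);

  R_xlen_t idx = 0;
  for (int k = 0; k < mz; ++k) {
    for (int j = 0; j < my; ++j) {
      for (int i = 0; i < mx; ++i, ++idx) {
        double x = a11 * i + a12 * j + a13 * k + b1;
        double y = a21 * i + a22 * j + a23 * k + b2;
        double z = a31 * i + a32 * j + a33 * k + b3;
        if (nearest) {
          int ix = (int)std::lround(x), iy = (int)std::lround(y),
              iz = (int)std::lround(z);
          ix = ix < 0 ? 0 : (ix > nx - 1 ? nx - 1 : ix);
          iy = iy < 0 ? 0 : (iy > ny - 1 ? ny - 1 : iy);
          iz = iz < 0 ? 0 : (iz > nz - 1 ? nz - 1 : iz);
          o[idx] = s[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        } else {
          x = x < 0 ? 0 : (x > nx - 1 ? nx - 1 : x);
          y = y < 0 ? 0 : (y > ny - 1 ? ny - 1 : y);
          z = z < 0 ? 0 : (z > nz - 1 ? nz - 1 : z);
          int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
          if (x0 > nx - 2) x0 = nx - 2 < 0 ? 0 : nx - 2;
          if (y0 > ny - 2) y0 = ny - 2 < 0 ? 0 : ny - 2;
          if (z0 > nz - 2) z0 = nz - 2 < 0 ? 0 : nz - 2;
          int x1 = nx == 1 ? x0 : x0 + 1;
          int y1 = ny == 1 ? y0 : y0 + 1;
          int z1 = nz == 1 ? z0 : z0 + 1;
          double fx = x - x0, fy = y - y0, fz = z - z0;
          #define AT(ii, jj, kk) s[(ii) + (R_xlen_t)nx * ((jj) + (R_xlen_t)ny * (kk))]
          double c00 = AT(x0, y0, z0) * (1 - fx) + AT(x1, y0, z0) * fx;
          double c10 = AT(x0, y1, z0) * (1 - fx) + AT(x1, y1, z0) * fx;
          double c01 = AT(x0, y0, z1) * (1 - fx) + AT(x1, y0, z1) * fx;
          double c11 = AT(x0, y1, z1) * (1 - fx) + AT(x1, y1, z1) * fx;
          #undef AT
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          o[idx] = c0 * (1 - fz) + c1 * fz;
        }
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

// 26-connected component labelling of a binary 3-D mask.  Components are
// numbered 1..K in order of discovery under a linear (column-major) scan, so
// component 1 contains the lowest linear foreground index.
// [[Rcpp::export]]
IntegerVector cpp_label_components26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int *m = mask.begin();
  int *L = lab.begin();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!m[start] || L[start]) continue;
    ++next;
    L[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (m[w] && !L[w]) {
              L[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double step, std::vector<int> &v, std::vector<double> &z) {
  // Felzenszwalb & Huttenlocher lower-envelope distance transform, 1-D.
  const double s2 = step * step;
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sq = (f[q] + s2 * q * q);
    double sk = (f[v[k]] + s2 * v[k] * v[k]);
    double inter = (sq - sk) / (2.0 * s2 * (q - v[k]));
    while (inter <= z[k]) {
      --k;
      sk = (f[v[k]] + s2 * v[k] * v[k]);
      inter = (sq - sk) / (2.0 * s2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from each voxel to the nearest
// foreground voxel, with anisotropic spacing.  Background-only input yields
// all-Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double *D = out.begin();
  const int *m = mask.begin();
  // large finite sentinel instead of Inf: keeps the lower-envelope
  // intersection arithmetic NaN-free for foreground-free rows
  const double huge = 1e20;
  for (R_xlen_t i = 0; i < n; ++i) D[i] = m[i] ? 0.0 : huge;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      dt1d(f, d, nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)nx * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = D[base + stride * k];
      dt1d(f, d, nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) D[base + stride * k] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    if (D[i] >= 1e19) D[i] = R_PosInf;
  out.attr("dim") = dim;
  return out;
}
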