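#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Reflect (half-sample symmetric) index into [0, n).
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Box median filter of odd size, reflect padding at the boundary.
// [[Rcpp::export(name = ".median_filter_box")]]
NumericVector median_filter_box(NumericVector x, IntegerVector dims, int size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int h = size / 2;
  const int m = size * size * size;
  NumericVector out(x.size());
  std::vector<double> buf(m);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int c = 0;
        for (int dk = -h; dk <= h; ++dk) {
          const int kk = reflect(k + dk, nz);
          const R_xlen_t zoff = (R_xlen_t)kk * nx * ny;
          for (int dj = -h; dj <= h; ++dj) {
            const int jj = reflect(j + dj, ny);
            const R_xlen_t yoff = zoff + (R_xlen_t)jj * nx;
            for (int di = -h; di <= h; ++di) {
              const int ii = reflect(i + di, nx);
              buf[c++] = x[yoff + ii];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        double med = buf[m / 2];
        if (m % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m / 2 - 1,
                           buf.begin() + m / 2);
          med = 0.5 * (med + buf[m / 2 - 1]);
        }
        out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = med;
      }
    }
  }
  return out;
}

// Label 26-connected foreground components; labels 1..n in discovery order,
// 0 for background.
// [[Rcpp::export(name = ".label_components_26")]]
IntegerVector label_components_26(LogicalVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!x[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      const int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            if (ii < 0 || ii >= nx || (di == 0 && dj == 0 && dk == 0)) continue;
            const R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (x[w] && !lab[w]) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return lab;
}

// im2col for SAME 3x3 convolution on an (H, W, C, N) array: output matrix
// (H*W*N) x (9*C), rows ordered pixel-fastest then sample, columns ordered
// patch-offset-fastest (dx, then dy) then channel.
// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3_cpp(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericMatrix out(HW * N, 9 * C);
  const double *xp = REAL(x);
  double *op = REAL(out);
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int o = (di + 1) + 3 * (dj + 1);
        double *col = op + ((R_xlen_t)(o + 9 * c)) * (HW * N);
        for (int n = 0; n < N; ++n) {
          const double *src = xp + ((R_xlen_t)n * C + c) * HW;
          double *dst = col + (R_xlen_t)n * HW;
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj;
            double *d = dst + (R_xlen_t)j * H;
            if (jj < 0 || jj >= W) {
              std::fill(d, d + H, 0.0);
              continue;
            }
            const double *s = src + (R_xlen_t)jj * H;
            const int lo = std::max(0, -di), hi = std::min(H, H - di);
            if (lo > 0) std::fill(d, d + lo, 0.0);
            for (int i = lo; i < hi; ++i) d[i] = s[i + di];
            if (hi < H) std::fill(d + hi, d + H, 0.0);
          }
        }
      }
    }
  }
  return out;
}

static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double ix, double iy, double iz) {
  // ix/iy/iz are 0-based fractional voxel coordinates, clamped to support.
  ix = std::min(std::max(ix, 0.0), (double)nx - 1);
  iy = std::min(std::max(iy, 0.0), (double)ny - 1);
  iz = std::min(std::max(iz, 0.0), (double)nz - 1);
  const int x0 = std::min((int)ix, nx - 2 >= 0 ? nx - 2 : 0);
  const int y0 = std::min((int)iy, ny - 2 >= 0 ? ny - 2 : 0);
  const int z0 = std::min((int)iz, nz - 2 >= 0 ? nz - 2 : 0);
  const double fx = nx > 1 ? ix - x0 : 0.0;
  const double fy = ny > 1 ? iy - y0 : 0.0;
  const double fz = nz > 1 ? iz - z0 : 0.0;
  const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
            z1 = std::min(z0 + 1, nz - 1);
#define AT(a, b, c) v[(R_xlen_t)(c)*nx * ny + (R_xlen_t)(b)*nx + (a)]
  return AT(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
         AT(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
         AT(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
         AT(x1, y1, z0) * fx * fy * (1 - fz) +
         AT(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
         AT(x1, y0, z1) * fx * (1 - fy) * fz +
         AT(x0, y1, z1) * (1 - fx) * fy * fz + AT(x1, y1, z1) * fx * fy * fz;
#undef AT
}

// Mean inhale intensity over the volume of interest of each exhale voxel:
// the exhale voxel cell's 8 corners are mapped by x + u(x); inhale voxel
// centres inside the mapped cell's bounding box (restricted to the inhale
// lung mask when one is supplied) are averaged. An empty set falls back to
// trilinear sampling at the mapped cell centre.
// voxel_idx: 0-based linear indices (exhale grid) to evaluate.
// in_mask: logical vector over the inhale grid, or NULL for no restriction.
// [[Rcpp::export(name = ".voi_mean_inhale")]]
NumericVector voi_mean_inhale_cpp(NumericVector inhale, IntegerVector in_dims,
                                  NumericVector in_spacing, NumericVector in_origin,
                                  NumericVector dvf, IntegerVector ex_dims,
                                  NumericVector ex_spacing, NumericVector ex_origin,
                                  IntegerVector voxel_idx,
                                  Nullable<LogicalVector> in_mask = R_NilValue) {
  const int *msk = nullptr;
  LogicalVector mvec;
  if (in_mask.isNotNull()) {
    mvec = in_mask.get();
    msk = LOGICAL(mvec);
  }
  const int nx = ex_dims[0], ny = ex_dims[1], nz = ex_dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int inx = in_dims[0], iny = in_dims[1], inz = in_dims[2];
  const double *uin = REAL(dvf);
  const double *iv = REAL(inhale);
  NumericVector out(voxel_idx.size());
  for (R_xlen_t s = 0; s < voxel_idx.size(); ++s) {
    const R_xlen_t v = voxel_idx[s];
    const int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    for (int c = 0; c < 8; ++c) {
      const double ci = i + ((c & 1) ? 0.5 : -0.5);
      const double cj = j + ((c & 2) ? 0.5 : -0.5);
      const double ck = k + ((c & 4) ? 0.5 : -0.5);
      double p[3] = {ex_origin[0] + ci * ex_spacing[0],
                     ex_origin[1] + cj * ex_spacing[1],
                     ex_origin[2] + ck * ex_spacing[2]};
      for (int a = 0; a < 3; ++a) {
        const double ua = tri_sample(uin + (R_xlen_t)a * nvox, nx, ny, nz, ci, cj, ck);
        const double m = p[a] + ua;
        if (m < lo[a]) lo[a] = m;
        if (m > hi[a]) hi[a] = m;
      }
    }
    // inhale voxel centres inside the bounding box
    int i0[3], i1[3];
    const int idm[3] = {inx, iny, inz};
    bool empty = false;
    for (int a = 0; a < 3; ++a) {
      i0[a] = (int)std::ceil((lo[a] - in_origin[a]) / in_spacing[a] - 1e-9);
      i1[a] = (int)std::floor((hi[a] - in_origin[a]) / in_spacing[a] + 1e-9);
      if (i0[a] < 0) i0[a] = 0;
      if (i1[a] > idm[a] - 1) i1[a] = idm[a] - 1;
      if (i0[a] > i1[a]) empty = true;
    }
    if (!empty) {
      double acc = 0.0;
      R_xlen_t cnt = 0;
      for (int kk = i0[2]; kk <= i1[2]; ++kk)
        for (int jj = i0[1]; jj <= i1[1]; ++jj)
          for (int ii = i0[0]; ii <= i1[0]; ++ii) {
            const R_xlen_t q = (R_xlen_t)kk * inx * iny + (R_xlen_t)jj * inx + ii;
            if (msk && !msk[q]) continue;
            acc += iv[q];
            ++cnt;
          }
      if (cnt > 0)
        out[s] = acc / cnt;
      else
        empty = true;
    }
    if (empty) {
      // fallback: trilinear sample at the mapped voxel centre
      double p[3];
      for (int a = 0; a < 3; ++a) {
        const double ua = uin[(R_xlen_t)a * nvox + v];
        const double pc = ex_origin[a] +
                          (a == 0 ? i : (a == 1 ? j : k)) * ex_spacing[a];
        p[a] = pc + ua;
      }
      out[s] = tri_sample(iv, inx, iny, inz,
                          (p[0] - in_origin[0]) / in_spacing[0],
                          (p[1] - in_origin[1]) / in_spacing[1],
                          (p[2] - in_origin[2]) / in_spacing[2]);
    }
  }
  return out;
}
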