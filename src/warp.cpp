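#include <Rcpp.h>
using namespace Rcpp;

// Backward-warping resampler shared by rotation and elastic deformation.
// For each output voxel p (0-based), the source location is
//   q = A * (p - c) + c + shift + disp[p]
// with c the volume centre. Sampling is trilinear or nearest-neighbour;
// source locations outside the grid yield `fill`.
// [[Rcpp::export]]
NumericVector cpp_warp(const NumericVector& vol, const IntegerVector& dims,
                       const NumericMatrix& A, const NumericVector& shift,
                       SEXP disp, const bool nearest, const double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const bool has_disp = disp != R_NilValue;
  const double* dvec = has_disp ? REAL(disp) : nullptr;
  const double* v = REAL(vol);

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        const double px = i - cx, py = j - cy, pz = k - cz;
        double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + cx + shift[0];
        double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + cy + shift[1];
        double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + cz + shift[2];
        if (has_disp) {
          qx += dvec[idx];
          qy += dvec[idx + n];
          qz += dvec[idx + 2 * n];
        }
        if (nearest) {
          const int ix = (int)std::lround(qx), iy = (int)std::lround(qy),
                    iz = (int)std::lround(qz);
          if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
            out[idx] = fill;
          } else {
            out[idx] = v[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
          }
        } else {
          const int x0 = (int)std::floor(qx), y0 = (int)std::floor(qy),
                    z0 = (int)std::floor(qz);
          if (x0 < -1 || x0 > nx - 1 || y0 < -1 || y0 > ny - 1 || z0 < -1 ||
              z0 > nz - 1) {
            out[idx] = fill;
            continue;
          }
          const double fx = qx - x0, fy = qy - y0, fz = qz - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz) {
            const int zz = z0 + dz;
            const double wz = dz ? fz : 1.0 - fz;
            if (wz == 0.0) continue;
            for (int dy = 0; dy <= 1; ++dy) {
              const int yy = y0 + dy;
              const double wy = dy ? fy : 1.0 - fy;
              if (wy == 0.0) continue;
              for (int dx = 0; dx <= 1; ++dx) {
                const int xx = x0 + dx;
                const double wx = dx ? fx : 1.0 - fx;
                if (wx == 0.0) continue;
                double val;
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                    zz >= nz) {
                  val = fill;
                } else {
                  val = v[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
                }
                acc += wx * wy * wz * val;
              }
            }
          }
          out[idx] = acc;
        }
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing with reflecting boundaries; kernel truncated
// at 3 sigma. sigma in voxels, isotropic in index space.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(const NumericVector& vol,
                               const IntegerVector& dims, const double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + r];
  }
  for (double& w : ker) w /= s;

  NumericVector cur = clone(vol);
  NumericVector tmp(n);
  const int nn[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};

  for (int ax = 0; ax < 3; ++ax) {
    const int len = nn[ax];
    const R_xlen_t st = stride[ax];
    for (R_xlen_t idx = 0; idx < n; ++idx) {
      // coordinate along axis `ax`
      int coord;
      if (ax == 0) coord = (int)(idx % nx);
      else if (ax == 1) coord = (int)((idx / nx) % ny);
      else coord = (int)(idx / ((R_xlen_t)nx * ny));
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int c = coord + t;
        if (c < 0) c = -c - 1;            // reflect
        if (c >= len) c = 2 * len - c - 1;
        acc += ker[t + r] * cur[idx + (R_xlen_t)(c - coord) * st];
      }
      tmp[idx] = acc;
    }
    std::copy(tmp.begin(), tmp.end(), cur.begin());
  }
  return cur;
}
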