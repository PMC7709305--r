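#include <Rcpp.h>
using namespace Rcpp;

// im2col for 3D same-padded convolution. Input x is an (nx, ny, nz, C)
// column-major array; output matrix has k^3*C rows (row index
// r = ((c*k + kz)*k + ky)*k + kx) and nx*ny*nz columns, one per voxel.
// Out-of-bounds taps are zero. BLAS matrix products against a
// (Cout x k^3*Cin) weight matrix then implement the convolution.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(const NumericVector& x, const IntegerVector& dims,
                          const int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int pad = (k - 1) / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(k * k * k * C, n);
  const double* xv = REAL(x);
  double* ov = REAL(out);
  const int kr = k * k * k;
  const R_xlen_t nrow = (R_xlen_t)kr * C;

  for (int c = 0; c < C; ++c) {
    const double* xc = xv + (R_xlen_t)c * n;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const R_xlen_t row = ((R_xlen_t)c * k + kz) * k * k + ky * k + kx;
          const int dx = kx - pad, dy = ky - pad, dz = kz - pad;
          R_xlen_t col = 0;
          for (int z = 0; z < nz; ++z) {
            const int sz = z + dz;
            for (int y = 0; y < ny; ++y) {
              const int sy = y + dy;
              const bool okyz = sz >= 0 && sz < nz && sy >= 0 && sy < ny;
              const R_xlen_t base =
                  okyz ? ((R_xlen_t)nx * (sy + (R_xlen_t)ny * sz)) : 0;
              for (int xq = 0; xq < nx; ++xq, ++col) {
                const int sx = xq + dx;
                double val = 0.0;
                if (okyz && sx >= 0 && sx < nx) val = xc[sx + base];
                ov[row + nrow * col] = val;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col3: scatter-accumulate columns back into an
// (nx, ny, nz, C) array. Used for the gradient with respect to the input.
// [[Rcpp::export]]
NumericVector cpp_col2im3(const NumericMatrix& cols, const IntegerVector& dims,
                          const int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int pad = (k - 1) / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out((R_xlen_t)n * C);
  const double* cv = REAL(cols);
  double* ov = REAL(out);
  const R_xlen_t nrow = cols.nrow();

  for (int c = 0; c < C; ++c) {
    double* oc = ov + (R_xlen_t)c * n;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const R_xlen_t row = ((R_xlen_t)c * k + kz) * k * k + ky * k + kx;
          const int dx = kx - pad, dy = ky - pad, dz = kz - pad;
          R_xlen_t col = 0;
          for (int z = 0; z < nz; ++z) {
            const int sz = z + dz;
            for (int y = 0; y < ny; ++y) {
              const int sy = y + dy;
              const bool okyz = sz >= 0 && sz < nz && sy >= 0 && sy < ny;
              for (int xq = 0; xq < nx; ++xq, ++col) {
                const int sx = xq + dx;
                if (okyz && sx >= 0 && sx < nx) {
                  oc[sx + (R_xlen_t)nx * (sy + (R_xlen_t)ny * sz)] +=
                      cv[row + nrow * col];
                }
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// 2x2x2 max pooling, stride 2, per channel. Returns pooled values and the
// 0-based linear argmax indices into the input array (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool3_fwd(const NumericVector& x, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const R_xlen_t no = (R_xlen_t)ox * oy * oz * C;
  NumericVector y(no);
  NumericVector idx(no);
  const double* xv = REAL(x);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    const R_xlen_t cb = (R_xlen_t)c * n;
    for (int z = 0; z < oz; ++z) {
      for (int yq = 0; yq < oy; ++yq) {
        for (int xq = 0; xq < ox; ++xq, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          R_xlen_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const R_xlen_t ii =
                    cb + (2 * xq + dx) +
                    (R_xlen_t)nx * ((2 * yq + dy) + (R_xlen_t)ny * (2 * z + dz));
                if (xv[ii] > best) {
                  best = xv[ii];
                  bi = ii;
                }
              }
          y[o] = best;
          idx[o] = (double)bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3_bwd(const NumericVector& dy,
                               const NumericVector& idx,
                               const IntegerVector& in_dims) {
  const R_xlen_t n =
      (R_xlen_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector dx(n);
  for (R_xlen_t o = 0; o < dy.size(); ++o) dx[(R_xlen_t)idx[o]] += dy[o];
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint (block sum).
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(const NumericVector& x,
                                const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericVector y((R_xlen_t)ox * oy * oz * C);
  const double* xv = REAL(x);
  double* yv = REAL(y);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, no = (R_xlen_t)ox * oy * oz;
  for (int c = 0; c < C; ++c) {
    for (int z = 0; z < oz; ++z)
      for (int yq = 0; yq < oy; ++yq)
        for (int xq = 0; xq < ox; ++xq) {
          yv[(R_xlen_t)c * no + xq + (R_xlen_t)ox * (yq + (R_xlen_t)oy * z)] =
              xv[(R_xlen_t)c * n + (xq / 2) +
                 (R_xlen_t)nx * ((yq / 2) + (R_xlen_t)ny * (z / 2))];
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(const NumericVector& dy,
                                const IntegerVector& in_dims) {
  const int nx = in_dims[0], ny = in_dims[1], nz = in_dims[2], C = in_dims[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericVector dx((R_xlen_t)nx * ny * nz * C);
  const double* dv = REAL(dy);
  double* xv = REAL(dx);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz, no = (R_xlen_t)ox * oy * oz;
  for (int c = 0; c < C; ++c) {
    for (int z = 0; z < oz; ++z)
      for (int yq = 0; yq < oy; ++yq)
        for (int xq = 0; xq < ox; ++xq) {
          xv[(R_xlen_t)c * n + (xq / 2) +
             (R_xlen_t)nx * ((yq / 2) + (R_xlen_t)ny * (z / 2))] +=
              dv[(R_xlen_t)c * no + xq + (R_xlen_t)ox * (yq + (R_xlen_t)oy * z)];
        }
  }
  return dx;
}
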