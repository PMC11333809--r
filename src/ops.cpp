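// Low-level 3D image and network operators.
// Array layout follows R: column-major, index = x + X*(y + Y*(z + Z*c)).
// Convolutions use 3x3x3 kernels with "same" zero padding, evaluated as
// im2col + GEMM in z-slabs to bound memory. The im2col column order is
// col = ci*27 + ((dz+1)*3 + (dy+1))*3 + (dx+1), matched by the R side when
// it reshapes weight tensors.

#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

static const int SLAB = 16;  // z-slices per im2col chunk

// single precision throughout the convolution path: halves the im2col
// memory traffic and doubles SIMD width; ample precision for NN training
static inline void fill_im2col(const double* x, int X, int Y, int Z, int Cin,
                               int z0, int nz, arma::fmat& K) {
  const int XY = X * Y;
  const long plane = (long)XY * Z;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (long)ci * plane;
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          int col = ci * 27 + ((dz + 1) * 3 + (dy + 1)) * 3 + (dx + 1);
          float* Kc = K.colptr(col);
          for (int z = 0; z < nz; ++z) {
            int zz = z0 + z + dz;
            for (int y = 0; y < Y; ++y) {
              int yy = y + dy;
              float* row = Kc + (long)(z * Y + y) * X;
              if (zz < 0 || zz >= Z || yy < 0 || yy >= Y) {
                std::fill(row, row + X, 0.0f);
                continue;
              }
              const double* src = xc + (long)zz * XY + (long)yy * X;
              int xlo = std::max(0, -dx), xhi = std::min(X, X - dx);
              for (int xx = 0; xx < xlo; ++xx) row[xx] = 0.0f;
              for (int xx = xlo; xx < xhi; ++xx) row[xx] = (float)src[xx + dx];
              for (int xx = xhi; xx < X; ++xx) row[xx] = 0.0f;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             const arma::mat& w, const arma::vec& b) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  int Cout = w.n_cols;
  if ((int)w.n_rows != 27 * Cin) stop("weight shape mismatch");
  arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b.t());
  NumericVector out((long)X * Y * Z * Cout);
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  const long plane = (long)X * Y * Z;
  for (int z0 = 0; z0 < Z; z0 += SLAB) {
    int nz = std::min(SLAB, Z - z0);
    long n = (long)X * Y * nz;
    arma::fmat K(n, 27 * Cin);
    fill_im2col(REAL(x), X, Y, Z, Cin, z0, nz, K);
    arma::fmat O = K * wf;  // n x Cout
    O.each_row() += bf;
    for (int co = 0; co < Cout; ++co) {
      double* dst = REAL(out) + (long)co * plane + (long)z0 * X * Y;
      const float* src = O.colptr(co);
      for (long i = 0; i < n; ++i) dst[i] = (double)src[i];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    const arma::mat& w, NumericVector gout) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  int Cout = w.n_cols;
  const int XY = X * Y;
  const long plane = (long)XY * Z;
  arma::fmat wf = arma::conv_to<arma::fmat>::from(w);
  NumericVector gx((long)plane * Cin);
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  arma::fmat gw(27 * Cin, Cout, arma::fill::zeros);
  arma::fvec gb(Cout, arma::fill::zeros);
  for (int z0 = 0; z0 < Z; z0 += SLAB) {
    int nz = std::min(SLAB, Z - z0);
    long n = (long)XY * nz;
    arma::fmat K(n, 27 * Cin);
    fill_im2col(REAL(x), X, Y, Z, Cin, z0, nz, K);
    arma::fmat G(n, Cout);
    for (int co = 0; co < Cout; ++co) {
      const double* src = REAL(gout) + (long)co * plane + (long)z0 * XY;
      float* dst = G.colptr(co);
      for (long i = 0; i < n; ++i) dst[i] = (float)src[i];
    }
    gw += K.t() * G;
    gb += arma::sum(G, 0).t();
    arma::fmat gK = G * wf.t();  // n x 27*Cin, scatter back
    for (int ci = 0; ci < Cin; ++ci) {
      double* gxc = REAL(gx) + (long)ci * plane;
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            int col = ci * 27 + ((dz + 1) * 3 + (dy + 1)) * 3 + (dx + 1);
            const float* Kc = gK.colptr(col);
            for (int z = 0; z < nz; ++z) {
              int zz = z0 + z + dz;
              if (zz < 0 || zz >= Z) continue;
              for (int y = 0; y < Y; ++y) {
                int yy = y + dy;
                if (yy < 0 || yy >= Y) continue;
                const float* row = Kc + (long)(z * Y + y) * X;
                double* dst = gxc + (long)zz * XY + (long)yy * X;
                int xlo = std::max(0, -dx), xhi = std::min(X, X - dx);
                for (int xx = xlo; xx < xhi; ++xx) dst[xx + dx] += (double)row[xx];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx,
                      _["gw"] = arma::conv_to<arma::mat>::from(gw),
                      _["gb"] = arma::conv_to<arma::vec>::from(gb));
}

// [[Rcpp::export]]
List cpp_maxpool3d(NumericVector x, IntegerVector xdim) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool requires even spatial dims");
  int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector y((long)Xo * Yo * Zo * C);
  IntegerVector idx((long)Xo * Yo * Zo * C);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  const double* xp = REAL(x);
  long o = 0;
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx, ++o) {
          double best = -HUGE_VAL; long bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                long i = (long)(2 * xx + dx) +
                         (long)X * ((2 * yy + dy) +
                         (long)Y * ((2 * z + dz) + (long)Z * c));
                if (xp[i] > best) { best = xp[i]; bidx = i; }
              }
          y[o] = best;
          idx[o] = (int)bidx;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(IntegerVector idx, NumericVector gy,
                                IntegerVector xdim) {
  NumericVector gx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (long i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3d(NumericVector x, IntegerVector xdim) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector y((long)Xo * Yo * Zo * C);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy) {
        const double* src = xp + (long)(z / 2) * X * Y + (long)(yy / 2) * X +
                            (long)c * X * Y * Z;
        double* dst = yp + (long)z * Xo * Yo + (long)yy * Xo +
                      (long)c * (long)Xo * Yo * Zo;
        for (int xx = 0; xx < Xo; ++xx) dst[xx] = src[xx / 2];
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3d_bwd(NumericVector gy, IntegerVector ydim) {
  int Xo = ydim[0], Yo = ydim[1], Zo = ydim[2], C = ydim[3];
  int X = Xo / 2, Y = Yo / 2, Z = Zo / 2;
  NumericVector gx((long)X * Y * Z * C);
  gx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  const double* gp = REAL(gy);
  double* xp = REAL(gx);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy) {
        const double* src = gp + (long)z * Xo * Yo + (long)yy * Xo +
                            (long)c * (long)Xo * Yo * Zo;
        double* dst = xp + (long)(z / 2) * X * Y + (long)(yy / 2) * X +
                      (long)c * X * Y * Z;
        for (int xx = 0; xx < Xo; ++xx) dst[xx / 2] += src[xx];
      }
  return gx;
}

static void blur_axis(std::vector<double>& buf, NumericVector& a,
                      int X, int Y, int Z, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (auto& v : k) v /= s;
  int n[3] = {X, Y, Z};
  long stride[3] = {1, X, (long)X * Y};
  int len = n[axis];
  long st = stride[axis];
  // iterate over all lines along `axis`
  int u = (axis + 1) % 3, v = (axis + 2) % 3;
  double* ap = REAL(a);
  for (int i = 0; i < n[u]; ++i)
    for (int j = 0; j < n[v]; ++j) {
      double* line = ap + (long)i * stride[u] + (long)j * stride[v];
      for (int t = 0; t < len; ++t) buf[t] = line[(long)t * st];
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
        for (int q = lo; q <= hi; ++q) acc += buf[q] * k[q - t + r];
        line[(long)t * st] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector x, IntegerVector xdim,
                               NumericVector sigma_vox) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2];
  NumericVector out = clone(x);
  out.attr("dim") = xdim;
  std::vector<double> buf(std::max(X, std::max(Y, Z)));
  blur_axis(buf, out, X, Y, Z, 0, sigma_vox[0]);
  blur_axis(buf, out, X, Y, Z, 1, sigma_vox[1]);
  blur_axis(buf, out, X, Y, Z, 2, sigma_vox[2]);
  return out;
}

// Resample: for each output voxel o (0-based), input coords p = A[,1:3] %*% o + A[,4];
// trilinear (or nearest) interpolation, outside-grid = 0.
// [[Rcpp::export]]
NumericVector cpp_affine_resample3d(NumericVector x, IntegerVector xdim,
                                    NumericMatrix A, IntegerVector outdim,
                                    bool nearest) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2];
  int Xo = outdim[0], Yo = outdim[1], Zo = outdim[2];
  NumericVector out((long)Xo * Yo * Zo);
  out.attr("dim") = outdim;
  const double* xp = REAL(x);
  double* op = REAL(out);
  long o = 0;
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int xx = 0; xx < Xo; ++xx, ++o) {
        double px = A(0, 0) * xx + A(0, 1) * y + A(0, 2) * z + A(0, 3);
        double py = A(1, 0) * xx + A(1, 1) * y + A(1, 2) * z + A(1, 3);
        double pz = A(2, 0) * xx + A(2, 1) * y + A(2, 2) * z + A(2, 3);
        if (nearest) {
          int ix = (int)std::lround(px), iy = (int)std::lround(py), iz = (int)std::lround(pz);
          if (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 || iz >= Z) { op[o] = 0; continue; }
          op[o] = xp[(long)ix + (long)X * (iy + (long)Y * iz)];
        } else {
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          double acc = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int ix = x0 + dx, iy = y0 + dy, iz = z0 + dz;
                if (ix < 0 || ix >= X || iy < 0 || iy >= Y || iz < 0 || iz >= Z) continue;
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                acc += w * xp[(long)ix + (long)X * (iy + (long)Y * iz)];
              }
          op[o] = acc;
        }
      }
  return out;
}

// 26-connected component labelling by BFS flood fill; labels 1..K in
// discovery order (scan order = increasing linear index), so the component
// containing the lowest linear voxel index gets label 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components26(IntegerVector mask, IntegerVector dims) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  long n = (long)X * Y * Z;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<long> stack;
  for (long start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      long cur = stack.back(); stack.pop_back();
      int cx = cur % X, cy = (cur / X) % Y, cz = cur / ((long)X * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int nx = cx + dx, ny = cy + dy, nz = cz + dz;
            if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
            long ni = (long)nx + (long)X * (ny + (long)Y * nz);
            if (mask[ni] && !lab[ni]) { lab[ni] = next; stack.push_back(ni); }
          }
    }
  }
  return lab;
}

// binary dilation with a Euclidean ball of radius r voxels
// [[Rcpp::export]]
IntegerVector cpp_dilate3d(IntegerVector mask, IntegerVector dims, double r) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  long n = (long)X * Y * Z;
  IntegerVector out(n);
  out.attr("dim") = dims;
  int ri = (int)std::floor(r);
  double r2 = r * r;
  for (long i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int cx = i % X, cy = (i / X) % Y, cz = i / ((long)X * Y);
    for (int dz = -ri; dz <= ri; ++dz)
      for (int dy = -ri; dy <= ri; ++dy)
        for (int dx = -ri; dx <= ri; ++dx) {
          if (dx * dx + dy * dy + dz * dz > r2) continue;
          int nx = cx + dx, ny = cy + dy, nz = cz + dz;
          if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
          out[(long)nx + (long)X * (ny + (long)Y * nz)] = 1;
        }
  }
  return out;
}
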