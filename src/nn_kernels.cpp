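// Neural-network kernels for the 3D U-net: same-padded 3D convolution
// (im2col + BLAS gemm, one axial slice at a time to bound memory), max
// pooling with argmax bookkeeping, instance normalization, and trilinear
// up-sampling with its exact adjoint. Feature tensors are channel-last
// R arrays with dim (X, Y, Z, C); weights are (kx, ky, kz, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector tensor_dim(const NumericVector& x, int need) {
  IntegerVector d = x.attr("dim");
  if (d.size() != need) stop("expected a %d-dimensional array", need);
  return d;
}

// Gather the im2col matrix for output slices [z0, z0+zc), laid out
// ((XY*zc) x K) with K = kx*ky*kz*Cin so every inner copy is contiguous
// in x and gemms stay large.
static void im2col_chunk(const double* x, int X, int Y, int Z, int Cin,
                         int kx, int ky, int kz, int z0, int zc,
                         arma::mat& col) {
  const int XY = X * Y;
  const int hx = kx / 2, hy = ky / 2, hz = kz / 2;
  double* cp = col.memptr();
  const size_t NR = (size_t)XY * zc;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * XY * Z;
    for (int dz = 0; dz < kz; ++dz) {
      for (int dy = 0; dy < ky; ++dy) {
        int oy = dy - hy;
        for (int dx = 0; dx < kx; ++dx) {
          int ox = dx - hx;
          int k = dx + kx * (dy + ky * (dz + kz * c));
          double* colk = cp + (size_t)k * NR;
          int y0 = std::max(0, -oy), y1 = std::min(Y, Y - oy);
          int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
          for (int zz = 0; zz < zc; ++zz) {
            int zi = z0 + zz + dz - hz;
            double* colz = colk + (size_t)zz * XY;
            if (zi < 0 || zi >= Z) {       // whole plane is padding
              std::fill(colz, colz + XY, 0.0);
              continue;
            }
            const double* xz = xc + (size_t)zi * XY;
            if (y0 > 0) std::fill(colz, colz + (size_t)y0 * X, 0.0);
            if (y1 < Y)
              std::fill(colz + (size_t)y1 * X, colz + (size_t)Y * X, 0.0);
            for (int yy = y0; yy < y1; ++yy) {
              double* row = colz + (size_t)yy * X;
              if (x0 > 0) std::fill(row, row + x0, 0.0);
              if (x1 < X) std::fill(row + x1, row + X, 0.0);
              std::copy(xz + (size_t)(yy + oy) * X + (x0 + ox),
                        xz + (size_t)(yy + oy) * X + (x1 + ox), row + x0);
            }
          }
        }
      }
    }
  }
}

// Adjoint of im2col_chunk: scatter-add ((XY*zc) x K) back into gx.
static void col2im_chunk(const arma::mat& col, double* gx, int X, int Y,
                         int Z, int Cin, int kx, int ky, int kz, int z0,
                         int zc) {
  const int XY = X * Y;
  const int hx = kx / 2, hy = ky / 2, hz = kz / 2;
  const double* cp = col.memptr();
  const size_t NR = (size_t)XY * zc;
  for (int c = 0; c < Cin; ++c) {
    double* xc = gx + (size_t)c * XY * Z;
    for (int dz = 0; dz < kz; ++dz) {
      for (int dy = 0; dy < ky; ++dy) {
        int oy = dy - hy;
        for (int dx = 0; dx < kx; ++dx) {
          int ox = dx - hx;
          int k = dx + kx * (dy + ky * (dz + kz * c));
          const double* colk = cp + (size_t)k * NR;
          int y0 = std::max(0, -oy), y1 = std::min(Y, Y - oy);
          int x0 = std::max(0, -ox), x1 = std::min(X, X - ox);
          for (int zz = 0; zz < zc; ++zz) {
            int zi = z0 + zz + dz - hz;
            if (zi < 0 || zi >= Z) continue;
            double* xz = xc + (size_t)zi * XY;
            const double* colz = colk + (size_t)zz * XY;
            for (int yy = y0; yy < y1; ++yy) {
              double* dst = xz + (size_t)(yy + oy) * X + (x0 + ox);
              const double* src = colz + (size_t)yy * X + x0;
              int n = x1 - x0;
              for (int xx = 0; xx < n; ++xx) dst[xx] += src[xx];
            }
          }
        }
      }
    }
  }
}

// chunk height keeping the im2col buffer around 128 MB
static int chunk_height(int XY, int K, int Z) {
  double cap = 16.0e6;  // doubles
  int zc = (int)(cap / ((double)XY * K));
  if (zc < 1) zc = 1;
  if (zc > Z) zc = Z;
  return zc;
}

// persistent scratch buffers (single-threaded R session)
static std::vector<double>& scratch(int which, size_t need) {
  static std::vector<double> bufs[3];
  if (bufs[which].size() < need) bufs[which].resize(need);
  return bufs[which];
}

// [[Rcpp::export(rng = false)]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx_ = tensor_dim(x, 4), dw = tensor_dim(w, 5);
  int X = dx_[0], Y = dx_[1], Z = dx_[2], Cin = dx_[3];
  int kx = dw[0], ky = dw[1], kz = dw[2], Cout = dw[4];
  if (dw[3] != Cin) stop("weight Cin does not match input channels");
  const int XY = X * Y, K = kx * ky * kz * Cin;
  NumericVector out((size_t)XY * Z * Cout);
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  arma::mat W(const_cast<double*>(w.begin()), K, Cout, false, true);
  int zc = chunk_height(XY, K, Z);
  for (int z0 = 0; z0 < Z; z0 += zc) {
    int h = std::min(zc, Z - z0);
    size_t nr = (size_t)XY * h;
    arma::mat col(scratch(0, nr * K).data(), nr, K, false, true);
    arma::mat res(scratch(1, nr * Cout).data(), nr, Cout, false, true);
    im2col_chunk(x.begin(), X, Y, Z, Cin, kx, ky, kz, z0, h, col);
    res = col * W;
    size_t n = (size_t)XY * h;
    for (int co = 0; co < Cout; ++co) {
      double* dst = out.begin() + (size_t)co * XY * Z + (size_t)z0 * XY;
      const double* src = res.colptr(co);
      double bc = b[co];
      for (size_t i = 0; i < n; ++i) dst[i] = src[i] + bc;
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gy,
               bool need_gx = true) {
  IntegerVector dx_ = tensor_dim(x, 4), dw = tensor_dim(w, 5);
  int X = dx_[0], Y = dx_[1], Z = dx_[2], Cin = dx_[3];
  int kx = dw[0], ky = dw[1], kz = dw[2], Cout = dw[4];
  const int XY = X * Y, K = kx * ky * kz * Cin;
  NumericVector gw((size_t)K * Cout), gb(Cout);
  gw.attr("dim") = dw;
  NumericVector gx(need_gx ? (size_t)XY * Z * Cin : 0);
  if (need_gx) gx.attr("dim") = dx_;
  arma::mat W(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  int zc = chunk_height(XY, K, Z);
  for (int z0 = 0; z0 < Z; z0 += zc) {
    int h = std::min(zc, Z - z0);
    size_t n = (size_t)XY * h;
    arma::mat col(scratch(0, n * K).data(), n, K, false, true);
    arma::mat gys(scratch(1, n * Cout).data(), n, Cout, false, true);
    arma::mat colg(scratch(2, n * K).data(), n, K, false, true);
    for (int co = 0; co < Cout; ++co) {
      const double* src = gy.begin() + (size_t)co * XY * Z + (size_t)z0 * XY;
      std::copy(src, src + n, gys.colptr(co));
      double s = 0;
      for (size_t i = 0; i < n; ++i) s += src[i];
      gb[co] += s;
    }
    im2col_chunk(x.begin(), X, Y, Z, Cin, kx, ky, kz, z0, h, col);
    GW += col.t() * gys;
    if (need_gx) {
      colg = gys * W.t();
      col2im_chunk(colg, gx.begin(), X, Y, Z, Cin, kx, ky, kz, z0, h);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(rng = false)]]
List maxpool3d_fw(NumericVector x, int fx, int fy, int fz) {
  IntegerVector d = tensor_dim(x, 4);
  int X = d[0], Y = d[1], Z = d[2], C = d[3];
  if (X % fx || Y % fy || Z % fz) stop("pooling factor does not divide shape");
  int Xo = X / fx, Yo = Y / fy, Zo = Z / fz;
  NumericVector y((size_t)Xo * Yo * Zo * C);
  IntegerVector idx((size_t)Xo * Yo * Zo * C);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  const double* xp = x.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * X * Y * Z;
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                size_t ii = (size_t)(zo * fz + dz) * X * Y +
                            (size_t)(yo * fy + dy) * X + (xo * fx + dx);
                if (xc[ii] > best) { best = xc[ii]; bi = ii; }
              }
          y[o] = best;
          idx[o] = (int)bi;  // spatial index within channel block
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(rng = false)]]
NumericVector maxpool3d_bw(NumericVector gy, IntegerVector idx,
                           IntegerVector in_dim) {
  int X = in_dim[0], Y = in_dim[1], Z = in_dim[2], C = in_dim[3];
  NumericVector gx((size_t)X * Y * Z * C);
  gx.attr("dim") = in_dim;
  size_t n_out = gy.size() / C;
  for (int c = 0; c < C; ++c) {
    double* gxc = gx.begin() + (size_t)c * X * Y * Z;
    const double* gyc = gy.begin() + (size_t)c * n_out;
    const int* ic = idx.begin() + (size_t)c * n_out;
    for (size_t i = 0; i < n_out; ++i) gxc[ic[i]] += gyc[i];
  }
  return gx;
}

// Instance norm with optionally fused ReLU on the output.
// [[Rcpp::export(rng = false)]]
List instnorm_fw(NumericVector x, NumericVector gamma, NumericVector beta,
                 double eps = 1e-5, bool relu = false) {
  IntegerVector d = tensor_dim(x, 4);
  size_t N = (size_t)d[0] * d[1] * d[2];
  int C = d[3];
  NumericVector y(x.size()), mu(C), istd(C);
  y.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + N * c;
    double m = 0;
    for (size_t i = 0; i < N; ++i) m += xc[i];
    m /= (double)N;
    double v = 0;
    for (size_t i = 0; i < N; ++i) { double t = xc[i] - m; v += t * t; }
    v /= (double)N;
    double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m; istd[c] = is;
    double g = gamma[c], b = beta[c];
    double* yc = y.begin() + N * c;
    if (relu)
      for (size_t i = 0; i < N; ++i) {
        double t = (xc[i] - m) * is * g + b;
        yc[i] = t > 0 ? t : 0;
      }
    else
      for (size_t i = 0; i < N; ++i) yc[i] = (xc[i] - m) * is * g + b;
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// Backward of instance norm; with relu = true, gy is first masked by the
// recomputed post-activation sign (the fused ReLU's gradient).
// [[Rcpp::export(rng = false)]]
List instnorm_bw(NumericVector x, NumericVector gamma, NumericVector beta,
                 NumericVector mu, NumericVector istd, NumericVector gy,
                 bool relu = false) {
  IntegerVector d = tensor_dim(x, 4);
  size_t N = (size_t)d[0] * d[1] * d[2];
  int C = d[3];
  NumericVector gx(x.size()), ggamma(C), gbeta(C);
  gx.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + N * c;
    const double* gc = gy.begin() + N * c;
    double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
    double sg = 0, sgx = 0;
    for (size_t i = 0; i < N; ++i) {
      double xh = (xc[i] - m) * is;
      double gi = gc[i];
      if (relu && xh * g + b <= 0) gi = 0;
      sg += gi;
      sgx += gi * xh;
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    double mg = sg / (double)N, mgx = sgx / (double)N;
    double* gxc = gx.begin() + N * c;
    for (size_t i = 0; i < N; ++i) {
      double xh = (xc[i] - m) * is;
      double gi = gc[i];
      if (relu && xh * g + b <= 0) gi = 0;
      gxc[i] = g * is * (gi - mg - xh * mgx);
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// In-place Adam update; p, m, v are modified directly (the caller owns
// unshared copies).
// [[Rcpp::export(rng = false)]]
void adam_step(NumericVector p, NumericVector g, NumericVector m,
               NumericVector v, double lr, double b1, double b2,
               double corr1, double corr2, double eps) {
  size_t n = p.size();
  double* pp = p.begin();
  const double* gp = g.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  for (size_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] / corr1) / (std::sqrt(vp[i] / corr2) + eps);
  }
}

// Trilinear up-sampling by integer factors (1 or 2 per axis), scale-factor
// coordinate convention in(i_out) = (i_out + 0.5) / f - 0.5, clamped.
struct LinW { int i0, i1; double w0, w1; };

static std::vector<LinW> axis_weights(int n_out, int n_in, int f) {
  std::vector<LinW> w(n_out);
  for (int i = 0; i < n_out; ++i) {
    double p = (i + 0.5) / f - 0.5;
    if (p < 0) p = 0;
    if (p > n_in - 1) p = n_in - 1;
    int i0 = (int)std::floor(p);
    int i1 = std::min(i0 + 1, n_in - 1);
    double t = p - i0;
    w[i] = {i0, i1, 1.0 - t, t};
  }
  return w;
}

// [[Rcpp::export(rng = false)]]
NumericVector upsample3d_fw(NumericVector x, int fx, int fy, int fz) {
  IntegerVector d = tensor_dim(x, 4);
  int X = d[0], Y = d[1], Z = d[2], C = d[3];
  int Xo = X * fx, Yo = Y * fy, Zo = Z * fz;
  auto wx = axis_weights(Xo, X, fx), wy = axis_weights(Yo, Y, fy),
       wz = axis_weights(Zo, Z, fz);
  NumericVector y((size_t)Xo * Yo * Zo * C);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * X * Y * Z;
    double* yc = y.begin() + (size_t)c * Xo * Yo * Zo;
    size_t o = 0;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx, ++o) {
          const LinW &ax = wx[xx], &ay = wy[yy], &az = wz[z];
          double v = 0;
          for (int dz = 0; dz < 2; ++dz) {
            int zi = dz ? az.i1 : az.i0; double wzv = dz ? az.w1 : az.w0;
            if (wzv == 0) continue;
            for (int dy = 0; dy < 2; ++dy) {
              int yi = dy ? ay.i1 : ay.i0; double wyv = dy ? ay.w1 : ay.w0;
              if (wyv == 0) continue;
              for (int dx = 0; dx < 2; ++dx) {
                int xi = dx ? ax.i1 : ax.i0; double wxv = dx ? ax.w1 : ax.w0;
                if (wxv == 0) continue;
                v += wzv * wyv * wxv *
                     xc[(size_t)zi * X * Y + (size_t)yi * X + xi];
              }
            }
          }
          yc[o] = v;
        }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector upsample3d_bw(NumericVector gy, int fx, int fy, int fz,
                            IntegerVector in_dim) {
  int X = in_dim[0], Y = in_dim[1], Z = in_dim[2], C = in_dim[3];
  int Xo = X * fx, Yo = Y * fy, Zo = Z * fz;
  auto wx = axis_weights(Xo, X, fx), wy = axis_weights(Yo, Y, fy),
       wz = axis_weights(Zo, Z, fz);
  NumericVector gx((size_t)X * Y * Z * C);
  gx.attr("dim") = in_dim;
  for (int c = 0; c < C; ++c) {
    double* gxc = gx.begin() + (size_t)c * X * Y * Z;
    const double* gyc = gy.begin() + (size_t)c * Xo * Yo * Zo;
    size_t o = 0;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx, ++o) {
          const LinW &ax = wx[xx], &ay = wy[yy], &az = wz[z];
          double g = gyc[o];
          if (g == 0) continue;
          for (int dz = 0; dz < 2; ++dz) {
            int zi = dz ? az.i1 : az.i0; double wzv = dz ? az.w1 : az.w0;
            if (wzv == 0) continue;
            for (int dy = 0; dy < 2; ++dy) {
              int yi = dy ? ay.i1 : ay.i0; double wyv = dy ? ay.w1 : ay.w0;
              if (wyv == 0) continue;
              for (int dx = 0; dx < 2; ++dx) {
                int xi = dx ? ax.i1 : ax.i0; double wxv = dx ? ax.w1 : ax.w0;
                if (wxv == 0) continue;
                gxc[(size_t)zi * X * Y + (size_t)yi * X + xi] +=
                    g * wzv * wyv * wxv;
              }
            }
          }
        }
  }
  return gx;
}
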