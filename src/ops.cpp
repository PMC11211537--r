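// Low-level numeric kernels: 3D convolution (im2col + GEMM), pooling,
// nearest/trilinear resizing, separable grid resampling, and an exact
// anisotropic Euclidean distance transform.  All volumes are channel-first
// R arrays with dim = (C, D, H, W); the first index varies fastest.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(int c, int d, int h, int w,
                               int C, int D, int H) {
  return (arma::uword)c + (arma::uword)C * ((arma::uword)d +
         (arma::uword)D * ((arma::uword)h + (arma::uword)H * (arma::uword)w));
}

// Reusable buffer backing the im2col matrix, to avoid per-call
// allocation churn in the training loop.
static std::vector<double>& im2col_buf() {
  static std::vector<double> buf;
  return buf;
}

// im2col for SAME zero padding, stride 1, odd kernel sizes.
// Result: K x N with K = C*kd*kh*kw, N = D*H*W (view into a shared
// buffer: valid until the next im2col call).
static arma::mat im2col(const arma::vec& x, int C, int D, int H, int W,
                        int kd, int kh, int kw) {
  const int N = D * H * W;
  const int K = C * kd * kh * kw;
  const int rd = kd / 2, rh = kh / 2, rw = kw / 2;
  std::vector<double>& buf = im2col_buf();
  if ((size_t)K * N > buf.size()) buf.resize((size_t)K * N);
  std::fill(buf.begin(), buf.begin() + (size_t)K * N, 0.0);
  arma::mat col(buf.data(), K, N, false, true);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const int n = d + D * (h + H * w);
        double* colptr = col.colptr(n);
        int k = 0;
        for (int ow = -rw; ow <= rw; ++ow) {
          const int sw = w + ow;
          for (int oh = -rh; oh <= rh; ++oh) {
            const int sh = h + oh;
            for (int od = -rd; od <= rd; ++od) {
              const int sd = d + od;
              if (sd >= 0 && sd < D && sh >= 0 && sh < H &&
                  sw >= 0 && sw < W) {
                const double* src = x.memptr() + idx4(0, sd, sh, sw, C, D, H);
                for (int c = 0; c < C; ++c) colptr[k + c] = src[c];
              }
              k += C;
            }
          }
        }
      }
  return col;
}

// Adjoint of im2col: scatter-add columns back into the padded volume.
static arma::vec col2im(const arma::mat& col, int C, int D, int H, int W,
                        int kd, int kh, int kw) {
  const int rd = kd / 2, rh = kh / 2, rw = kw / 2;
  arma::vec x((arma::uword)C * D * H * W, arma::fill::zeros);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const int n = d + D * (h + H * w);
        const double* colptr = col.colptr(n);
        int k = 0;
        for (int ow = -rw; ow <= rw; ++ow) {
          const int sw = w + ow;
          for (int oh = -rh; oh <= rh; ++oh) {
            const int sh = h + oh;
            for (int od = -rd; od <= rd; ++od) {
              const int sd = d + od;
              if (sd >= 0 && sd < D && sh >= 0 && sh < H &&
                  sw >= 0 && sw < W) {
                double* dst = x.memptr() + idx4(0, sd, sh, sw, C, D, H);
                for (int c = 0; c < C; ++c) dst[c] += colptr[k + c];
              }
              k += C;
            }
          }
        }
      }
  return x;
}

// y (Cout,D,H,W) = conv3d(x (C,D,H,W); wmat (K x Cout), bias (Cout))
// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix wmat, NumericVector bias,
                             IntegerVector ksz) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int kd = ksz[0], kh = ksz[1], kw = ksz[2];
  const int Cout = wmat.ncol();
  const int N = D * H * W;
  arma::vec xv(x.begin(), x.size(), false);
  arma::mat Wm(wmat.begin(), wmat.nrow(), Cout, false);
  arma::mat col = im2col(xv, C, D, H, W, kd, kh, kw);
  arma::mat y = Wm.t() * col;           // Cout x N
  arma::vec bv(bias.begin(), Cout, false);
  y.each_col() += bv;
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Cout, D, H, W);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims,
                    NumericMatrix wmat, NumericVector dy,
                    IntegerVector ksz) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int kd = ksz[0], kh = ksz[1], kw = ksz[2];
  const int Cout = wmat.ncol();
  const int N = D * H * W;
  arma::vec xv(x.begin(), x.size(), false);
  arma::mat Wm(wmat.begin(), wmat.nrow(), Cout, false);
  arma::mat dY((double*)dy.begin(), Cout, N, false);
  arma::mat col = im2col(xv, C, D, H, W, kd, kh, kw);
  arma::mat dW = col * dY.t();          // K x Cout
  arma::vec db = arma::sum(dY, 1);
  arma::mat dcol = Wm * dY;             // K x N
  arma::vec dx = col2im(dcol, C, D, H, W, kd, kh, kw);
  NumericVector dxr(dx.begin(), dx.end());
  dxr.attr("dim") = IntegerVector::create(C, D, H, W);
  return List::create(_["dx"] = dxr,
                      _["dw"] = wrap(dW),
                      _["db"] = wrap(db));
}

// Pointwise (1x1x1) convolution fast path: plain channel mixing.
// [[Rcpp::export]]
NumericVector cpp_conv1x1_fwd(NumericVector x, IntegerVector dims,
                              NumericMatrix wmat, NumericVector bias) {
  const int C = dims[0];
  const int N = dims[1] * dims[2] * dims[3];
  const int Cout = wmat.ncol();
  arma::mat X((double*)x.begin(), C, N, false);
  arma::mat Wm(wmat.begin(), C, Cout, false);
  arma::mat y = Wm.t() * X;
  arma::vec bv(bias.begin(), Cout, false);
  y.each_col() += bv;
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Cout, dims[1], dims[2], dims[3]);
  return out;
}

// [[Rcpp::export]]
List cpp_conv1x1_bwd(NumericVector x, IntegerVector dims,
                     NumericMatrix wmat, NumericVector dy) {
  const int C = dims[0];
  const int N = dims[1] * dims[2] * dims[3];
  const int Cout = wmat.ncol();
  arma::mat X((double*)x.begin(), C, N, false);
  arma::mat Wm(wmat.begin(), C, Cout, false);
  arma::mat dY((double*)dy.begin(), Cout, N, false);
  arma::mat dW = X * dY.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dx = Wm * dY;
  NumericVector dxr(dx.begin(), dx.end());
  dxr.attr("dim") = dims;
  return List::create(_["dx"] = dxr, _["dw"] = wrap(dW),
                      _["db"] = wrap(db));
}

// Pooling with per-axis factors in {1,2}; dims must be divisible.
// type 0 = max (records argmax), 1 = average.
// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector x, IntegerVector dims, IntegerVector f,
                  int type) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int fd = f[0], fh = f[1], fw = f[2];
  const int oD = D / fd, oH = H / fh, oW = W / fw;
  const double cnt = fd * fh * fw;
  NumericVector y((R_xlen_t)C * oD * oH * oW);
  IntegerVector am(type == 0 ? y.size() : 0);
  for (int w = 0; w < oW; ++w)
    for (int h = 0; h < oH; ++h)
      for (int d = 0; d < oD; ++d)
        for (int c = 0; c < C; ++c) {
          const arma::uword o = idx4(c, d, h, w, C, oD, oH);
          if (type == 0) {
            double best = R_NegInf; arma::uword bi = 0;
            for (int aw = 0; aw < fw; ++aw)
              for (int ah = 0; ah < fh; ++ah)
                for (int ad = 0; ad < fd; ++ad) {
                  arma::uword i = idx4(c, d * fd + ad, h * fh + ah,
                                       w * fw + aw, C, D, H);
                  if (x[i] > best) { best = x[i]; bi = i; }
                }
            y[o] = best; am[o] = (int)bi;
          } else {
            double s = 0.0;
            for (int aw = 0; aw < fw; ++aw)
              for (int ah = 0; ah < fh; ++ah)
                for (int ad = 0; ad < fd; ++ad)
                  s += x[idx4(c, d * fd + ad, h * fh + ah, w * fw + aw,
                              C, D, H)];
            y[o] = s / cnt;
          }
        }
  y.attr("dim") = IntegerVector::create(C, oD, oH, oW);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bwd(NumericVector dy, IntegerVector dims,
                           IntegerVector f, int type, IntegerVector argmax) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int fd = f[0], fh = f[1], fw = f[2];
  const int oD = D / fd, oH = H / fh, oW = W / fw;
  const double cnt = fd * fh * fw;
  NumericVector dx((R_xlen_t)C * D * H * W);
  for (int w = 0; w < oW; ++w)
    for (int h = 0; h < oH; ++h)
      for (int d = 0; d < oD; ++d)
        for (int c = 0; c < C; ++c) {
          const arma::uword o = idx4(c, d, h, w, C, oD, oH);
          if (type == 0) {
            dx[argmax[o]] += dy[o];
          } else {
            const double g = dy[o] / cnt;
            for (int aw = 0; aw < fw; ++aw)
              for (int ah = 0; ah < fh; ++ah)
                for (int ad = 0; ad < fd; ++ad)
                  dx[idx4(c, d * fd + ad, h * fh + ah, w * fw + aw,
                          C, D, H)] += g;
          }
        }
  dx.attr("dim") = dims;
  return dx;
}

// Nearest-neighbour integer upsampling; backward is block summation.
// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, IntegerVector dims,
                               IntegerVector f) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int fd = f[0], fh = f[1], fw = f[2];
  const int oD = D * fd, oH = H * fh, oW = W * fw;
  NumericVector y((R_xlen_t)C * oD * oH * oW);
  for (int w = 0; w < oW; ++w)
    for (int h = 0; h < oH; ++h)
      for (int d = 0; d < oD; ++d) {
        const double* src = x.begin() + idx4(0, d / fd, h / fh, w / fw,
                                             C, D, H);
        double* dst = y.begin() + idx4(0, d, h, w, C, oD, oH);
        for (int c = 0; c < C; ++c) dst[c] = src[c];
      }
  y.attr("dim") = IntegerVector::create(C, oD, oH, oW);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dy, IntegerVector dims,
                               IntegerVector f) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int fd = f[0], fh = f[1], fw = f[2];
  const int oD = D * fd, oH = H * fh, oW = W * fw;
  NumericVector dx((R_xlen_t)C * D * H * W);
  for (int w = 0; w < oW; ++w)
    for (int h = 0; h < oH; ++h)
      for (int d = 0; d < oD; ++d) {
        const double* src = dy.begin() + idx4(0, d, h, w, C, oD, oH);
        double* dst = dx.begin() + idx4(0, d / fd, h / fh, w / fw, C, D, H);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  dx.attr("dim") = dims;
  return dx;
}

// Per-channel instance normalisation with affine transform.
// [[Rcpp::export]]
List cpp_instnorm_fwd(NumericVector x, IntegerVector dims,
                      NumericVector gain, NumericVector bias, double eps) {
  const int C = dims[0];
  const R_xlen_t N = (R_xlen_t)dims[1] * dims[2] * dims[3];
  NumericVector y(x.size()), xhat(x.size()), istd(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t n = 0; n < N; ++n) s += x[c + C * n];
    const double mu = s / N;
    for (R_xlen_t n = 0; n < N; ++n) {
      const double d = x[c + C * n] - mu;
      s2 += d * d;
    }
    const double is = 1.0 / std::sqrt(s2 / N + eps);
    istd[c] = is;
    for (R_xlen_t n = 0; n < N; ++n) {
      const double h = (x[c + C * n] - mu) * is;
      xhat[c + C * n] = h;
      y[c + C * n] = gain[c] * h + bias[c];
    }
  }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_instnorm_bwd(NumericVector dy, NumericVector xhat,
                      NumericVector istd, NumericVector gain,
                      IntegerVector dims) {
  const int C = dims[0];
  const R_xlen_t N = (R_xlen_t)dims[1] * dims[2] * dims[3];
  NumericVector dx(dy.size()), dgain(C), dbias(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0, sxh = 0.0;
    for (R_xlen_t n = 0; n < N; ++n) {
      const double g = dy[c + C * n];
      const double h = xhat[c + C * n];
      sg += g * h;
      sb += g;
    }
    dgain[c] = sg;
    dbias[c] = sb;
    const double m_dxh = gain[c] * sb / N;      // mean of dxhat
    const double m_dxh_xh = gain[c] * sg / N;   // mean of dxhat * xhat
    for (R_xlen_t n = 0; n < N; ++n) {
      const double dxh = gain[c] * dy[c + C * n];
      dx[c + C * n] = istd[c] *
        (dxh - m_dxh - xhat[c + C * n] * m_dxh_xh);
    }
    (void)sxh;
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgain"] = dgain,
                      _["dbias"] = dbias);
}

// Fused conv3d -> instance norm -> ReLU forward.  Returns everything the
// backward pass needs besides the conv input itself.
// [[Rcpp::export]]
List cpp_cir_fwd(NumericVector x, IntegerVector dims, NumericMatrix wmat,
                 NumericVector bias, IntegerVector ksz, NumericVector gain,
                 NumericVector nbias, double eps) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int kd = ksz[0], kh = ksz[1], kw = ksz[2];
  const int Cout = wmat.ncol();
  const R_xlen_t N = (R_xlen_t)D * H * W;
  arma::vec xv(x.begin(), x.size(), false);
  arma::mat Wm(wmat.begin(), wmat.nrow(), Cout, false);
  arma::mat conv;
  if (kd == 1 && kh == 1 && kw == 1) {
    arma::mat X((double*)x.begin(), C, N, false);
    conv = Wm.t() * X;
  } else {
    arma::mat col = im2col(xv, C, D, H, W, kd, kh, kw);
    conv = Wm.t() * col;
  }
  arma::vec bv(bias.begin(), Cout, false);
  conv.each_col() += bv;
  NumericVector y((R_xlen_t)Cout * N), xhat((R_xlen_t)Cout * N),
                istd(Cout);
  LogicalVector keep((R_xlen_t)Cout * N);
  for (int c = 0; c < Cout; ++c) {
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t n = 0; n < N; ++n) s += conv(c, n);
    const double mu = s / N;
    for (R_xlen_t n = 0; n < N; ++n) {
      const double d = conv(c, n) - mu;
      s2 += d * d;
    }
    const double is = 1.0 / std::sqrt(s2 / N + eps);
    istd[c] = is;
    for (R_xlen_t n = 0; n < N; ++n) {
      const double h = (conv(c, n) - mu) * is;
      xhat[c + (R_xlen_t)Cout * n] = h;
      const double v = gain[c] * h + nbias[c];
      const bool k = v > 0;
      keep[c + (R_xlen_t)Cout * n] = k;
      y[c + (R_xlen_t)Cout * n] = k ? v : 0.0;
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, D, H, W);
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd,
                      _["keep"] = keep);
}

// Fused backward: dy -> ReLU mask -> instance-norm backward -> conv
// backward.  Returns gradients for the conv input, conv weight/bias and
// the norm gain/bias.
// [[Rcpp::export]]
List cpp_cir_bwd(NumericVector dy, NumericVector x, IntegerVector dims,
                 NumericMatrix wmat, IntegerVector ksz, NumericVector gain,
                 NumericVector xhat, NumericVector istd,
                 LogicalVector keep) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int kd = ksz[0], kh = ksz[1], kw = ksz[2];
  const int Cout = wmat.ncol();
  const R_xlen_t N = (R_xlen_t)D * H * W;
  NumericVector dgain(Cout), dnbias(Cout);
  arma::mat dconv(Cout, N);
  for (int c = 0; c < Cout; ++c) {
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t n = 0; n < N; ++n) {
      const R_xlen_t i = c + (R_xlen_t)Cout * n;
      const double g = keep[i] ? dy[i] : 0.0;
      sg += g * xhat[i];
      sb += g;
    }
    dgain[c] = sg;
    dnbias[c] = sb;
    const double m_dxh = gain[c] * sb / N;
    const double m_dxh_xh = gain[c] * sg / N;
    for (R_xlen_t n = 0; n < N; ++n) {
      const R_xlen_t i = c + (R_xlen_t)Cout * n;
      const double g = keep[i] ? dy[i] : 0.0;
      dconv(c, n) = istd[c] * (gain[c] * g - m_dxh - xhat[i] * m_dxh_xh);
    }
  }
  arma::vec db = arma::sum(dconv, 1);
  NumericVector dxr;
  NumericMatrix dwr;
  if (kd == 1 && kh == 1 && kw == 1) {
    arma::mat X((double*)x.begin(), C, N, false);
    arma::mat Wm(wmat.begin(), C, Cout, false);
    arma::mat dW = X * dconv.t();
    arma::mat dx = Wm * dconv;
    dxr = NumericVector(dx.begin(), dx.end());
    dwr = wrap(dW);
  } else {
    arma::vec xv(x.begin(), x.size(), false);
    arma::mat Wm(wmat.begin(), wmat.nrow(), Cout, false);
    arma::mat col = im2col(xv, C, D, H, W, kd, kh, kw);
    arma::mat dW = col * dconv.t();
    arma::mat dcol = Wm * dconv;
    arma::vec dx = col2im(dcol, C, D, H, W, kd, kh, kw);
    dxr = NumericVector(dx.begin(), dx.end());
    dwr = wrap(dW);
  }
  dxr.attr("dim") = dims;
  return List::create(_["dx"] = dxr, _["dw"] = dwr, _["db"] = wrap(db),
                      _["dgain"] = dgain, _["dbias"] = dnbias);
}

struct LinW { int i0, i1; double w0, w1; };

static std::vector<LinW> lin_weights(int n_in, int n_out) {
  std::vector<LinW> v(n_out);
  for (int i = 0; i < n_out; ++i) {
    double x = (n_out == 1) ? 0.0
             : (double)i * (double)(n_in - 1) / (double)(n_out - 1);
    int i0 = (int)std::floor(x);
    if (i0 > n_in - 2) i0 = n_in - 2;
    if (i0 < 0) i0 = 0;
    double t = x - i0;
    if (n_in == 1) { v[i] = {0, 0, 1.0, 0.0}; }
    else v[i] = {i0, i0 + 1, 1.0 - t, t};
  }
  return v;
}

// Trilinear resize (align-corners) of a (C,D,H,W) array to (C,od,oh,ow).
// [[Rcpp::export]]
NumericVector cpp_resize3_fwd(NumericVector x, IntegerVector dims,
                              IntegerVector odims) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int oD = odims[0], oH = odims[1], oW = odims[2];
  std::vector<LinW> wd = lin_weights(D, oD), wh = lin_weights(H, oH),
                    ww = lin_weights(W, oW);
  NumericVector y((R_xlen_t)C * oD * oH * oW);
  for (int w = 0; w < oW; ++w)
    for (int h = 0; h < oH; ++h)
      for (int d = 0; d < oD; ++d) {
        double* dst = y.begin() + idx4(0, d, h, w, C, oD, oH);
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          for (int aw = 0; aw < 2; ++aw) {
            const int iw = aw ? ww[w].i1 : ww[w].i0;
            const double gw = aw ? ww[w].w1 : ww[w].w0;
            if (gw == 0.0) continue;
            for (int ah = 0; ah < 2; ++ah) {
              const int ih = ah ? wh[h].i1 : wh[h].i0;
              const double gh = ah ? wh[h].w1 : wh[h].w0;
              if (gh == 0.0) continue;
              for (int ad = 0; ad < 2; ++ad) {
                const int id = ad ? wd[d].i1 : wd[d].i0;
                const double gd = ad ? wd[d].w1 : wd[d].w0;
                if (gd == 0.0) continue;
                s += gw * gh * gd * x[idx4(c, id, ih, iw, C, D, H)];
              }
            }
          }
          dst[c] = s;
        }
      }
  y.attr("dim") = IntegerVector::create(C, oD, oH, oW);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize3_bwd(NumericVector dy, IntegerVector dims,
                              IntegerVector odims) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int oD = odims[0], oH = odims[1], oW = odims[2];
  std::vector<LinW> wd = lin_weights(D, oD), wh = lin_weights(H, oH),
                    ww = lin_weights(W, oW);
  NumericVector dx((R_xlen_t)C * D * H * W);
  for (int w = 0; w < oW; ++w)
    for (int h = 0; h < oH; ++h)
      for (int d = 0; d < oD; ++d) {
        const double* src = dy.begin() + idx4(0, d, h, w, C, oD, oH);
        for (int aw = 0; aw < 2; ++aw) {
          const int iw = aw ? ww[w].i1 : ww[w].i0;
          const double gw = aw ? ww[w].w1 : ww[w].w0;
          if (gw == 0.0) continue;
          for (int ah = 0; ah < 2; ++ah) {
            const int ih = ah ? wh[h].i1 : wh[h].i0;
            const double gh = ah ? wh[h].w1 : wh[h].w0;
            if (gh == 0.0) continue;
            for (int ad = 0; ad < 2; ++ad) {
              const int id = ad ? wd[d].i1 : wd[d].i0;
              const double gd = ad ? wd[d].w1 : wd[d].w0;
              if (gd == 0.0) continue;
              double* dst = dx.begin() + idx4(0, id, ih, iw, C, D, H);
              const double g = gw * gh * gd;
              for (int c = 0; c < C; ++c) dst[c] += g * src[c];
            }
          }
        }
      }
  dx.attr("dim") = dims;
  return dx;
}

// Resample the FIRST axis of a 3D (n1,n2,n3) array to n_out samples.
// Output coordinate i maps to input coordinate i*scale (voxel units,
// origin-aligned).  method 0 = nearest, 1 = cubic Catmull-Rom with
// linearly extrapolated border samples.
// [[Rcpp::export]]
NumericVector cpp_resample_axis1(NumericVector x, IntegerVector dims,
                                 int n_out, double scale, int method) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector y((R_xlen_t)n_out * n2 * n3);
  const R_xlen_t plane_in = n1, plane_out = n_out;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const double* src = x.begin() + ((R_xlen_t)j + (R_xlen_t)n2 * k) * plane_in;
      double* dst = y.begin() + ((R_xlen_t)j + (R_xlen_t)n2 * k) * plane_out;
      for (int i = 0; i < n_out; ++i) {
        const double pos = i * scale;
        if (method == 0) {
          int p = (int)std::lround(pos);
          if (p < 0) p = 0; if (p > n1 - 1) p = n1 - 1;
          dst[i] = src[p];
        } else {
          const int p1 = (int)std::floor(pos);
          const double t = pos - p1;
          // Catmull-Rom weights for samples at p1-1 .. p1+2
          const double w0 = ((-0.5 * t + 1.0) * t - 0.5) * t;
          const double w1 = ((1.5 * t - 2.5) * t) * t + 1.0;
          const double w2 = ((-1.5 * t + 2.0) * t + 0.5) * t;
          const double w3 = (0.5 * t - 0.5) * t * t;
          double s = 0.0;
          const double wts[4] = {w0, w1, w2, w3};
          for (int a = 0; a < 4; ++a) {
            const int p = p1 - 1 + a;
            double val;
            if (n1 == 1) val = src[0];
            else if (p < 0)        // linear extrapolation keeps ramps exact
              val = src[0] + p * (src[1] - src[0]);
            else if (p > n1 - 1)
              val = src[n1 - 1] + (p - (n1 - 1)) * (src[n1 - 1] - src[n1 - 2]);
            else val = src[p];
            s += wts[a] * val;
          }
          dst[i] = s;
        }
      }
    }
  y.attr("dim") = IntegerVector::create(n_out, n2, n3);
  return y;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing s; f holds squared distances, INF where no feature yet.
static void dt1d(double* f, int n, double s, double* d,
                 int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = R_NegInf; z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    if (f[q] == R_PosInf) continue;
    if (f[v[0]] == R_PosInf) { v[0] = q; continue; }
    double sA;
    while (true) {
      const int p = v[k];
      sA = ((f[q] + q * (double)q * s * s) - (f[p] + p * (double)p * s * s)) /
           (2.0 * s * s * (q - p));
      if (sA <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sA;
    z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == R_PosInf) { d[q] = R_PosInf; continue; }
    while (z[k + 1] < q) ++k;
    const double dq = (double)(q - v[k]) * s;
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact anisotropic squared Euclidean distance transform of a 3D mask:
// distance in mm from every voxel to the nearest nonzero voxel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int D = dims[0], H = dims[1], W = dims[2];
  NumericVector g((R_xlen_t)D * H * W);
  for (R_xlen_t i = 0; i < g.size(); ++i)
    g[i] = mask[i] ? 0.0 : R_PosInf;
  const int nmax = std::max(D, std::max(H, W));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1 (fastest)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double* col = g.begin() + ((R_xlen_t)h + (R_xlen_t)H * w) * D;
      for (int i = 0; i < D; ++i) f[i] = col[i];
      dt1d(f.data(), D, spacing[0], d.data(), v.data(), z.data());
      for (int i = 0; i < D; ++i) col[i] = d[i];
    }
  // axis 2
  for (int w = 0; w < W; ++w)
    for (int dd = 0; dd < D; ++dd) {
      for (int h = 0; h < H; ++h)
        f[h] = g[(R_xlen_t)dd + D * ((R_xlen_t)h + (R_xlen_t)H * w)];
      dt1d(f.data(), H, spacing[1], d.data(), v.data(), z.data());
      for (int h = 0; h < H; ++h)
        g[(R_xlen_t)dd + D * ((R_xlen_t)h + (R_xlen_t)H * w)] = d[h];
    }
  // axis 3
  for (int h = 0; h < H; ++h)
    for (int dd = 0; dd < D; ++dd) {
      for (int w = 0; w < W; ++w)
        f[w] = g[(R_xlen_t)dd + D * ((R_xlen_t)h + (R_xlen_t)H * w)];
      dt1d(f.data(), W, spacing[2], d.data(), v.data(), z.data());
      for (int w = 0; w < W; ++w)
        g[(R_xlen_t)dd + D * ((R_xlen_t)h + (R_xlen_t)H * w)] = d[w];
    }
  g.attr("dim") = dims;
  return g;
}
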