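// Convolution and pooling kernels for the residual-network backbones.
// Data layout follows R column-major arrays: activations are [H, W, C, N],
// convolution weights are [kh, kw, C, F]. Convolutions are computed per
// sample via im2col + GEMM; the column-buffer row index is
// kh_i + kh * (kw_i + kw * c), matching the column-major flattening of the
// weight array, so the weight matrix is just a reshape.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  // col: (kh*kw*C) x (Ho*Wo)
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int pix = ho + Ho * wo;
      for (int c = 0; c < C; ++c) {
        for (int kwi = 0; kwi < kw; ++kwi) {
          const int w = wo * stride - pad + kwi;
          for (int khi = 0; khi < kh; ++khi) {
            const int h = ho * stride - pad + khi;
            const int r = khi + kh * (kwi + kw * c);
            col(r, pix) = (h >= 0 && h < H && w >= 0 && w < W)
              ? x[h + H * (w + W * c)] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int pix = ho + Ho * wo;
      for (int c = 0; c < C; ++c) {
        for (int kwi = 0; kwi < kw; ++kwi) {
          const int w = wo * stride - pad + kwi;
          if (w < 0 || w >= W) continue;
          for (int khi = 0; khi < kh; ++khi) {
            const int h = ho * stride - pad + khi;
            if (h < 0 || h >= H) continue;
            const int r = khi + kh * (kwi + kw * c);
            dx[h + H * (w + W * c)] += col(r, pix);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = conv_out(H, kh, stride, pad), Wo = conv_out(W, kw, stride, pad);
  const arma::mat wmat(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  const arma::vec bvec(const_cast<double*>(bias.begin()), F, false, true);

  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat col(kh * kw * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
           H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat out = wmat.t() * col;      // F x (Ho*Wo)
    out.each_col() += bvec;
    double* yp = y.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * F;
    for (int f = 0; f < F; ++f)
      for (int pix = 0; pix < Ho * Wo; ++pix)
        yp[pix + Ho * Wo * 0 + static_cast<R_xlen_t>(f) * Ho * Wo] = out(f, pix);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = conv_out(H, kh, stride, pad), Wo = conv_out(W, kw, stride, pad);
  const arma::mat wmat(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dwmat(kh * kw * C, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  arma::mat col(kh * kw * C, Ho * Wo);
  arma::mat dymat(F, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * F;
    for (int f = 0; f < F; ++f)
      for (int pix = 0; pix < Ho * Wo; ++pix)
        dymat(f, pix) = dyp[pix + static_cast<R_xlen_t>(f) * Ho * Wo];
    im2col(x.begin() + static_cast<R_xlen_t>(n) * H * W * C,
           H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    dwmat += col * dymat.t();
    db += arma::sum(dymat, 1);
    arma::mat dcol = wmat * dymat;       // (kh*kw*C) x (Ho*Wo)
    col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + static_cast<R_xlen_t>(n) * H * W * C);
  }
  NumericVector dwr(w.size());
  std::copy(dwmat.begin(), dwmat.end(), dwr.begin());
  dwr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = conv_out(H, k, stride, pad), Wo = conv_out(W, k, stride, pad);
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector arg(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + static_cast<R_xlen_t>(n) * H * W * C;
    double* yp = y.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * C;
    int* ap = arg.begin() + static_cast<R_xlen_t>(n) * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kwi = 0; kwi < k; ++kwi) {
            const int w = wo * stride - pad + kwi;
            if (w < 0 || w >= W) continue;
            for (int khi = 0; khi < k; ++khi) {
              const int h = ho * stride - pad + khi;
              if (h < 0 || h >= H) continue;
              const double v = xp[h + H * (w + W * c)];
              if (v > best) { best = v; besti = h + H * (w + W * c); }
            }
          }
          yp[ho + Ho * (wo + Wo * c)] = best;
          ap[ho + Ho * (wo + Wo * c)] = besti;   // index within sample slab
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector argmax,
                                   IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = xdim;
  IntegerVector yd = dy.attr("dim");
  const R_xlen_t slab_y = static_cast<R_xlen_t>(yd[0]) * yd[1] * yd[2];
  const R_xlen_t slab_x = static_cast<R_xlen_t>(H) * W * C;
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + n * slab_y;
    const int* ap = argmax.begin() + n * slab_y;
    double* dxp = dx.begin() + n * slab_x;
    for (R_xlen_t i = 0; i < slab_y; ++i) dxp[ap[i]] += dyp[i];
  }
  return dx;
}
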