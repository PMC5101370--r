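// Minimal im2col-based convolution and pooling primitives for the
// from-scratch CNN trainer.  Layout conventions (column-major, as in R):
//   activations: array(H, W, C, N)
//   conv weights: matrix(n_filters, k*k*C) with column index
//                 j = kh + k*kw + k*k*c   (0-based, matching R flatten
//                 of an array(k, k, C) patch)
// Gradients mirror the forward shapes exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void im2col_one(const double* x, int H, int W, int C,
                              int k, int stride, int pad,
                              int Ho, int Wo, arma::fmat& col) {
  // col: (k*k*C) x (Ho*Wo), zero-filled for out-of-bounds (zero padding)
  col.zeros();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int pos = ho + Ho * wo;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      float* cptr = col.colptr(pos);
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            cptr[kh + k * kw + k * k * c] =
              static_cast<float>(x[h + H * (w + W * c)]);
          }
        }
      }
    }
  }
}

static inline void col2im_one(const arma::fmat& col, int H, int W, int C,
                              int k, int stride, int pad,
                              int Ho, int Wo, double* dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int pos = ho + Ho * wo;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      const float* cptr = col.colptr(pos);
      for (int c = 0; c < C; ++c) {
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            dx[h + H * (w + W * c)] += cptr[kh + k * kw + k * k * c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, IntegerVector dimx,
                       NumericMatrix w, NumericVector b,
                       int k, int stride, int pad) {
  const int H = dimx[0], W = dimx[1], C = dimx[2], N = dimx[3];
  const int nf = w.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int npos = Ho * Wo;

  // single-precision internals: one im2col matrix over the whole batch
  // feeding a single large SGEMM
  arma::mat wmd(w.begin(), nf, w.ncol(), false);
  arma::fmat wm = arma::conv_to<arma::fmat>::from(wmd);
  arma::fvec bv = arma::conv_to<arma::fvec>::from(
    arma::vec(b.begin(), nf, false));

  NumericVector y(static_cast<R_xlen_t>(npos) * nf * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, nf, N);

  arma::fmat col(k * k * C, static_cast<arma::uword>(npos) * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + static_cast<R_xlen_t>(H) * W * C * n;
    arma::fmat coln(col.colptr(static_cast<arma::uword>(npos) * n),
                    k * k * C, npos, false, true);
    im2col_one(xn, H, W, C, k, stride, pad, Ho, Wo, coln);
  }
  arma::fmat out = wm * col;           // nf x (npos*N)
  out.each_col() += bv;
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + static_cast<R_xlen_t>(npos) * nf * n;
    for (int f = 0; f < nf; ++f)
      for (int p = 0; p < npos; ++p)
        yn[p + npos * f] = out(f, static_cast<arma::uword>(npos) * n + p);
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, IntegerVector dimx,
              NumericMatrix w, NumericVector dy,
              int k, int stride, int pad, bool need_dx) {
  const int H = dimx[0], W = dimx[1], C = dimx[2], N = dimx[3];
  const int nf = w.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int npos = Ho * Wo;

  arma::mat wmd(w.begin(), nf, w.ncol(), false);
  arma::fmat wm = arma::conv_to<arma::fmat>::from(wmd);

  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = dimx;

  arma::fmat col(k * k * C, static_cast<arma::uword>(npos) * N);
  arma::fmat dyn(nf, static_cast<arma::uword>(npos) * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + static_cast<R_xlen_t>(H) * W * C * n;
    const double* dyp = dy.begin() + static_cast<R_xlen_t>(npos) * nf * n;
    for (int f = 0; f < nf; ++f)
      for (int p = 0; p < npos; ++p)
        dyn(f, static_cast<arma::uword>(npos) * n + p) =
          static_cast<float>(dyp[p + npos * f]);
    arma::fmat coln(col.colptr(static_cast<arma::uword>(npos) * n),
                    k * k * C, npos, false, true);
    im2col_one(xn, H, W, C, k, stride, pad, Ho, Wo, coln);
  }
  arma::fmat dwf = dyn * col.t();
  arma::fvec dbf = arma::sum(dyn, 1);
  if (need_dx) {
    arma::fmat dcol = wm.t() * dyn;    // (k*k*C) x (npos*N)
    for (int n = 0; n < N; ++n) {
      double* dxn = dx.begin() + static_cast<R_xlen_t>(H) * W * C * n;
      arma::fmat dcoln(const_cast<float*>(
                         dcol.colptr(static_cast<arma::uword>(npos) * n)),
                       k * k * C, npos, false, true);
      col2im_one(dcoln, H, W, C, k, stride, pad, Ho, Wo, dxn);
    }
  }
  arma::mat dw = arma::conv_to<arma::mat>::from(dwf);
  arma::vec db = arma::conv_to<arma::vec>::from(dbf);
  return List::create(_["dx"] = dx,
                      _["dw"] = wrap(dw),
                      _["db"] = wrap(db));
}

// [[Rcpp::export(name = ".pool_fwd")]]
List pool_fwd(NumericVector x, IntegerVector dimx,
              int p, int stride, bool max_pool) {
  const int H = dimx[0], W = dimx[1], C = dimx[2], N = dimx[3];
  const int Ho = (H - p) / stride + 1;
  const int Wo = (W - p) / stride + 1;
  const R_xlen_t out_n = static_cast<R_xlen_t>(Ho) * Wo * C;
  NumericVector y(out_n * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(max_pool ? out_n * N : 0);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + static_cast<R_xlen_t>(H) * W * C * n;
    double* yn = y.begin() + out_n * n;
    int* in = max_pool ? idx.begin() + out_n * n : nullptr;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + static_cast<R_xlen_t>(H) * W * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride, w0 = wo * stride;
          if (max_pool) {
            double best = xc[h0 + H * w0];
            int besti = h0 + H * w0;
            for (int dw_ = 0; dw_ < p; ++dw_)
              for (int dh = 0; dh < p; ++dh) {
                const int i = (h0 + dh) + H * (w0 + dw_);
                if (xc[i] > best) { best = xc[i]; besti = i; }
              }
            yn[ho + Ho * (wo + Wo * c)] = best;
            in[ho + Ho * (wo + Wo * c)] = besti;
          } else {
            double s = 0.0;
            for (int dw_ = 0; dw_ < p; ++dw_)
              for (int dh = 0; dh < p; ++dh)
                s += xc[(h0 + dh) + H * (w0 + dw_)];
            yn[ho + Ho * (wo + Wo * c)] = s / (p * p);
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".pool_bwd")]]
NumericVector pool_bwd(NumericVector dy, IntegerVector dimy,
                       IntegerVector dimx, IntegerVector idx,
                       int p, int stride, bool max_pool) {
  const int Ho = dimy[0], Wo = dimy[1], C = dimy[2], N = dimy[3];
  const int H = dimx[0], W = dimx[1];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = dimx;
  const R_xlen_t out_n = static_cast<R_xlen_t>(Ho) * Wo * C;

  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + out_n * n;
    double* dxn = dx.begin() + static_cast<R_xlen_t>(H) * W * C * n;
    const int* in = max_pool ? idx.begin() + out_n * n : nullptr;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + static_cast<R_xlen_t>(H) * W * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = dyn[ho + Ho * (wo + Wo * c)];
          if (max_pool) {
            dxc[in[ho + Ho * (wo + Wo * c)]] += g;
          } else {
            const double gpp = g / (p * p);
            const int h0 = ho * stride, w0 = wo * stride;
            for (int dw_ = 0; dw_ < p; ++dw_)
              for (int dh = 0; dh < p; ++dh)
                dxc[(h0 + dh) + H * (w0 + dw_)] += gpp;
          }
        }
      }
    }
  }
  return dx;
}

// In-place momentum-SGD update with L2 weight decay:
//   v <- momentum * v - lr * (g + wd * w);  w <- w + v
// Operates directly on the (privately owned) weight and velocity buffers.
// [[Rcpp::export(name = ".sgd_step")]]
void sgd_step(NumericVector w, NumericVector v, NumericVector g,
              double lr, double momentum, double wd) {
  const R_xlen_t n = w.size();
  double* wp = w.begin();
  double* vp = v.begin();
  const double* gp = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    vp[i] = momentum * vp[i] - lr * (gp[i] + wd * wp[i]);
    wp[i] += vp[i];
  }
}

// In-place Adam update.  m/v are the first/second moment buffers; t is the
// 1-based step count used for bias correction.  Weight decay is applied as
// an L2 gradient term (classic Adam).
// [[Rcpp::export(name = ".adam_step")]]
void adam_step(NumericVector w, NumericVector m, NumericVector v,
               NumericVector g, double lr, double beta1, double beta2,
               double eps, double wd, int t) {
  const R_xlen_t n = w.size();
  double* wp = w.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  const double* gp = g.begin();
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = gp[i] + wd * wp[i];
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gi;
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gi * gi;
    wp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}
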