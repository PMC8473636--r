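// Convolution kernels for the package's small neural-network engine.
// Feature maps are R arrays with dim (H, W, C, N), column-major; weights
// for a standard convolution have dim (kh, kw, Cin, Cout), depthwise
// (kh, kw, C).  im2col columns are output pixels in column-major (h fastest),
// rows are (i, j, c) with i fastest, matching the flattened weight array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill an im2col matrix (K x P) for one sample, one channel range.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   arma::mat& col) {
  const int Ho = out_len(H, kh, stride, pad);
  const int Wo = out_len(W, kw, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      double* cp = col.colptr(p);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      int k = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          const int wsrc = w0 + j;
          for (int i = 0; i < kh; ++i, ++k) {
            const int hsrc = h0 + i;
            cp[k] = (hsrc >= 0 && hsrc < H && wsrc >= 0 && wsrc < W)
                      ? xc[hsrc + (size_t)H * wsrc] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the transpose of im2col: dcol (K x P) back into dx.
static void col2im(const arma::mat& dcol, int H, int W, int C,
                   int kh, int kw, int stride, int pad, double* dx) {
  const int Ho = out_len(H, kh, stride, pad);
  const int Wo = out_len(W, kw, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      const double* cp = dcol.colptr(p);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      int k = 0;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          const int wsrc = w0 + j;
          for (int i = 0; i < kh; ++i, ++k) {
            const int hsrc = h0 + i;
            if (hsrc >= 0 && hsrc < H && wsrc >= 0 && wsrc < W)
              xc[hsrc + (size_t)H * wsrc] += cp[k];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: input has %d channels, kernel expects %d", C, wd[2]);
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  const int K = kh * kw * C, P = Ho * Wo;

  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  const bool one_by_one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat col(one_by_one ? 1 : K, one_by_one ? 1 : P);
  for (int n = 0; n < N; ++n) {
    arma::mat out(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    if (one_by_one) {          // no im2col copy: input is already (P x C)
      arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                  P, C, false, true);
      out = X * Wm;
    } else {
      im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, col);
      out = col.t() * Wm;
    }
    out.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  const int K = kh * kw * C, P = Ho * Wo;

  NumericVector dx(Rf_allocVector(REALSXP, x.size()));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = xd;
  NumericVector dw(Rf_allocVector(REALSXP, w.size()));
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  dWm.zeros();
  arma::rowvec dbv(Cout, arma::fill::zeros);
  const bool one_by_one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat col(one_by_one ? 1 : K, one_by_one ? 1 : P);
  for (int n = 0; n < N; ++n) {
    double* xn = const_cast<double*>(x.begin()) + (size_t)H * W * C * n;
    arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)P * Cout * n,
                  P, Cout, false, true);
    dbv += arma::sum(dYn, 0);
    if (one_by_one) {
      arma::mat X(xn, P, C, false, true);
      dWm += X.t() * dYn;
      arma::mat dX(dx.begin() + (size_t)H * W * C * n, P, C, false, true);
      dX = dYn * Wm.t();
      continue;
    }
    im2col(xn, H, W, C, kh, kw, stride, pad, col);
    dWm += col * dYn;
    arma::mat dcol = Wm * dYn.t();        // K x P
    col2im(dcol, H, W, C, kh, kw, stride, pad,
           dx.begin() + (size_t)H * W * C * n);
  }
  for (int c = 0; c < Cout; ++c) db[c] = dbv[c];
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector dwconv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                               int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv2d: input has %d channels, kernel expects %d", C, wd[2]);
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  const int K = kh * kw, P = Ho * Wo;

  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      im2col(x.begin() + (size_t)H * W * (c + (size_t)C * n), H, W, 1,
             kh, kw, stride, pad, col);
      arma::colvec wc(const_cast<double*>(w.begin()) + (size_t)K * c, K, false, true);
      arma::rowvec out = wc.t() * col;    // 1 x P
      double* yp = y.begin() + (size_t)P * (c + (size_t)C * n);
      for (int p = 0; p < P; ++p) yp[p] = out[p] + b[c];
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  const int K = kh * kw, P = Ho * Wo;

  NumericVector dx(Rf_allocVector(REALSXP, x.size()));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = xd;
  NumericVector dw(Rf_allocVector(REALSXP, w.size()));
  std::fill(dw.begin(), dw.end(), 0.0);
  dw.attr("dim") = wd;
  NumericVector db(C);

  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      im2col(x.begin() + off, H, W, 1, kh, kw, stride, pad, col);
      arma::colvec dyc(const_cast<double*>(dy.begin()) + (size_t)P * (c + (size_t)C * n),
                       P, false, true);
      arma::colvec dwc = col * dyc;       // K
      double* dwp = dw.begin() + (size_t)K * c;
      for (int k = 0; k < K; ++k) dwp[k] += dwc[k];
      db[c] += arma::accu(dyc);
      arma::colvec wc(const_cast<double*>(w.begin()) + (size_t)K * c, K, false, true);
      arma::mat dcol = wc * dyc.t();      // K x P
      col2im(dcol, H, W, 1, kh, kw, stride, pad, dx.begin() + off);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- fast depthwise direct loops (no im2col allocation) -----------------

// [[Rcpp::export]]
NumericVector dwconv2d_fwd_fast(NumericVector x, NumericVector w, NumericVector b,
                                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const double bc = b[c];
      // interior outputs touch no padding: tight unchecked loops there
      const int ho_lo = (pad + stride - 1) / stride;
      const int ho_hi = (H - kh + pad) / stride;      // inclusive
      const int wo_lo = ho_lo, wo_hi = (W - kw + pad) / stride;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * stride - pad;
        const bool w_in = (wo >= wo_lo && wo <= wo_hi);
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride - pad;
          double acc = bc;
          if (w_in && ho >= ho_lo && ho <= ho_hi) {
            const double* base = xc + (size_t)H * w0 + h0;
            for (int j = 0; j < kw; ++j) {
              const double* col = base + (size_t)H * j;
              const double* wj = wc + kh * j;
              for (int i = 0; i < kh; ++i) acc += wj[i] * col[i];
            }
          } else {
            for (int j = 0; j < kw; ++j) {
              const int ws = w0 + j;
              if (ws < 0 || ws >= W) continue;
              const double* col = xc + (size_t)H * ws;
              const double* wj = wc + kh * j;
              for (int i = 0; i < kh; ++i) {
                const int hs = h0 + i;
                if (hs >= 0 && hs < H) acc += wj[i] * col[hs];
              }
            }
          }
          yc[ho + Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv2d_bwd_fast(NumericVector x, NumericVector w, NumericVector dy,
                       int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  NumericVector dx(Rf_allocVector(REALSXP, x.size()));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = xd;
  NumericVector dw(Rf_allocVector(REALSXP, w.size()));
  std::fill(dw.begin(), dw.end(), 0.0);
  dw.attr("dim") = wd;
  NumericVector db(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)kh * kw * c;
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double dbacc = 0.0;
      const int ho_lo = (pad + stride - 1) / stride;
      const int ho_hi = (H - kh + pad) / stride;      // inclusive
      const int wo_lo = ho_lo, wo_hi = (W - kw + pad) / stride;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * stride - pad;
        const bool w_in = (wo >= wo_lo && wo <= wo_hi);
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = dyc[ho + Ho * wo];
          dbacc += g;
          const int h0 = ho * stride - pad;
          if (w_in && ho >= ho_lo && ho <= ho_hi) {
            const double* base = xc + (size_t)H * w0 + h0;
            double* dbase = dxc + (size_t)H * w0 + h0;
            for (int j = 0; j < kw; ++j) {
              const double* col = base + (size_t)H * j;
              double* dcol = dbase + (size_t)H * j;
              double* dwj = dwc + kh * j;
              const double* wj = wc + kh * j;
              for (int i = 0; i < kh; ++i) {
                dwj[i] += g * col[i];
                dcol[i] += g * wj[i];
              }
            }
          } else {
            for (int j = 0; j < kw; ++j) {
              const int ws = w0 + j;
              if (ws < 0 || ws >= W) continue;
              const double* col = xc + (size_t)H * ws;
              double* dcol = dxc + (size_t)H * ws;
              for (int i = 0; i < kh; ++i) {
                const int hs = h0 + i;
                if (hs >= 0 && hs < H) {
                  dwc[i + kh * j] += g * col[hs];
                  dcol[hs] += g * wc[i + kh * j];
                }
              }
            }
          }
        }
      }
      db[c] += dbacc;
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- activations (single pass, dims preserved) --------------------------
// type: 0 relu, 1 relu6, 2 lrelu, 3 sigmoid, 4 tanh, 5 clamp01

// [[Rcpp::export]]
NumericVector act_fwd_cpp(NumericVector x, int type, double alpha) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  const R_xlen_t n = x.size();
  const double* xp = x.begin(); double* yp = y.begin();
  switch (type) {
  case 0: for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0; break;
  case 1: for (R_xlen_t i = 0; i < n; ++i)
            yp[i] = xp[i] <= 0 ? 0 : (xp[i] >= 6 ? 6 : xp[i]); break;
  case 2: for (R_xlen_t i = 0; i < n; ++i)
            yp[i] = xp[i] > 0 ? xp[i] : alpha * xp[i]; break;
  case 3: for (R_xlen_t i = 0; i < n; ++i) yp[i] = 1.0 / (1.0 + std::exp(-xp[i])); break;
  case 4: for (R_xlen_t i = 0; i < n; ++i) yp[i] = std::tanh(xp[i]); break;
  case 5: for (R_xlen_t i = 0; i < n; ++i)
            yp[i] = xp[i] <= 0 ? 0 : (xp[i] >= 1 ? 1 : xp[i]); break;
  }
  return y;
}

// cache is the input x (types 0,1,2,5) or the output y (types 3,4).
// [[Rcpp::export]]
NumericVector act_bwd_cpp(NumericVector cache, NumericVector dy, int type,
                          double alpha) {
  NumericVector dx(Rf_allocVector(REALSXP, dy.size()));
  dx.attr("dim") = dy.attr("dim");
  const R_xlen_t n = dy.size();
  const double* cp = cache.begin(); const double* gp = dy.begin();
  double* dp = dx.begin();
  switch (type) {
  case 0: for (R_xlen_t i = 0; i < n; ++i) dp[i] = cp[i] > 0 ? gp[i] : 0; break;
  case 1: for (R_xlen_t i = 0; i < n; ++i)
            dp[i] = (cp[i] > 0 && cp[i] < 6) ? gp[i] : 0; break;
  case 2: for (R_xlen_t i = 0; i < n; ++i)
            dp[i] = cp[i] > 0 ? gp[i] : alpha * gp[i]; break;
  case 3: for (R_xlen_t i = 0; i < n; ++i) dp[i] = gp[i] * cp[i] * (1 - cp[i]); break;
  case 4: for (R_xlen_t i = 0; i < n; ++i) dp[i] = gp[i] * (1 - cp[i] * cp[i]); break;
  case 5: for (R_xlen_t i = 0; i < n; ++i)
            dp[i] = (cp[i] > 0 && cp[i] < 1) ? gp[i] : 0; break;
  }
  return dx;
}

// y[h,w,c,n] = x[h,w,c,n] * s[c,n]
// [[Rcpp::export]]
NumericVector bcast_mul_channel_cpp(NumericVector x, NumericMatrix s) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int CN = xd[2] * xd[3];
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = xd;
  const double* xp = x.begin(); double* yp = y.begin();
  const double* sp = s.begin();
  for (int k = 0; k < CN; ++k) {
    const double v = sp[k];
    const double* xi = xp + HW * k; double* yi = yp + HW * k;
    for (size_t i = 0; i < HW; ++i) yi[i] = xi[i] * v;
  }
  return y;
}

// out[c,n] = sum over h,w of a[h,w,c,n] * b[h,w,c,n]
// [[Rcpp::export]]
NumericMatrix channel_dot_cpp(NumericVector a, NumericVector b) {
  IntegerVector xd = a.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericMatrix out(C, N);
  const double* ap = a.begin(); const double* bp = b.begin();
  for (int k = 0; k < C * N; ++k) {
    const double* ai = ap + HW * k; const double* bi = bp + HW * k;
    double acc = 0;
    for (size_t i = 0; i < HW; ++i) acc += ai[i] * bi[i];
    out[k] = acc;
  }
  return out;
}

// constant spatial broadcast: y[h,w,c,n] = s[c,n]
// [[Rcpp::export]]
NumericVector bcast_channel_const_cpp(NumericMatrix s, int H, int W) {
  const int C = s.nrow(), N = s.ncol();
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t HW = (size_t)H * W;
  double* yp = y.begin(); const double* sp = s.begin();
  for (int k = 0; k < C * N; ++k) {
    double* yi = yp + HW * k;
    const double v = sp[k];
    for (size_t i = 0; i < HW; ++i) yi[i] = v;
  }
  return y;
}
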