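// Low-level tensor kernels for the CNN engine.
//
// Layout convention (matches R column-major arrays):
//   activations: dim c(H, W, C, N)
//   conv weights: dim c(KH, KW, Cin, Cout)
// im2col rows are ordered kh-fastest, then kw, then cin, so that a weight
// array reshaped to (KH*KW*Cin) x Cout multiplies patch columns directly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}


static NumericVector num4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector int4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static void im2col(const double *x, int H, int W, int C,
                   int KH, int KW, int stride, int pad_h, int pad_w,
                   int Ho, int Wo, double *cols) {
  // cols: (KH*KW*C) x (Ho*Wo), column-major, output pixels h-fastest
  const int K = KH * KW * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double *col = cols + (size_t)(wo * Ho + ho) * K;
      const int h0 = ho * stride - pad_h;
      const int w0 = wo * stride - pad_w;
      for (int c = 0; c < C; ++c) {
        const double *xc = x + (size_t)c * H * W;
        for (int kw = 0; kw < KW; ++kw) {
          const int w = w0 + kw;
          const bool win = (w >= 0 && w < W);
          for (int kh = 0; kh < KH; ++kh) {
            const int h = h0 + kh;
            col[c * KH * KW + kw * KH + kh] =
              (win && h >= 0 && h < H) ? xc[(size_t)w * H + h] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const double *cols, int H, int W, int C,
                   int KH, int KW, int stride, int pad_h, int pad_w,
                   int Ho, int Wo, double *x) {
  const int K = KH * KW * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double *col = cols + (size_t)(wo * Ho + ho) * K;
      const int h0 = ho * stride - pad_h;
      const int w0 = wo * stride - pad_w;
      for (int c = 0; c < C; ++c) {
        double *xc = x + (size_t)c * H * W;
        for (int kw = 0; kw < KW; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < KH; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            xc[(size_t)w * H + h] += col[c * KH * KW + kw * KH + kh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad_h, int pad_w) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (KH, KW, Cin, Cout)");
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("input channel mismatch: got %d, weights expect %d", C, Cin);
  const int Ho = (H + 2 * pad_h - KH) / stride + 1;
  const int Wo = (W + 2 * pad_w - KW) / stride + 1;
  if (Ho <= 0 || Wo <= 0) stop("kernel larger than padded input");
  const int K = KH * KW * C, P = Ho * Wo;

  NumericVector out = num4(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);    // K x Cout view
  arma::mat cols(K, P);
  arma::rowvec bv(b.begin(), Cout);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad_h, pad_w,
           Ho, Wo, cols.memptr());
    arma::mat on(out.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    on = cols.t() * Wm;                             // P x Cout
    on.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad_h, int pad_w) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int KH = wd[0], KW = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * pad_h - KH) / stride + 1;
  const int Wo = (W + 2 * pad_w - KW) / stride + 1;
  const int K = KH * KW * C, P = Ho * Wo;

  NumericVector dx = num4(H, W, C, N);
  NumericVector dw = num4(KH, KW, C, Cout);
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat cols(K, P), dcols(K, P);
  for (int n = 0; n < N; ++n) {
    arma::mat dOn((double*)dout.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad_h, pad_w,
           Ho, Wo, cols.memptr());
    dWm += cols * dOn;                              // K x Cout
    dbv += arma::sum(dOn, 0).t();
    dcols = Wm * dOn.t();                           // K x P
    col2im(dcols.memptr(), H, W, C, KH, KW, stride, pad_h, pad_w, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  NumericVector out = num4(Ho, Wo, C, N);
  IntegerVector idx = int4(Ho, Wo, C, N);       // argmax within the (H,W) plane
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + ((size_t)n * C + c) * H * W;
      double *op = out.begin() + ((size_t)n * C + c) * Ho * Wo;
      int *ip = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY; int bi = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int w = wo * stride + kw;
            for (int kh = 0; kh < k; ++kh) {
              const int h = ho * stride + kh;
              const double v = xp[(size_t)w * H + h];
              if (v > best) { best = v; bi = w * H + h; }
            }
          }
          op[(size_t)wo * Ho + ho] = best;
          ip[(size_t)wo * Ho + ho] = bi;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector in_dim, IntegerVector idx,
                              NumericVector dout) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  IntegerVector od = dout.attr("dim");
  const int Ho = od[0], Wo = od[1];
  NumericVector dx = num4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double *dxp = dx.begin() + ((size_t)n * C + c) * H * W;
      const double *dop = dout.begin() + ((size_t)n * C + c) * Ho * Wo;
      const int *ip = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int p = 0; p < Ho * Wo; ++p) dxp[ip[p]] += dop[p];
    }
  }
  return dx;
}

// 3x3 average pooling, stride 1, zero padding 1 (inception pooling branch)
// [[Rcpp::export]]
NumericVector avgpool3_fwd_cpp(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  NumericVector out = num4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + ((size_t)n * C + c) * H * W;
      double *op = out.begin() + ((size_t)n * C + c) * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double s = 0.0;
          for (int dw = -1; dw <= 1; ++dw) {
            const int ww = w + dw;
            if (ww < 0 || ww >= W) continue;
            for (int dh = -1; dh <= 1; ++dh) {
              const int hh = h + dh;
              if (hh < 0 || hh >= H) continue;
              s += xp[(size_t)ww * H + hh];
            }
          }
          op[(size_t)w * H + h] = s / 9.0;          // zero-padded count, fixed 9
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool3_bwd_cpp(NumericVector dout) {
  // adjoint of the fixed-divisor zero-padded 3x3 mean: same stencil
  int H, W, C, N; get_dims4(dout, H, W, C, N);
  NumericVector dx = num4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *dop = dout.begin() + ((size_t)n * C + c) * H * W;
      double *dxp = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double s = 0.0;
          for (int dw = -1; dw <= 1; ++dw) {
            const int ww = w + dw;
            if (ww < 0 || ww >= W) continue;
            for (int dh = -1; dh <= 1; ++dh) {
              const int hh = h + dh;
              if (hh < 0 || hh >= H) continue;
              s += dop[(size_t)ww * H + hh];
            }
          }
          dxp[(size_t)w * H + h] = s / 9.0;
        }
    }
  return dx;
}

struct BilinearW { int i0, i1; double w0, w1; };

static std::vector<BilinearW> bilinear_weights(int in, int out) {
  // half-pixel convention (align_corners = false)
  std::vector<BilinearW> w(out);
  const double scale = (double)in / out;
  for (int o = 0; o < out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    const int i0 = (int)std::floor(src);
    const int i1 = std::min(i0 + 1, in - 1);
    const double f = src - i0;
    w[o] = {i0, i1, 1.0 - f, f};
  }
  return w;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_fwd_cpp(NumericVector x, int Ho, int Wo) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  NumericVector out = num4(Ho, Wo, C, N);
  std::vector<BilinearW> wh = bilinear_weights(H, Ho), ww = bilinear_weights(W, Wo);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + ((size_t)n * C + c) * H * W;
      double *op = out.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const BilinearW &bw = ww[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const BilinearW &bh = wh[ho];
          op[(size_t)wo * Ho + ho] =
            bw.w0 * (bh.w0 * xp[(size_t)bw.i0 * H + bh.i0] +
                     bh.w1 * xp[(size_t)bw.i0 * H + bh.i1]) +
            bw.w1 * (bh.w0 * xp[(size_t)bw.i1 * H + bh.i0] +
                     bh.w1 * xp[(size_t)bw.i1 * H + bh.i1]);
        }
      }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_bwd_cpp(NumericVector dout, int H, int W) {
  int Ho, Wo, C, N; get_dims4(dout, Ho, Wo, C, N);
  NumericVector dx = num4(H, W, C, N);
  std::vector<BilinearW> wh = bilinear_weights(H, Ho), ww = bilinear_weights(W, Wo);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *dxp = dx.begin() + ((size_t)n * C + c) * H * W;
      const double *dop = dout.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const BilinearW &bw = ww[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const BilinearW &bh = wh[ho];
          const double g = dop[(size_t)wo * Ho + ho];
          dxp[(size_t)bw.i0 * H + bh.i0] += bw.w0 * bh.w0 * g;
          dxp[(size_t)bw.i0 * H + bh.i1] += bw.w0 * bh.w1 * g;
          dxp[(size_t)bw.i1 * H + bh.i0] += bw.w1 * bh.w0 * g;
          dxp[(size_t)bw.i1 * H + bh.i1] += bw.w1 * bh.w1 * g;
        }
      }
    }
  return dx;
}

// 4-connected component labeling of a binary matrix; labels 1..n, 0 elsewhere
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!m(h, w) || lab(h, w) != 0) continue;
      ++next;
      stack.push_back(w * H + h);
      lab(h, w) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int ph = p % H, pw = p / H;
        const int nh[4] = {ph - 1, ph + 1, ph, ph};
        const int nw[4] = {pw, pw, pw - 1, pw + 1};
        for (int k = 0; k < 4; ++k) {
          if (nh[k] < 0 || nh[k] >= H || nw[k] < 0 || nw[k] >= W) continue;
          if (m(nh[k], nw[k]) && lab(nh[k], nw[k]) == 0) {
            lab(nh[k], nw[k]) = next;
            stack.push_back(nw[k] * H + nh[k]);
          }
        }
      }
    }
  return lab;
}
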