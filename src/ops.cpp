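// Tensor compute kernels for the segmentation network.
//
// Layout conventions (column-major, matching R arrays):
//   activations x : dim (H, W, C, N)
//   conv weights W: dim (kh, kw, Cin, Cout)
// Convolution is implemented as im2col + GEMM (Armadillo). The im2col
// row index r = i + kh*(j + kw*c) matches the column-major flattening of
// one output-channel slice of W, so W can be viewed in place as a
// (kh*kw*Cin) x Cout matrix without copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;


static inline NumericVector alloc4d(int a, int b, int c, int d) {
  NumericVector v((long)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void get_dims4(const NumericVector &x, int *d) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

static inline int conv_out_size(int in, int k, int stride, int pad, int dil) {
  int eff = (k - 1) * dil + 1;
  int out = (in + 2 * pad - eff) / stride + 1;
  if (out < 1) stop("convolution output size would be < 1");
  return out;
}

// Fill the im2col matrix (K x P, K = kh*kw*C, P = Ho*Wo, p = ho + Ho*wo)
// for sample n of x.
static void im2col(const double *x, int H, int W, int C, long samp_off,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat &col) {
  col.zeros();
  const int P = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + samp_off + (long)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        double *colr = col.memptr() + r; // stride K between columns
        const int K = col.n_rows;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j * dil;
          if (wi < 0 || wi >= W) continue;
          const double *xcol = xc + (long)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + i * dil;
            if (hi < 0 || hi >= H) continue;
            colr[(long)(ho + Ho * wo) * K] = xcol[hi];
          }
        }
        (void)P;
      }
    }
  }
}

// Scatter-add the columns matrix back into a sample of dx (col2im).
static void col2im(const arma::mat &col, double *dx, int H, int W, int C,
                   long samp_off, int kh, int kw, int stride, int pad,
                   int dil, int Ho, int Wo) {
  const int K = col.n_rows;
  for (int c = 0; c < C; ++c) {
    double *xc = dx + samp_off + (long)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        const double *colr = col.memptr() + r;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j * dil;
          if (wi < 0 || wi >= W) continue;
          double *xcol = xc + (long)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + i * dil;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += colr[(long)(ho + Ho * wo) * K];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, SEXP bias,
                        int stride, int pad, int dilation) {
  int xd[4];
  get_dims4(x, xd);
  IntegerVector wdim = w.attr("dim");
  if (wdim.size() != 4) stop("weights must be (kh, kw, Cin, Cout)");
  const int H = xd[0], W_ = xd[1], C = xd[2], N = xd[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("input channels do not match weight Cin");
  const int Ho = conv_out_size(H, kh, stride, pad, dilation);
  const int Wo = conv_out_size(W_, kw, stride, pad, dilation);
  const int K = kh * kw * C, P = Ho * Wo;

  NumericVector y = alloc4d(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat col(K, P);
  const bool has_b = !Rf_isNull(bias);
  arma::vec bv = has_b ? arma::vec(REAL(bias), Cout) : arma::vec();

  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W_, C, (long)n * H * W_ * C, kh, kw, stride, pad,
           dilation, Ho, Wo, col);
    arma::mat out = Wm.t() * col; // Cout x P
    if (has_b) out.each_col() += bv;
    // y[ho, wo, c, n] = out(c, p)
    double *yn = y.begin() + (long)n * P * Cout;
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < P; ++p) yn[p + (long)c * P] = out(c, p);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad, int dilation, bool need_dx,
               bool need_db) {
  int xd[4], yd[4];
  get_dims4(x, xd);
  get_dims4(dy, yd);
  IntegerVector wdim = w.attr("dim");
  const int H = xd[0], W_ = xd[1], C = xd[2], N = xd[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = yd[0], Wo = yd[1];
  if (yd[2] != Cout || yd[3] != N) stop("dy shape mismatch");
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat dWm(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) dx = alloc4d(H, W_, C, N);
  arma::mat col(K, P), dym(Cout, P);

  for (int n = 0; n < N; ++n) {
    const double *dyn = dy.begin() + (long)n * P * Cout;
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < P; ++p) dym(c, p) = dyn[p + (long)c * P];
    im2col(x.begin(), H, W_, C, (long)n * H * W_ * C, kh, kw, stride, pad,
           dilation, Ho, Wo, col);
    dWm += col * dym.t();
    if (need_db) db += arma::sum(dym, 1);
    if (need_dx) {
      arma::mat dcol = Wm * dym; // K x P
      col2im(dcol, dx.begin(), H, W_, C, (long)n * H * W_ * C, kh, kw,
             stride, pad, dilation, Ho, Wo);
    }
  }
  NumericVector dW(w.size());
  std::copy(dWm.begin(), dWm.end(), dW.begin());
  dW.attr("dim") = wdim;
  List out = List::create(_["dW"] = dW);
  if (need_db) out["db"] = NumericVector(db.begin(), db.end());
  if (need_dx) out["dx"] = dx;
  return out;
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  int xd[4];
  get_dims4(x, xd);
  const int H = xd[0], W_ = xd[1], C = xd[2], N = xd[3];
  const int Ho = conv_out_size(H, k, stride, pad, 1);
  const int Wo = conv_out_size(W_, k, stride, pad, 1);
  NumericVector y = alloc4d(Ho, Wo, C, N);
  IntegerVector idx(y.size()); // 0-based linear index into x
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  long q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const long off = ((long)n * C + c) * H * W_;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          long bi = -1;
          for (int j = 0; j < k; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W_) continue;
            for (int i = 0; i < k; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              const double v = xp[off + (long)wi * H + hi];
              if (v > best) {
                best = v;
                bi = off + (long)wi * H + hi;
              }
            }
          }
          // y laid out as (Ho, Wo, C, N): position q must match
          const long pos = ho + (long)Ho * (wo + (long)Wo * (c + (long)C * n));
          yp[pos] = best;
          ip[pos] = (int)bi;
          ++q;
        }
      }
    }
  }
  (void)q;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector idx,
                         IntegerVector xdim) {
  NumericVector dx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  const double *dyp = dy.begin();
  const int *ip = idx.begin();
  double *dxp = dx.begin();
  const long n = dy.size();
  for (long q = 0; q < n; ++q) dxp[ip[q]] += dyp[q];
  return dx;
}

// Bilinear 2x upsampling, half-pixel (corners not aligned) convention.
static inline void src_coord(int o, int in, int *i0, int *i1, double *w1) {
  double s = (o + 0.5) / 2.0 - 0.5;
  int f = (int)std::floor(s);
  *w1 = s - f;
  *i0 = f < 0 ? 0 : (f >= in ? in - 1 : f);
  int g = f + 1;
  *i1 = g < 0 ? 0 : (g >= in ? in - 1 : g);
}

// [[Rcpp::export(name = ".upsample2x_fw")]]
NumericVector upsample2x_fw(NumericVector x) {
  int xd[4];
  get_dims4(x, xd);
  const int H = xd[0], W_ = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W_;
  NumericVector y = alloc4d(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> wh(Ho), ww(Wo);
  for (int o = 0; o < Ho; ++o) src_coord(o, H, &h0[o], &h1[o], &wh[o]);
  for (int o = 0; o < Wo; ++o) src_coord(o, W_, &w0[o], &w1[o], &ww[o]);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double *xs = xp + cn * H * W_;
    double *ys = yp + cn * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      const double *c0 = xs + (long)w0[ow] * H;
      const double *c1 = xs + (long)w1[ow] * H;
      const double b = ww[ow];
      for (int oh = 0; oh < Ho; ++oh) {
        const double a = wh[oh];
        ys[oh + (long)ow * Ho] =
            (1 - b) * ((1 - a) * c0[h0[oh]] + a * c0[h1[oh]]) +
            b * ((1 - a) * c1[h0[oh]] + a * c1[h1[oh]]);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2x_bw")]]
NumericVector upsample2x_bw(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W_ = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W_;
  NumericVector dx = alloc4d(H, W_, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> wh(Ho), ww(Wo);
  for (int o = 0; o < Ho; ++o) src_coord(o, H, &h0[o], &h1[o], &wh[o]);
  for (int o = 0; o < Wo; ++o) src_coord(o, W_, &w0[o], &w1[o], &ww[o]);
  const double *dyp = dy.begin();
  double *dxp = dx.begin();
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double *ys = dyp + cn * Ho * Wo;
    double *xs = dxp + cn * H * W_;
    for (int ow = 0; ow < Wo; ++ow) {
      double *c0 = xs + (long)w0[ow] * H;
      double *c1 = xs + (long)w1[ow] * H;
      const double b = ww[ow];
      for (int oh = 0; oh < Ho; ++oh) {
        const double a = wh[oh];
        const double g = ys[oh + (long)ow * Ho];
        c0[h0[oh]] += (1 - b) * (1 - a) * g;
        c0[h1[oh]] += (1 - b) * a * g;
        c1[h0[oh]] += b * (1 - a) * g;
        c1[h1[oh]] += b * a * g;
      }
    }
  }
  return dx;
}

// Connected-component labelling of a binary matrix by flood fill.
// connectivity: 4 or 8 (for the foreground being labelled).
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(IntegerMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W_ = mask.ncol();
  IntegerMatrix lab(H, W_);
  std::vector<long> stack;
  const int dh4[] = {-1, 1, 0, 0}, dw4[] = {0, 0, -1, 1};
  const int dh8[] = {-1, 1, 0, 0, -1, -1, 1, 1},
            dw8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dh = connectivity == 4 ? dh4 : dh8;
  const int *dw = connectivity == 4 ? dw4 : dw8;
  const int nd = connectivity;
  int next = 0;
  for (int w = 0; w < W_; ++w) {
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      lab(h, w) = next;
      stack.push_back(h + (long)H * w);
      while (!stack.empty()) {
        const long p = stack.back();
        stack.pop_back();
        const int ph = p % H, pw = p / H;
        for (int d = 0; d < nd; ++d) {
          const int qh = ph + dh[d], qw = pw + dw[d];
          if (qh < 0 || qh >= H || qw < 0 || qw >= W_) continue;
          if (mask(qh, qw) != 0 && lab(qh, qw) == 0) {
            lab(qh, qw) = next;
            stack.push_back(qh + (long)H * qw);
          }
        }
      }
    }
  }
  return lab;
}
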