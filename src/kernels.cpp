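// Low-level CPU kernels for the segmentation network.
//
// All image tensors are R arrays with dim (H, W, C, N) in R's column-major
// order; convolution weights have dim (KH, KW, Cin, Cout).  Convolutions are
// computed by im2col + BLAS matrix multiply (Armadillo), which is the only
// place the package needs compiled speed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix K (KH*KW*Cin x Ho*Wo) for sample n.
static void im2col(const double* x, int H, int W, int C, int n,
                   int KH, int KW, int stride, int pad,
                   int Ho, int Wo, arma::mat& K) {
  const double* xn = x + (size_t)H * W * C * n;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = xn + (size_t)H * W * c;
        for (int j = 0; j < KW; ++j) {
          int w = w0 + j;
          bool win = (w >= 0 && w < W);
          for (int i = 0; i < KH; ++i) {
            int h = h0 + i;
            int row = i + KH * (j + KW * c);
            K(row, col) = (win && h >= 0 && h < H) ? xc[h + (size_t)H * w] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of a dK column matrix back to the input gradient (col2im).
static void col2im_add(const arma::mat& dK, double* dx, int H, int W, int C,
                       int n, int KH, int KW, int stride, int pad,
                       int Ho, int Wo) {
  double* xn = dx + (size_t)H * W * C * n;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = xn + (size_t)H * W * c;
        for (int j = 0; j < KW; ++j) {
          int w = w0 + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < KH; ++i) {
            int h = h0 + i;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += dK(i + KH * (j + KW * c), col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  int Ho = out_dim(H, KH, stride, pad), Wo = out_dim(W, KW, stride, pad);
  int R = KH * KW * Cin;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), R, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat K(R, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, KH, KW, stride, pad, Ho, Wo, K);
    arma::mat Yn(y.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout, false, true);
    Yn = K.t() * Wm;
    Yn.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_dim(H, KH, stride, pad), Wo = out_dim(W, KW, stride, pad);
  int R = KH * KW * Cin;
  NumericVector dx((size_t)H * W * C * N), dw(w.size()), db(Cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat Wm(w.begin(), R, Cout, false, true);
  arma::mat dWm(dw.begin(), R, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat K(R, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat dYn(dy.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout, false, true);
    im2col(x.begin(), H, W, C, n, KH, KW, stride, pad, Ho, Wo, K);
    dWm += K * dYn;
    dbv += arma::sum(dYn, 0);
    arma::mat dK = Wm * dYn.t();
    col2im_add(dK, dx.begin(), H, W, C, n, KH, KW, stride, pad, Ho, Wo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2.  Also returns the 0-based argmax index into the
// input array so the backward pass is a plain scatter.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t best = base + 2 * ho + (size_t)H * (2 * wo);
          double bv = xp[best];
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t k = base + (2 * ho + di) + (size_t)H * (2 * wo + dj);
              if (xp[k] > bv) { bv = xp[k]; best = k; }
            }
          // column-major output order is (ho, wo, c, n); recompute flat index
          size_t oi = (size_t)ho + Ho * ((size_t)wo + Wo * ((size_t)c + (size_t)C * n));
          y[oi] = bv;
          idx[oi] = (int)best;
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// k x k average pooling with stride k (used for extended-skip downsampling).
// [[Rcpp::export(name = ".avgpool_fwd")]]
NumericVector avgpool_fwd(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / k, Wo = W / k;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di)
              s += xp[base + (k * ho + di) + (size_t)H * (k * wo + dj)];
          y[(size_t)ho + Ho * ((size_t)wo + Wo * ((size_t)c + (size_t)C * n))] = s * inv;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".avgpool_bwd")]]
NumericVector avgpool_bwd(NumericVector dy, int k, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = H / k, Wo = W / k;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dy[(size_t)ho + Ho * ((size_t)wo + Wo * ((size_t)c + (size_t)C * n))] * inv;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di)
              dx[base + (k * ho + di) + (size_t)H * (k * wo + dj)] += g;
        }
    }
  return dx;
}

struct LinW { int i0, i1; double w1; };

static void lin_weights(int in, int out, std::vector<LinW>& v) {
  v.resize(out);
  double scale = (double)in / out;
  for (int d = 0; d < out; ++d) {
    double s = (d + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > in - 1) s = in - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, in - 1);
    v[d] = {i0, i1, s - i0};
  }
}

// Bilinear resize to (Ho, Wo); half-pixel-center convention.
// [[Rcpp::export(name = ".bilinear_fwd")]]
NumericVector bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<LinW> hw, ww;
  lin_weights(H, Ho, hw);
  lin_weights(W, Wo, ww);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const LinW& lw = ww[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const LinW& lh = hw[ho];
          double top = xc[lh.i0 + (size_t)H * lw.i0] * (1 - lw.w1) +
                       xc[lh.i0 + (size_t)H * lw.i1] * lw.w1;
          double bot = xc[lh.i1 + (size_t)H * lw.i0] * (1 - lw.w1) +
                       xc[lh.i1 + (size_t)H * lw.i1] * lw.w1;
          y[(size_t)ho + Ho * ((size_t)wo + Wo * ((size_t)c + (size_t)C * n))] =
            top * (1 - lh.w1) + bot * lh.w1;
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".bilinear_bwd")]]
NumericVector bilinear_bwd(NumericVector dy, IntegerVector xdim) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  std::vector<LinW> hw, ww;
  lin_weights(H, Ho, hw);
  lin_weights(W, Wo, ww);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const LinW& lw = ww[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const LinW& lh = hw[ho];
          double g = dy[(size_t)ho + Ho * ((size_t)wo + Wo * ((size_t)c + (size_t)C * n))];
          xc[lh.i0 + (size_t)H * lw.i0] += g * (1 - lh.w1) * (1 - lw.w1);
          xc[lh.i0 + (size_t)H * lw.i1] += g * (1 - lh.w1) * lw.w1;
          xc[lh.i1 + (size_t)H * lw.i0] += g * lh.w1 * (1 - lw.w1);
          xc[lh.i1 + (size_t)H * lw.i1] += g * lh.w1 * lw.w1;
        }
      }
    }
  return dx;
}
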