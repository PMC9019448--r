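// Low-level tensor kernels for the segmentation networks.
//
// Layout convention (column-major, matching R arrays):
//   activations  (H, W, D, C, N)   index = h + H*(w + W*(d + D*(c + C*n)))
//   conv weights (kh, kw, kd, Cin, Cout)
// 2D slice batches are handled as D == 1.
//
// Convolutions use chunked im2col + GEMM so that the column buffer stays
// bounded regardless of volume size. Transposed convolutions are restricted
// to kernel == stride (the only form the decoders use), which makes the
// scatter non-overlapping.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvGeom {
  int H, W, D, Cin, N;
  int kh, kw, kd, Cout;
  int sh, sw, sd;
  int ph, pw, pd;
  int Ho, Wo, Do;
  long K;     // rows of the im2col matrix
  long Mtot;  // output voxels per sample
};

ConvGeom make_geom(const IntegerVector& xdim, const IntegerVector& wdim,
                   const IntegerVector& stride, const IntegerVector& pad) {
  ConvGeom g;
  g.H = xdim[0]; g.W = xdim[1]; g.D = xdim[2]; g.Cin = xdim[3]; g.N = xdim[4];
  g.kh = wdim[0]; g.kw = wdim[1]; g.kd = wdim[2]; g.Cout = wdim[4];
  if (wdim[3] != g.Cin) stop("conv: weight Cin (%d) != input Cin (%d)", wdim[3], g.Cin);
  g.sh = stride[0]; g.sw = stride[1]; g.sd = stride[2];
  g.ph = pad[0]; g.pw = pad[1]; g.pd = pad[2];
  g.Ho = (g.H + 2 * g.ph - g.kh) / g.sh + 1;
  g.Wo = (g.W + 2 * g.pw - g.kw) / g.sw + 1;
  g.Do = (g.D + 2 * g.pd - g.kd) / g.sd + 1;
  if (g.Ho < 1 || g.Wo < 1 || g.Do < 1) stop("conv: kernel larger than padded input");
  g.K = (long)g.kh * g.kw * g.kd * g.Cin;
  g.Mtot = (long)g.Ho * g.Wo * g.Do;
  return g;
}

long chunk_cols(long K, long Mtot) {
  long m = 4194304L / (K ? K : 1);  // ~32 MB double buffer
  if (m < 64) m = 64;
  if (m > Mtot) m = Mtot;
  return m;
}

// Fill col (K x M) with the im2col block for output columns [m0, m0+M) of
// sample n. Zero entries correspond to padding.
void im2col_chunk(const double* x, const ConvGeom& g, int n, long m0, long M,
                  arma::mat& col) {
  col.zeros();
  const long sampOff = (long)g.H * g.W * g.D * g.Cin * n;
  for (long mi = 0; mi < M; ++mi) {
    long m = m0 + mi;
    int ho = (int)(m % g.Ho);
    int wo = (int)((m / g.Ho) % g.Wo);
    int dd = (int)(m / ((long)g.Ho * g.Wo));
    int h0 = ho * g.sh - g.ph, w0 = wo * g.sw - g.pw, d0 = dd * g.sd - g.pd;
    double* cptr = col.colptr(mi);
    for (int ci = 0; ci < g.Cin; ++ci) {
      const long cOff = sampOff + (long)g.H * g.W * g.D * ci;
      for (int k = 0; k < g.kd; ++k) {
        int d = d0 + k;
        if (d < 0 || d >= g.D) continue;
        for (int j = 0; j < g.kw; ++j) {
          int w = w0 + j;
          if (w < 0 || w >= g.W) continue;
          const long base = cOff + (long)g.H * (w + (long)g.W * d);
          long r = (long)g.kh * (j + (long)g.kw * (k + (long)g.kd * ci));
          for (int i = 0; i < g.kh; ++i) {
            int h = h0 + i;
            if (h >= 0 && h < g.H) cptr[r + i] = x[base + h];
          }
        }
      }
    }
  }
}

// Scatter-add dcol (K x M) back into dx for sample n (col2im transpose).
void col2im_chunk(double* dx, const ConvGeom& g, int n, long m0, long M,
                  const arma::mat& dcol) {
  const long sampOff = (long)g.H * g.W * g.D * g.Cin * n;
  for (long mi = 0; mi < M; ++mi) {
    long m = m0 + mi;
    int ho = (int)(m % g.Ho);
    int wo = (int)((m / g.Ho) % g.Wo);
    int dd = (int)(m / ((long)g.Ho * g.Wo));
    int h0 = ho * g.sh - g.ph, w0 = wo * g.sw - g.pw, d0 = dd * g.sd - g.pd;
    const double* cptr = dcol.colptr(mi);
    for (int ci = 0; ci < g.Cin; ++ci) {
      const long cOff = sampOff + (long)g.H * g.W * g.D * ci;
      for (int k = 0; k < g.kd; ++k) {
        int d = d0 + k;
        if (d < 0 || d >= g.D) continue;
        for (int j = 0; j < g.kw; ++j) {
          int w = w0 + j;
          if (w < 0 || w >= g.W) continue;
          const long base = cOff + (long)g.H * (w + (long)g.W * d);
          long r = (long)g.kh * (j + (long)g.kw * (k + (long)g.kd * ci));
          for (int i = 0; i < g.kh; ++i) {
            int h = h0 + i;
            if (h >= 0 && h < g.H) dx[base + h] += cptr[r + i];
          }
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_conv3d_forward")]]
NumericVector cpp_conv3d_forward(const NumericVector& x, const IntegerVector& xdim,
                                 const NumericVector& w, const IntegerVector& wdim,
                                 const NumericVector& bias,
                                 const IntegerVector& stride, const IntegerVector& pad) {
  ConvGeom g = make_geom(xdim, wdim, stride, pad);
  NumericVector y((long)g.Mtot * g.Cout * g.N);
  arma::mat Wm(const_cast<double*>(w.begin()), g.K, g.Cout, false, true);
  long Mc = chunk_cols(g.K, g.Mtot);
  arma::mat col(g.K, Mc);
  for (int n = 0; n < g.N; ++n) {
    arma::mat Y(y.begin() + (long)g.Mtot * g.Cout * n, g.Mtot, g.Cout, false, true);
    for (long m0 = 0; m0 < g.Mtot; m0 += Mc) {
      long M = std::min(Mc, g.Mtot - m0);
      arma::mat cview = col.head_cols(M);
      im2col_chunk(x.begin(), g, n, m0, M, cview);
      Y.rows(m0, m0 + M - 1) = cview.t() * Wm;
    }
    for (int co = 0; co < g.Cout; ++co) Y.col(co) += bias[co];
  }
  y.attr("dim") = IntegerVector::create(g.Ho, g.Wo, g.Do, g.Cout, g.N);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv3d_backward_input")]]
NumericVector cpp_conv3d_backward_input(const NumericVector& dy, const IntegerVector& xdim,
                                        const NumericVector& w, const IntegerVector& wdim,
                                        const IntegerVector& stride, const IntegerVector& pad) {
  ConvGeom g = make_geom(xdim, wdim, stride, pad);
  NumericVector dx((long)g.H * g.W * g.D * g.Cin * g.N);
  arma::mat Wm(const_cast<double*>(w.begin()), g.K, g.Cout, false, true);
  long Mc = chunk_cols(g.K, g.Mtot);
  for (int n = 0; n < g.N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (long)g.Mtot * g.Cout * n,
                 g.Mtot, g.Cout, false, true);
    for (long m0 = 0; m0 < g.Mtot; m0 += Mc) {
      long M = std::min(Mc, g.Mtot - m0);
      arma::mat dcol = Wm * dY.rows(m0, m0 + M - 1).t();
      col2im_chunk(dx.begin(), g, n, m0, M, dcol);
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export(name = ".cpp_conv3d_backward_weights")]]
List cpp_conv3d_backward_weights(const NumericVector& x, const IntegerVector& xdim,
                                 const NumericVector& dy,
                                 const IntegerVector& wdim,
                                 const IntegerVector& stride, const IntegerVector& pad) {
  ConvGeom g = make_geom(xdim, wdim, stride, pad);
  NumericVector dw((long)g.K * g.Cout);
  NumericVector db(g.Cout);
  arma::mat dW(dw.begin(), g.K, g.Cout, false, true);
  arma::vec dB(db.begin(), g.Cout, false, true);
  long Mc = chunk_cols(g.K, g.Mtot);
  arma::mat col(g.K, Mc);
  for (int n = 0; n < g.N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (long)g.Mtot * g.Cout * n,
                 g.Mtot, g.Cout, false, true);
    for (long m0 = 0; m0 < g.Mtot; m0 += Mc) {
      long M = std::min(Mc, g.Mtot - m0);
      arma::mat cview = col.head_cols(M);
      im2col_chunk(x.begin(), g, n, m0, M, cview);
      dW += cview * dY.rows(m0, m0 + M - 1);
    }
    dB += arma::sum(dY, 0).t();
  }
  dw.attr("dim") = wdim;
  return List::create(_["dw"] = dw, _["db"] = db);
}

namespace {

// Rearranged weight matrix for transposed conv: (Cin x P), P = kh*kw*kd*Cout,
// p = i + kh*(j + kw*(k + kd*co)).
arma::mat fold_tr_weights(const NumericVector& w, const IntegerVector& wdim) {
  int kh = wdim[0], kw = wdim[1], kd = wdim[2], Cin = wdim[3], Cout = wdim[4];
  long P = (long)kh * kw * kd * Cout;
  arma::mat Wr(Cin, P);
  const double* wp = w.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int k = 0; k < kd; ++k)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            long src = i + (long)kh * (j + (long)kw * (k + (long)kd * (ci + (long)Cin * co)));
            long p = i + (long)kh * (j + (long)kw * (k + (long)kd * co));
            Wr(ci, p) = wp[src];
          }
  return Wr;
}

}  // namespace

// Transposed conv with kernel == stride: each input voxel paints a disjoint
// kh x kw x kd block of the output.
// [[Rcpp::export(name = ".cpp_convtr3d_forward")]]
NumericVector cpp_convtr3d_forward(const NumericVector& x, const IntegerVector& xdim,
                                   const NumericVector& w, const IntegerVector& wdim,
                                   const NumericVector& bias) {
  int H = xdim[0], W = xdim[1], D = xdim[2], Cin = xdim[3], N = xdim[4];
  int kh = wdim[0], kw = wdim[1], kd = wdim[2], Cout = wdim[4];
  if (wdim[3] != Cin) stop("convtr: weight Cin mismatch");
  int Ho = H * kh, Wo = W * kw, Do = D * kd;
  long M = (long)H * W * D, P = (long)kh * kw * kd * Cout;
  NumericVector y((long)Ho * Wo * Do * Cout * N);
  arma::mat Wr = fold_tr_weights(w, wdim);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + M * Cin * n, M, Cin, false, true);
    arma::mat Cols = X * Wr;  // M x P
    double* yp = y.begin() + (long)Ho * Wo * Do * Cout * n;
    for (long m = 0; m < M; ++m) {
      int h = (int)(m % H), wq = (int)((m / H) % W), d = (int)(m / ((long)H * W));
      for (int co = 0; co < Cout; ++co) {
        const long cOff = (long)Ho * Wo * Do * co;
        for (int k = 0; k < kd; ++k)
          for (int j = 0; j < kw; ++j) {
            long base = cOff + (long)(h * kh) +
                        (long)Ho * ((wq * kw + j) + (long)Wo * (d * kd + k));
            long p = (long)kh * (j + (long)kw * (k + (long)kd * co));
            for (int i = 0; i < kh; ++i)
              yp[base + i] = Cols(m, p + i) + bias[co];
          }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".cpp_convtr3d_backward")]]
List cpp_convtr3d_backward(const NumericVector& x, const IntegerVector& xdim,
                           const NumericVector& dy,
                           const NumericVector& w, const IntegerVector& wdim) {
  int H = xdim[0], W = xdim[1], D = xdim[2], Cin = xdim[3], N = xdim[4];
  int kh = wdim[0], kw = wdim[1], kd = wdim[2], Cout = wdim[4];
  int Ho = H * kh, Wo = W * kw, Do = D * kd;
  long M = (long)H * W * D, P = (long)kh * kw * kd * Cout;
  arma::mat Wr = fold_tr_weights(w, wdim);
  NumericVector dx((long)H * W * D * Cin * N);
  NumericVector dwv(w.size());
  NumericVector db(Cout);
  arma::mat dWr(Cin, P, arma::fill::zeros);
  arma::vec dB(db.begin(), Cout, false, true);
  arma::mat dCols(M, P);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (long)Ho * Wo * Do * Cout * n;
    for (long m = 0; m < M; ++m) {
      int h = (int)(m % H), wq = (int)((m / H) % W), d = (int)(m / ((long)H * W));
      for (int co = 0; co < Cout; ++co) {
        const long cOff = (long)Ho * Wo * Do * co;
        for (int k = 0; k < kd; ++k)
          for (int j = 0; j < kw; ++j) {
            long base = cOff + (long)(h * kh) +
                        (long)Ho * ((wq * kw + j) + (long)Wo * (d * kd + k));
            long p = (long)kh * (j + (long)kw * (k + (long)kd * co));
            for (int i = 0; i < kh; ++i)
              dCols(m, p + i) = dyp[base + i];
          }
      }
    }
    arma::mat X(const_cast<double*>(x.begin()) + M * Cin * n, M, Cin, false, true);
    arma::mat dX(dx.begin() + M * Cin * n, M, Cin, false, true);
    dX = dCols * Wr.t();
    dWr += X.t() * dCols;
    // bias: sum of dy over all voxels per output channel
    for (int co = 0; co < Cout; ++co) {
      const double* cp = dyp + (long)Ho * Wo * Do * co;
      double s = 0.0;
      for (long q = 0; q < (long)Ho * Wo * Do; ++q) s += cp[q];
      dB(co) += s;
    }
  }
  // unfold dWr back to (kh,kw,kd,Cin,Cout)
  double* dwp = dwv.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int k = 0; k < kd; ++k)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            long dst = i + (long)kh * (j + (long)kw * (k + (long)kd * (ci + (long)Cin * co)));
            long p = i + (long)kh * (j + (long)kw * (k + (long)kd * co));
            dwp[dst] = dWr(ci, p);
          }
  dx.attr("dim") = xdim;
  dwv.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// Pooling. type 0 = max (argmax recorded as 1-based linear index into x),
// type 1 = average over valid (non-padding) window elements.
// [[Rcpp::export(name = ".cpp_pool3d_forward")]]
List cpp_pool3d_forward(const NumericVector& x, const IntegerVector& xdim,
                        const IntegerVector& kernel, const IntegerVector& stride,
                        const IntegerVector& pad, int type) {
  int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  int kh = kernel[0], kw = kernel[1], kd = kernel[2];
  int sh = stride[0], sw = stride[1], sd = stride[2];
  int ph = pad[0], pw = pad[1], pd = pad[2];
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  int Do = (D + 2 * pd - kd) / sd + 1;
  if (Ho < 1 || Wo < 1 || Do < 1) stop("pool: kernel larger than padded input");
  long Mo = (long)Ho * Wo * Do;
  NumericVector y(Mo * C * N);
  IntegerVector arg(type == 0 ? (Mo * C * N) : 0);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long inOff = (long)H * W * D * (c + (long)C * n);
      const long outOff = Mo * (c + (long)C * n);
      for (int dd = 0; dd < Do; ++dd)
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho) {
            double best = -HUGE_VAL, acc = 0.0;
            long bestIdx = -1; int cnt = 0;
            for (int k = 0; k < kd; ++k) {
              int d = dd * sd - pd + k;
              if (d < 0 || d >= D) continue;
              for (int j = 0; j < kw; ++j) {
                int w = wo * sw - pw + j;
                if (w < 0 || w >= W) continue;
                for (int i = 0; i < kh; ++i) {
                  int h = ho * sh - ph + i;
                  if (h < 0 || h >= H) continue;
                  long idx = inOff + h + (long)H * (w + (long)W * d);
                  double v = xp[idx];
                  ++cnt; acc += v;
                  if (v > best) { best = v; bestIdx = idx; }
                }
              }
            }
            long o = outOff + ho + (long)Ho * (wo + (long)Wo * dd);
            if (type == 0) { yp[o] = best; arg[o] = (int)(bestIdx + 1); }
            else yp[o] = cnt > 0 ? acc / cnt : 0.0;
          }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, C, N);
  List out = List::create(_["y"] = y, _["argmax"] = arg);
  return out;
}

// [[Rcpp::export(name = ".cpp_pool3d_backward")]]
NumericVector cpp_pool3d_backward(const NumericVector& dy, const IntegerVector& xdim,
                                  const IntegerVector& kernel, const IntegerVector& stride,
                                  const IntegerVector& pad, int type,
                                  const IntegerVector& argmax) {
  int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  int kh = kernel[0], kw = kernel[1], kd = kernel[2];
  int sh = stride[0], sw = stride[1], sd = stride[2];
  int ph = pad[0], pw = pad[1], pd = pad[2];
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  int Do = (D + 2 * pd - kd) / sd + 1;
  long Mo = (long)Ho * Wo * Do;
  NumericVector dx((long)H * W * D * C * N);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  if (type == 0) {
    for (long o = 0; o < (long)Mo * C * N; ++o)
      if (argmax[o] > 0) dxp[argmax[o] - 1] += dyp[o];
  } else {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const long inOff = (long)H * W * D * (c + (long)C * n);
        const long outOff = Mo * (c + (long)C * n);
        for (int dd = 0; dd < Do; ++dd)
          for (int wo = 0; wo < Wo; ++wo)
            for (int ho = 0; ho < Ho; ++ho) {
              int cnt = 0;
              for (int k = 0; k < kd; ++k) {
                int d = dd * sd - pd + k;
                if (d < 0 || d >= D) continue;
                for (int j = 0; j < kw; ++j) {
                  int w = wo * sw - pw + j;
                  if (w < 0 || w >= W) continue;
                  for (int i = 0; i < kh; ++i) {
                    int h = ho * sh - ph + i;
                    if (h >= 0 && h < H) ++cnt;
                  }
                }
              }
              if (cnt == 0) continue;
              double g = dyp[outOff + ho + (long)Ho * (wo + (long)Wo * dd)] / cnt;
              for (int k = 0; k < kd; ++k) {
                int d = dd * sd - pd + k;
                if (d < 0 || d >= D) continue;
                for (int j = 0; j < kw; ++j) {
                  int w = wo * sw - pw + j;
                  if (w < 0 || w >= W) continue;
                  for (int i = 0; i < kh; ++i) {
                    int h = ho * sh - ph + i;
                    if (h >= 0 && h < H)
                      dxp[inOff + h + (long)H * (w + (long)W * d)] += g;
                  }
                }
              }
            }
      }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// ---- per-channel helpers (hot path of batch norm / SE gating) ----

// y = x * a[c,n] + b[c,n]; a, b are C x N matrices
// [[Rcpp::export(name = ".cpp_channel_affine")]]
NumericVector cpp_channel_affine(const NumericVector& x, const IntegerVector& xdim,
                                 const NumericMatrix& a, const NumericMatrix& b) {
  long hwd = (long)xdim[0] * xdim[1] * xdim[2];
  int C = xdim[3], N = xdim[4];
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double aa = a(c, n), bb = b(c, n);
      long off = hwd * (c + (long)C * n);
      for (long i = 0; i < hwd; ++i) yp[off + i] = xp[off + i] * aa + bb;
    }
  y.attr("dim") = xdim;
  return y;
}

// per-channel, per-sample sums of x (or of x*y when y is given): C x N
// [[Rcpp::export(name = ".cpp_channel_dot")]]
NumericMatrix cpp_channel_dot(const NumericVector& x, const IntegerVector& xdim,
                              const Nullable<NumericVector>& y) {
  long hwd = (long)xdim[0] * xdim[1] * xdim[2];
  int C = xdim[3], N = xdim[4];
  NumericMatrix out(C, N);
  const double* xp = x.begin();
  if (y.isNotNull()) {
    NumericVector yy(y);
    const double* yp = yy.begin();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        long off = hwd * (c + (long)C * n);
        double s = 0.0;
        for (long i = 0; i < hwd; ++i) s += xp[off + i] * yp[off + i];
        out(c, n) = s;
      }
  } else {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        long off = hwd * (c + (long)C * n);
        double s = 0.0;
        for (long i = 0; i < hwd; ++i) s += xp[off + i];
        out(c, n) = s;
      }
  }
  return out;
}

// broadcast a C x N matrix over (H,W,D,C,N)
// [[Rcpp::export(name = ".cpp_channel_expand")]]
NumericVector cpp_channel_expand(const NumericMatrix& a, const IntegerVector& xdim) {
  long hwd = (long)xdim[0] * xdim[1] * xdim[2];
  int C = xdim[3], N = xdim[4];
  NumericVector y(hwd * C * N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double aa = a(c, n);
      long off = hwd * (c + (long)C * n);
      for (long i = 0; i < hwd; ++i) yp[off + i] = aa;
    }
  y.attr("dim") = xdim;
  return y;
}
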