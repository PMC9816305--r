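// Convolution primitives used by every network variant.
//
// Feature maps are H x W x C numeric arrays (channels last, column-major);
// convolutions are cross-correlations with zero same-padding and stride 1.
// Each k x k kernel is applied as k^2 "tap" GEMMs over the valid spatial
// window, which keeps the heavy work inside BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::IntegerVector;
using Rcpp::List;
using Rcpp::NumericVector;

// Valid output rows/cols for a tap with offset `off` on an axis of length n.
static inline bool tap_range(int off, int n, int& a0, int& a1) {
  a0 = std::max(0, -off);
  a1 = std::min(n - 1, n - 1 - off);
  return a1 >= a0;
}

// Cin x Cout weight matrix of tap (ti, tj) from a (k, k, Cin, Cout) array.
static mat tap_weights(const NumericVector& w, int k, int Cin, int Cout,
                       int ti, int tj) {
  mat Wt(Cin, Cout);
  const double* p = w.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wt(ci, co) = p[ti + (size_t)k * (tj + (size_t)k * (ci + (size_t)Cin * co))];
  return Wt;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const Rcpp::NumericVector& w,
                          const arma::vec& b, int dilation) {
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  const int c0 = (k - 1) / 2;
  cube y(H, W, Cout, fill::zeros);
  for (int ti = 0; ti < k; ++ti) {
    for (int tj = 0; tj < k; ++tj) {
      const int oi = dilation * (ti - c0), oj = dilation * (tj - c0);
      int yr0, yr1, yc0, yc1;
      if (!tap_range(oi, H, yr0, yr1) || !tap_range(oj, W, yc0, yc1)) continue;
      const int nr = yr1 - yr0 + 1, nc = yc1 - yc0 + 1;
      mat Wt = tap_weights(w, k, Cin, Cout, ti, tj);
      cube xs = x.subcube(yr0 + oi, yc0 + oj, 0, yr1 + oi, yc1 + oj, Cin - 1);
      mat Xm(xs.memptr(), (size_t)nr * nc, Cin, false);
      mat Ym = Xm * Wt;
      cube Yc(Ym.memptr(), nr, nc, Cout, false);
      y.subcube(yr0, yc0, 0, yr1, yc1, Cout - 1) += Yc;
    }
  }
  for (int co = 0; co < Cout; ++co) y.slice(co) += b(co);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const Rcpp::NumericVector& w,
                          const arma::cube& gy, int dilation) {
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  const int c0 = (k - 1) / 2;
  cube gx(H, W, Cin, fill::zeros);
  NumericVector gw((size_t)k * k * Cin * Cout);
  gw.attr("dim") = wd;
  vec gb(Cout);
  for (int co = 0; co < Cout; ++co) gb(co) = accu(gy.slice(co));
  for (int ti = 0; ti < k; ++ti) {
    for (int tj = 0; tj < k; ++tj) {
      const int oi = dilation * (ti - c0), oj = dilation * (tj - c0);
      int yr0, yr1, yc0, yc1;
      if (!tap_range(oi, H, yr0, yr1) || !tap_range(oj, W, yc0, yc1)) continue;
      const int nr = yr1 - yr0 + 1, nc = yc1 - yc0 + 1;
      mat Wt = tap_weights(w, k, Cin, Cout, ti, tj);
      cube xs = x.subcube(yr0 + oi, yc0 + oj, 0, yr1 + oi, yc1 + oj, Cin - 1);
      cube gs = gy.subcube(yr0, yc0, 0, yr1, yc1, Cout - 1);
      mat Xm(xs.memptr(), (size_t)nr * nc, Cin, false);
      mat Gm(gs.memptr(), (size_t)nr * nc, Cout, false);
      mat GW = Xm.t() * Gm;  // Cin x Cout
      double* pg = gw.begin();
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          pg[ti + (size_t)k * (tj + (size_t)k * (ci + (size_t)Cin * co))] +=
              GW(ci, co);
      mat GX = Gm * Wt.t();  // n x Cin
      cube GXc(GX.memptr(), nr, nc, Cin, false);
      gx.subcube(yr0 + oi, yc0 + oj, 0, yr1 + oi, yc1 + oj, Cin - 1) += GXc;
    }
  }
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// Depthwise convolution: one k x k kernel per input channel, w is (k, k, C).
// [[Rcpp::export]]
arma::cube cpp_dwconv_fwd(const arma::cube& x, const Rcpp::NumericVector& w,
                          const arma::vec& b, int dilation) {
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], C = wd[2];
  const int H = x.n_rows, W = x.n_cols;
  const int c0 = (k - 1) / 2;
  const double* pw = w.begin();
  cube y(H, W, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice(c).memptr();
    double* yc = y.slice(c).memptr();
    const double bc = b(c);
    for (size_t i = 0; i < (size_t)H * W; ++i) yc[i] = bc;
    for (int ti = 0; ti < k; ++ti) {
      for (int tj = 0; tj < k; ++tj) {
        const int oi = dilation * (ti - c0), oj = dilation * (tj - c0);
        int yr0, yr1, yc0, yc1;
        if (!tap_range(oi, H, yr0, yr1) || !tap_range(oj, W, yc0, yc1))
          continue;
        const double wt = pw[ti + (size_t)k * (tj + (size_t)k * c)];
        if (wt == 0.0) continue;
        const int nr = yr1 - yr0 + 1;
        for (int j = yc0; j <= yc1; ++j) {
          const double* xp = xc + (size_t)(j + oj) * H + yr0 + oi;
          double* yp = yc + (size_t)j * H + yr0;
          for (int i = 0; i < nr; ++i) yp[i] += wt * xp[i];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_dwconv_bwd(const arma::cube& x, const Rcpp::NumericVector& w,
                          const arma::cube& gy, int dilation) {
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], C = wd[2];
  const int H = x.n_rows, W = x.n_cols;
  const int c0 = (k - 1) / 2;
  const double* pw = w.begin();
  cube gx(H, W, C, fill::zeros);
  NumericVector gw((size_t)k * k * C);
  gw.attr("dim") = wd;
  double* pg = gw.begin();
  vec gb(C);
  for (int c = 0; c < C; ++c) {
    gb(c) = accu(gy.slice(c));
    const double* xc = x.slice(c).memptr();
    const double* gc = gy.slice(c).memptr();
    double* gxc = gx.slice(c).memptr();
    for (int ti = 0; ti < k; ++ti) {
      for (int tj = 0; tj < k; ++tj) {
        const int oi = dilation * (ti - c0), oj = dilation * (tj - c0);
        int yr0, yr1, yc0, yc1;
        if (!tap_range(oi, H, yr0, yr1) || !tap_range(oj, W, yc0, yc1))
          continue;
        const int nr = yr1 - yr0 + 1;
        const double wt = pw[ti + (size_t)k * (tj + (size_t)k * c)];
        double acc = 0.0;
        for (int j = yc0; j <= yc1; ++j) {
          const double* xp = xc + (size_t)(j + oj) * H + yr0 + oi;
          const double* gp = gc + (size_t)j * H + yr0;
          double* gxp = gxc + (size_t)(j + oj) * H + yr0 + oi;
          for (int i = 0; i < nr; ++i) {
            acc += gp[i] * xp[i];
            gxp[i] += wt * gp[i];
          }
        }
        pg[ti + (size_t)k * (tj + (size_t)k * c)] += acc;
      }
    }
  }
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// Non-overlapping spatial max pooling; remainder rows/cols are dropped.
// Returns the pooled map and the 0-based flat (h + H * w) argmax per window.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const arma::cube& x, int size) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / size, Wo = W / size;
  cube y(Ho, Wo, C);
  IntegerVector idx((size_t)Ho * Wo * C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  int* pi = idx.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice(c).memptr();
    double* yc = y.slice(c).memptr();
    int* ic = pi + (size_t)Ho * Wo * c;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -datum::inf;
        int bi = ho * size + H * wo * size;
        for (int dw = 0; dw < size; ++dw) {
          const double* col = xc + (size_t)(wo * size + dw) * H + ho * size;
          for (int dh = 0; dh < size; ++dh) {
            if (col[dh] > best) {
              best = col[dh];
              bi = ho * size + dh + H * (wo * size + dw);
            }
          }
        }
        yc[ho + (size_t)Ho * wo] = best;
        ic[ho + (size_t)Ho * wo] = bi;
      }
    }
  }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// Elementwise ReLU preserving dims.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_relu(const Rcpp::NumericVector& x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* px = x.begin();
  double* py = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) py[i] = px[i] > 0 ? px[i] : 0;
  return y;
}

// gy * (ref > 0): the ReLU backward mask applied in one pass. `ref` may be
// the pre- or post-activation tensor (same sign pattern where it matters).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_relu_bwd(const Rcpp::NumericVector& gy,
                                 const Rcpp::NumericVector& ref) {
  NumericVector g(gy.size());
  g.attr("dim") = gy.attr("dim");
  const double* pg = gy.begin();
  const double* pr = ref.begin();
  double* po = g.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) po[i] = pr[i] > 0 ? pg[i] : 0;
  return g;
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const Rcpp::IntegerVector& idx, const arma::cube& gy,
                           int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  const int* pi = idx.begin();
  for (int c = 0; c < C; ++c) {
    double* gs = gx.slice(c).memptr();
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        gs[pi[ho + (size_t)Ho * (wo + (size_t)Wo * c)]] += gy(ho, wo, c);
  }
  return gx;
}
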