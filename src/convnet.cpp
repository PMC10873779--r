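// Minimal convolutional kernels for the multi-input demo model.
// Image batches are R arrays with dim (H, W, C, N), column-major.
// Convolutions are valid (no padding), stride 1; pooling is 2x2, stride 2.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col patch extraction: rows indexed by (patch, sample) with each
// sample's oH*oW patches contiguous; cols by (kh, kw, channel).
static arma::mat im2col(const double* x, int H, int W, int C, int N,
                        int kh, int kw) {
  int oH = H - kh + 1, oW = W - kw + 1, P = oH * oW;
  arma::mat out(P * N, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (size_t)c * H * W;
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          int col = i + kh * (j + kw * c);
          double* o = out.colptr(col) + (size_t)n * P;
          for (int ow = 0; ow < oW; ++ow) {
            const double* src = xc + (size_t)(ow + j) * H + i;
            double* dst = o + (size_t)ow * oH;
            for (int oh = 0; oh < oH; ++oh) dst[oh] = src[oh];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_forward")]]
List conv2d_forward(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  int oH = H - kh + 1, oW = W - kw + 1, P = oH * oW;
  arma::mat Pm = im2col(x.begin(), H, W, C, N, kh, kw);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  arma::mat Y = Pm * Wm;
  Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), F, false, true);
  // reorder (patch, sample) x F  ->  array (oH, oW, F, N)
  NumericVector y((R_xlen_t)oH * oW * F * N);
  y.attr("dim") = IntegerVector::create(oH, oW, F, N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      const double* src = Y.colptr(f) + (size_t)n * P;
      double* dst = yp + (size_t)P * (f + (size_t)F * n);
      std::copy(src, src + P, dst);
    }
  NumericMatrix patches(Pm.n_rows, Pm.n_cols);
  std::copy(Pm.begin(), Pm.end(), patches.begin());
  return List::create(_["y"] = y, _["patches"] = patches);
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericMatrix patches, NumericVector w,
                     NumericVector dy, IntegerVector xdim) {
  IntegerVector wd = w.attr("dim"), yd = dy.attr("dim");
  int kh = wd[0], kw = wd[1], C = wd[2], F = wd[3];
  int oH = yd[0], oW = yd[1], N = yd[3], P = oH * oW;
  int H = xdim[0], W = xdim[1];
  // dy array -> matrix with im2col row order
  arma::mat dY(P * N, F);
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      const double* src = dyp + (size_t)P * (f + (size_t)F * n);
      std::copy(src, src + P, dY.colptr(f) + (size_t)n * P);
    }
  arma::mat Pm(patches.begin(), patches.nrow(), patches.ncol(), false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  arma::mat dWm = Pm.t() * dY;
  arma::rowvec dbv = arma::sum(dY, 0);
  arma::mat dP = dY * Wm.t();
  NumericVector dw(dWm.begin(), dWm.end());
  dw.attr("dim") = wd;
  NumericVector db(dbv.begin(), dbv.end());
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    double* xn = dxp + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* xc = xn + (size_t)c * H * W;
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          int col = i + kh * (j + kw * c);
          const double* g = dP.colptr(col) + (size_t)n * P;
          for (int ow = 0; ow < oW; ++ow) {
            double* dst = xc + (size_t)(ow + j) * H + i;
            const double* src = g + (size_t)ow * oH;
            for (int oh = 0; oh < oH; ++oh) dst[oh] += src[oh];
          }
        }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int oH = H / 2, oW = W / 2;
  size_t M = (size_t)oH * oW * C * N;
  NumericVector y(M);
  IntegerVector which(M);  // 1-based linear index into x
  y.attr("dim") = which.attr("dim") = IntegerVector::create(oH, oW, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      size_t yoff = (size_t)oH * oW * (c + (size_t)C * n);
      for (int ow = 0; ow < oW; ++ow)
        for (int oh = 0; oh < oH; ++oh) {
          size_t base = xoff + (size_t)(2 * ow) * H + 2 * oh;
          size_t cand[4] = {base, base + 1, base + H, base + H + 1};
          size_t best = cand[0];
          for (int t = 1; t < 4; ++t)
            if (xp[cand[t]] > xp[best]) best = cand[t];
          size_t yi = yoff + (size_t)ow * oH + oh;
          y[yi] = xp[best];
          which[yi] = (int)(best + 1);
        }
    }
  return List::create(_["y"] = y, _["which"] = which);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(IntegerVector which, NumericVector dy,
                                IntegerVector xdim) {
  size_t M = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(M);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[which[i] - 1] += dy[i];
  return dx;
}
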