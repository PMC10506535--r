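// im2col-based 2-D convolution kernels for the GAN framework.
// Tensor layout matches R arrays: x is H x W x C (column-major), weights are
// kh x kw x Cin x Cout, so the flattened patch index is
// iy + kh*(ix + kw*c), identical to R's dim ordering.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void conv_out_dims(int H, int W, int kh, int kw, int stride, int pad,
                          int& Ho, int& Wo) {
  Ho = (H + 2 * pad - kh) / stride + 1;
  Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("convolution input smaller than kernel");
}

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride,
                        int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols((arma::uword)Ho * Wo, (arma::uword)kh * kw * C,
                 arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ix = 0; ix < kw; ++ix) {
      for (int iy = 0; iy < kh; ++iy) {
        const arma::uword colidx = iy + (arma::uword)kh * (ix + (arma::uword)kw * c);
        for (int ox = 0; ox < Wo; ++ox) {
          const int sx = ox * stride + ix - pad;
          if (sx < 0 || sx >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int sy = oy * stride + iy - pad;
            if (sy < 0 || sy >= H) continue;
            cols(oy + (arma::uword)Ho * ox, colidx) = x(sy, sx, c);
          }
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C, int kh,
                         int kw, int stride, int pad, int Ho, int Wo) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ix = 0; ix < kw; ++ix) {
      for (int iy = 0; iy < kh; ++iy) {
        const arma::uword colidx = iy + (arma::uword)kh * (ix + (arma::uword)kw * c);
        for (int ox = 0; ox < Wo; ++ox) {
          const int sx = ox * stride + ix - pad;
          if (sx < 0 || sx >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int sy = oy * stride + iy - pad;
            if (sy < 0 || sy >= H) continue;
            x(sy, sx, c) += cols(oy + (arma::uword)Ho * ox, colidx);
          }
        }
      }
    }
  }
  return x;
}

static arma::cube as_cube(const NumericVector& v, std::string what) {
  IntegerVector d = v.attr("dim");
  if (d.size() != 3) stop("%s must be a 3-d array (H x W x C)", what.c_str());
  arma::cube out((const double*)v.begin(), d[0], d[1], d[2]);
  return out;
}

// Forward pass; optionally also returns the im2col matrix so the backward
// pass can skip recomputing it.
// [[Rcpp::export(name = ".conv2d_fwd", rng = false)]]
List conv2d_fwd(NumericVector x_, NumericVector w_, NumericVector b_,
                int stride, int pad, bool keep_cols) {
  IntegerVector wd = w_.attr("dim");
  if (wd.size() != 4) stop("weights must be kh x kw x Cin x Cout");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  arma::cube x = as_cube(x_, "input");
  if ((int)x.n_slices != cin) stop("input channel count does not match weights");
  int Ho, Wo;
  conv_out_dims(x.n_rows, x.n_cols, kh, kw, stride, pad, Ho, Wo);
  arma::mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat wm((double*)w_.begin(), (arma::uword)kh * kw * cin, cout, false);
  arma::mat y = cols * wm;
  arma::rowvec b((double*)b_.begin(), cout, false);
  y.each_row() += b;
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, cout);
  if (!keep_cols) return List::create(Named("y") = out);
  NumericVector colsv(cols.begin(), cols.end());
  colsv.attr("dim") = IntegerVector::create((int)cols.n_rows,
                                            (int)cols.n_cols);
  return List::create(Named("y") = out, Named("cols") = colsv);
}

// Backward pass. `cols_` may be the cached im2col matrix from the forward
// pass (pass R_NilValue to recompute it from x_).
// [[Rcpp::export(name = ".conv2d_bwd", rng = false)]]
List conv2d_bwd(NumericVector x_, NumericVector w_, NumericVector dy_,
                int stride, int pad, SEXP cols_) {
  IntegerVector wd = w_.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  arma::cube x = as_cube(x_, "input");
  arma::cube dy = as_cube(dy_, "output gradient");
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  arma::mat cols;
  if (Rf_isNull(cols_)) {
    cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  } else {
    NumericMatrix cm(cols_);
    cols = arma::mat(cm.begin(), cm.nrow(), cm.ncol(), false);
  }
  arma::mat wm((double*)w_.begin(), (arma::uword)kh * kw * cin, cout, false);
  arma::mat dym((double*)dy.memptr(), (arma::uword)Ho * Wo, cout, false);
  arma::mat dw = cols.t() * dym;
  arma::rowvec db = arma::sum(dym, 0);
  arma::mat dcols = dym * wm.t();
  arma::cube dx = col2im(dcols, x.n_rows, x.n_cols, cin, kh, kw, stride, pad,
                         Ho, Wo);
  NumericVector dxv(dx.begin(), dx.end());
  dxv.attr("dim") = IntegerVector::create((int)x.n_rows, (int)x.n_cols, cin);
  NumericVector dwv(dw.begin(), dw.end());
  dwv.attr("dim") = IntegerVector::create(kh, kw, cin, cout);
  NumericVector dbv(db.begin(), db.end());
  return List::create(Named("dx") = dxv, Named("dw") = dwv, Named("db") = dbv);
}
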