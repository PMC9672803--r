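#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 3x3x3 convolution, padding 1, stride 1, on batched volumes.
// Layout is R column-major: x has dim (D, H, W, Cin, N), weights are a
// (27*Cin x Cout) matrix whose rows are ordered kd-fastest, then kh, kw, cin
// (i.e. the flattening of an R array with dim c(3, 3, 3, Cin, Cout)).

static void im2col_sample(const double* xn, int D, int H, int W, int C,
                          arma::mat& M) {
  const std::size_t S = (std::size_t)D * H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (std::size_t)c * S;
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh)
        for (int kd = 0; kd < 3; ++kd) {
          const int col = kd + 3 * kh + 9 * kw + 27 * c;
          double* Mcol = M.colptr(col);
          const int dd = kd - 1, dh = kh - 1, dw = kw - 1;
          for (int wv = 0; wv < W; ++wv) {
            const int sw = wv + dw;
            for (int hv = 0; hv < H; ++hv) {
              const int sh = hv + dh;
              double* Mp = Mcol + ((std::size_t)wv * H + hv) * D;
              if (sw < 0 || sw >= W || sh < 0 || sh >= H) {
                std::fill(Mp, Mp + D, 0.0);
                continue;
              }
              const double* src = xc + ((std::size_t)sw * H + sh) * D;
              Mp[0] = (dd >= 0) ? src[0 + dd] : 0.0;
              for (int dv = 1; dv < D - 1; ++dv) Mp[dv] = src[dv + dd];
              Mp[D - 1] = (D - 1 + dd < D) ? src[D - 1 + dd] : 0.0;
              if (D == 1) Mp[0] = (dd == 0) ? src[0] : 0.0;
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericMatrix w, NumericVector b) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int S = D * H * W, K = 27 * C, Cout = w.ncol();
  if (w.nrow() != K) stop("conv3d: weight rows %d != 27*Cin %d", w.nrow(), K);
  if (b.size() != Cout) stop("conv3d: bias length mismatch");
  NumericVector y((R_xlen_t)S * Cout * N);
  y.attr("dim") = IntegerVector::create(D, H, W, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false);
  arma::rowvec bv(b.begin(), Cout, false);
  arma::mat M(S, K);
  for (int n = 0; n < N; ++n) {
    im2col_sample(x.begin() + (std::size_t)n * S * C, D, H, W, C, M);
    arma::mat Y(y.begin() + (std::size_t)n * S * Cout, S, Cout, false, true);
    Y = M * Wm;
    Y.each_row() += bv;
  }
  return y;
}

static void col2im_sample(const arma::mat& DX, double* dxn,
                          int D, int H, int W, int C) {
  const std::size_t S = (std::size_t)D * H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dxn + (std::size_t)c * S;
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh)
        for (int kd = 0; kd < 3; ++kd) {
          const int col = kd + 3 * kh + 9 * kw + 27 * c;
          const double* Mcol = DX.colptr(col);
          const int dd = kd - 1, dh = kh - 1, dw = kw - 1;
          for (int wv = 0; wv < W; ++wv) {
            const int sw = wv + dw;
            if (sw < 0 || sw >= W) continue;
            for (int hv = 0; hv < H; ++hv) {
              const int sh = hv + dh;
              if (sh < 0 || sh >= H) continue;
              const double* Mp = Mcol + ((std::size_t)wv * H + hv) * D;
              double* dst = xc + ((std::size_t)sw * H + sh) * D;
              const int d0 = (dd < 0) ? 1 : 0;
              const int d1 = (dd > 0) ? D - 1 : D;
              for (int dv = d0; dv < d1; ++dv) dst[dv + dd] += Mp[dv];
            }
          }
        }
  }
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericMatrix w, NumericVector dy) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int S = D * H * W, K = 27 * C, Cout = w.ncol();
  NumericVector dx((R_xlen_t)S * C * N);
  dx.attr("dim") = xdim;
  arma::mat Wm(w.begin(), K, Cout, false);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat M(S, K), DX(S, K);
  for (int n = 0; n < N; ++n) {
    im2col_sample(x.begin() + (std::size_t)n * S * C, D, H, W, C, M);
    arma::mat G(const_cast<double*>(dy.begin()) + (std::size_t)n * S * Cout,
                S, Cout, false);
    dW += M.t() * G;
    db += arma::sum(G, 0);
    DX = G * Wm.t();
    col2im_sample(DX, dx.begin() + (std::size_t)n * S * C, D, H, W, C);
  }
  NumericMatrix dWr(K, Cout);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(Cout);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = dbr);
}
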