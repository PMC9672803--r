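#include <Rcpp.h>
using namespace Rcpp;

// 2x2x2 max pooling with stride 2; spatial dims must be even.
// arg stores, per pooled voxel, the linear offset of the winning voxel inside
// its (D,H,W) channel slice, so the backward pass is a pure scatter.

// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  if (D % 2 || H % 2 || W % 2) stop("maxpool3d: spatial dims must be even");
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const std::size_t S = (std::size_t)D * H * W, So = (std::size_t)Do * Ho * Wo;
  NumericVector y((R_xlen_t)So * C * N);
  IntegerVector arg((R_xlen_t)So * C * N);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int nc = 0; nc < N * C; ++nc) {
    const double* xs = xp + (std::size_t)nc * S;
    double* ys = yp + (std::size_t)nc * So;
    int* as = ap + (std::size_t)nc * So;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int doo = 0; doo < Do; ++doo) {
          double best = -1e300; int bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd) {
                const int idx = (2 * doo + dd) + D * ((2 * ho + dh) + H * (2 * wo + dw));
                const double v = xs[idx];
                if (v > best) { best = v; bi = idx; }
              }
          const std::size_t o = doo + (std::size_t)Do * (ho + (std::size_t)Ho * wo);
          ys[o] = best; as[o] = bi;
        }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(NumericVector dy, IntegerVector arg,
                                IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const std::size_t S = (std::size_t)D * H * W;
  const std::size_t So = S / 8;
  NumericVector dx((R_xlen_t)S * C * N);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ap = arg.begin();
  for (int nc = 0; nc < N * C; ++nc) {
    double* dxs = dxp + (std::size_t)nc * S;
    const double* dys = dyp + (std::size_t)nc * So;
    const int* as = ap + (std::size_t)nc * So;
    for (std::size_t o = 0; o < So; ++o) dxs[as[o]] += dys[o];
  }
  return dx;
}

// Trilinear 2x upsampling (align_corners = false): output voxel o samples the
// input at (o + 0.5)/2 - 0.5, clamped at the borders.

static void axis_weights(int n_in, int n_out, std::vector<int>& i0,
                         std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(n_out); i1.resize(n_out); w1.resize(n_out);
  for (int o = 0; o < n_out; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int lo = (int)std::floor(src);
    if (lo > n_in - 2) lo = n_in - 2;
    if (lo < 0) lo = 0;
    i0[o] = lo; i1[o] = (n_in == 1) ? 0 : lo + 1;
    w1[o] = (n_in == 1) ? 0.0 : src - lo;
  }
}

// [[Rcpp::export]]
NumericVector upsample2x_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  const std::size_t S = (std::size_t)D * H * W, So = (std::size_t)Do * Ho * Wo;
  NumericVector y((R_xlen_t)So * C * N);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  std::vector<int> d0, d1, h0, h1, w0, w1;
  std::vector<double> wd, wh, ww;
  axis_weights(D, Do, d0, d1, wd);
  axis_weights(H, Ho, h0, h1, wh);
  axis_weights(W, Wo, w0, w1, ww);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int nc = 0; nc < N * C; ++nc) {
    const double* xs = xp + (std::size_t)nc * S;
    double* ys = yp + (std::size_t)nc * So;
    for (int wo = 0; wo < Wo; ++wo) {
      const double fw = ww[wo];
      const std::size_t wA = (std::size_t)w0[wo] * H, wB = (std::size_t)w1[wo] * H;
      for (int ho = 0; ho < Ho; ++ho) {
        const double fh = wh[ho];
        const std::size_t hA = (wA + h0[ho]) * D, hB = (wA + h1[ho]) * D;
        const std::size_t hC = (wB + h0[ho]) * D, hD = (wB + h1[ho]) * D;
        double* yrow = ys + ((std::size_t)wo * Ho + ho) * Do;
        for (int doo = 0; doo < Do; ++doo) {
          const double fd = wd[doo];
          const int a = d0[doo], b = d1[doo];
          const double c00 = xs[hA + a] * (1 - fd) + xs[hA + b] * fd;
          const double c01 = xs[hB + a] * (1 - fd) + xs[hB + b] * fd;
          const double c10 = xs[hC + a] * (1 - fd) + xs[hC + b] * fd;
          const double c11 = xs[hD + a] * (1 - fd) + xs[hD + b] * fd;
          yrow[doo] = (c00 * (1 - fh) + c01 * fh) * (1 - fw)
                    + (c10 * (1 - fh) + c11 * fh) * fw;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2x_bwd_cpp(NumericVector dy, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  const std::size_t S = (std::size_t)D * H * W, So = (std::size_t)Do * Ho * Wo;
  NumericVector dx((R_xlen_t)S * C * N);
  dx.attr("dim") = xdim;
  std::vector<int> d0, d1, h0, h1, w0, w1;
  std::vector<double> wd, wh, ww;
  axis_weights(D, Do, d0, d1, wd);
  axis_weights(H, Ho, h0, h1, wh);
  axis_weights(W, Wo, w0, w1, ww);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int nc = 0; nc < N * C; ++nc) {
    double* dxs = dxp + (std::size_t)nc * S;
    const double* dys = dyp + (std::size_t)nc * So;
    for (int wo = 0; wo < Wo; ++wo) {
      const double fw = ww[wo];
      const std::size_t wA = (std::size_t)w0[wo] * H, wB = (std::size_t)w1[wo] * H;
      for (int ho = 0; ho < Ho; ++ho) {
        const double fh = wh[ho];
        const std::size_t hA = (wA + h0[ho]) * D, hB = (wA + h1[ho]) * D;
        const std::size_t hC = (wB + h0[ho]) * D, hD = (wB + h1[ho]) * D;
        const double* grow = dys + ((std::size_t)wo * Ho + ho) * Do;
        for (int doo = 0; doo < Do; ++doo) {
          const double g = grow[doo];
          if (g == 0.0) continue;
          const double fd = wd[doo];
          const int a = d0[doo], b = d1[doo];
          dxs[hA + a] += g * (1 - fd) * (1 - fh) * (1 - fw);
          dxs[hA + b] += g * fd * (1 - fh) * (1 - fw);
          dxs[hB + a] += g * (1 - fd) * fh * (1 - fw);
          dxs[hB + b] += g * fd * fh * (1 - fw);
          dxs[hC + a] += g * (1 - fd) * (1 - fh) * fw;
          dxs[hC + b] += g * fd * (1 - fh) * fw;
          dxs[hD + a] += g * (1 - fd) * fh * fw;
          dxs[hD + b] += g * fd * fh * fw;
        }
      }
    }
  }
  return dx;
}
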