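#include <Rcpp.h>
using namespace Rcpp;

// Volume resampling onto a new voxel grid with the same field of view.
// Output voxel centers map to input continuous coordinates by
//   src = (i + 0.5) * out_spacing / in_spacing - 0.5
// (center-of-first-voxel alignment), clamped at the borders.

struct AxisMap {
  std::vector<int> i0, i1, nn;
  std::vector<double> f;
};

static AxisMap axis_map(int n_in, int n_out, double in_sp, double out_sp) {
  AxisMap m;
  m.i0.resize(n_out); m.i1.resize(n_out); m.nn.resize(n_out); m.f.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) * out_sp / in_sp - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int lo = (int)std::floor(src);
    if (lo > n_in - 2) lo = std::max(0, n_in - 2);
    double f = src - lo;
    m.i0[i] = lo;
    m.i1[i] = (n_in == 1) ? 0 : lo + 1;
    m.f[i] = (n_in == 1) ? 0.0 : f;
    m.nn[i] = (int)std::lround(src);
    if (m.nn[i] > n_in - 1) m.nn[i] = n_in - 1;
  }
  return m;
}

// [[Rcpp::export]]
NumericVector resample3d_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector in_sp, IntegerVector odim,
                             NumericVector out_sp, bool nearest) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  AxisMap md = axis_map(D, Do, in_sp[0], out_sp[0]);
  AxisMap mh = axis_map(H, Ho, in_sp[1], out_sp[1]);
  AxisMap mw = axis_map(W, Wo, in_sp[2], out_sp[2]);
  NumericVector y((R_xlen_t)Do * Ho * Wo);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* yrow = yp + ((std::size_t)wo * Ho + ho) * Do;
      if (nearest) {
        const std::size_t base = ((std::size_t)mw.nn[wo] * H + mh.nn[ho]) * D;
        for (int d = 0; d < Do; ++d) yrow[d] = xp[base + md.nn[d]];
      } else {
        const double fh = mh.f[ho], fw = mw.f[wo];
        const std::size_t hA = ((std::size_t)mw.i0[wo] * H + mh.i0[ho]) * D;
        const std::size_t hB = ((std::size_t)mw.i0[wo] * H + mh.i1[ho]) * D;
        const std::size_t hC = ((std::size_t)mw.i1[wo] * H + mh.i0[ho]) * D;
        const std::size_t hD = ((std::size_t)mw.i1[wo] * H + mh.i1[ho]) * D;
        for (int d = 0; d < Do; ++d) {
          const double fd = md.f[d];
          const int a = md.i0[d], b = md.i1[d];
          const double c00 = xp[hA + a] * (1 - fd) + xp[hA + b] * fd;
          const double c01 = xp[hB + a] * (1 - fd) + xp[hB + b] * fd;
          const double c10 = xp[hC + a] * (1 - fd) + xp[hC + b] * fd;
          const double c11 = xp[hD + a] * (1 - fd) + xp[hD + b] * fd;
          yrow[d] = (c00 * (1 - fh) + c01 * fh) * (1 - fw)
                  + (c10 * (1 - fh) + c11 * fh) * fw;
        }
      }
    }
  }
  return y;
}
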