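#include <Rcpp.h>
using namespace Rcpp;

// 3D connected-component labeling of a binary mask by iterative flood fill.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).

// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const std::size_t S = (std::size_t)D * H * W;
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<std::array<int, 3>> nb;
  for (int dw = -1; dw <= 1; ++dw)
    for (int dh = -1; dh <= 1; ++dh)
      for (int dd = -1; dd <= 1; ++dd) {
        const int nz = std::abs(dd) + std::abs(dh) + std::abs(dw);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        nb.push_back({dd, dh, dw});
      }

  IntegerVector labels((R_xlen_t)S);
  labels.attr("dim") = dims;
  int current = 0;
  std::vector<std::size_t> stack;
  const int* mp = mask.begin();
  int* lp = labels.begin();
  for (std::size_t i = 0; i < S; ++i) {
    if (!mp[i] || lp[i]) continue;
    ++current;
    lp[i] = current;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const std::size_t v = stack.back();
      stack.pop_back();
      const int d = (int)(v % D);
      const int h = (int)((v / D) % H);
      const int w = (int)(v / ((std::size_t)D * H));
      for (const auto& o : nb) {
        const int nd = d + o[0], nh = h + o[1], nw = w + o[2];
        if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W)
          continue;
        const std::size_t u = nd + (std::size_t)D * (nh + (std::size_t)H * nw);
        if (mp[u] && !lp[u]) {
          lp[u] = current;
          stack.push_back(u);
        }
      }
    }
  }
  return labels;
}
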