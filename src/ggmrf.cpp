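// Iterated conditional modes for the generalized Gauss-Markov random field
// label smoother.  Raster-order sweeps over non-background pixels; each pixel
// takes the class in 1..K minimizing
//   |obs - c|^alpha + rho^alpha * lambda^beta * sum_r eta * d(est_r, c)^beta
// over the 8-neighborhood, background (0) frozen and excluded from sums.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = "ggmrf_icm_cpp")]]
List ggmrf_icm_cpp(IntegerMatrix observed, double alpha, double beta,
                   double rho, double lambda, double eta, int max_sweeps,
                   bool potts, int n_classes) {
  const int H = observed.nrow(), W = observed.ncol(), K = n_classes;
  IntegerMatrix est = clone(observed);
  const double pair_scale = std::pow(rho, alpha) * std::pow(lambda, beta) * eta;
  // |i - j| over class codes is at most K - 1
  std::vector<double> dpow(K);
  for (int d = 0; d < K; ++d)
    dpow[d] = potts ? (d > 0 ? 1.0 : 0.0) : std::pow((double)d, beta);
  std::vector<double> apow(K);
  for (int d = 0; d < K; ++d)
    apow[d] = potts ? (d > 0 ? 1.0 : 0.0) : std::pow((double)d, alpha);

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  std::vector<int> flips;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    int changed = 0;
    for (int i = 0; i < H; ++i) {
      for (int j = 0; j < W; ++j) {
        const int obs = observed(i, j);
        if (obs == 0) continue;
        int nbr[8]; int nn = 0;
        for (int k = 0; k < 8; ++k) {
          const int r = i + dr[k], c = j + dc[k];
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          const int lab = est(r, c);
          if (lab != 0) nbr[nn++] = lab;
        }
        double best_e = R_PosInf; int best_c = est(i, j);
        for (int cand = 1; cand <= K; ++cand) {
          double e = apow[std::abs(obs - cand)];
          for (int k = 0; k < nn; ++k)
            e += pair_scale * dpow[std::abs(nbr[k] - cand)];
          if (e < best_e - 1e-12) { best_e = e; best_c = cand; }
          else if (std::abs(e - best_e) <= 1e-12 && cand < best_c) best_c = cand;
        }
        if (best_c != est(i, j)) { est(i, j) = best_c; ++changed; }
      }
    }
    flips.push_back(changed);
    if (changed == 0) break;
  }
  return List::create(_["map"] = est, _["flips"] = wrap(flips));
}
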