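// Optical-map molecule-to-map alignment: dynamic programming over label
// intervals. Two runs of consecutive intervals are compatible when their
// summed lengths agree within sizing_tol (relative to the map side). Score =
// matched labels minus miss_penalty per skipped label on either side;
// molecule labels outside the aligned core are penalized as skips.
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_map_align(NumericVector mol, NumericVector map,
                   double sizing_tol, double miss_penalty, int max_skip) {
  int p = mol.size(), q = map.size();
  if (p < 2 || q < 2)
    return List::create(_["score"] = R_NegInf);
  std::vector<double> S((size_t)p * q, R_NegInf);
  std::vector<int> bi((size_t)p * q, -1), bj((size_t)p * q, -1);
  // starting a path at (i, j): unmatched leading molecule labels are skips
  for (int i = 0; i < std::min(p, max_skip + 1); ++i)
    for (int j = 0; j < q; ++j)
      S[(size_t)i * q + j] = 1.0 - miss_penalty * i;
  for (int i = 1; i < p; ++i) {
    for (int j = 1; j < q; ++j) {
      size_t c = (size_t)i * q + j;
      double best = S[c];
      for (int pi = std::max(0, i - 1 - max_skip); pi <= i - 1; ++pi) {
        double dmol = mol[i] - mol[pi];
        for (int pj = std::max(0, j - 1 - max_skip); pj <= j - 1; ++pj) {
          size_t pc = (size_t)pi * q + pj;
          if (S[pc] == R_NegInf) continue;
          double dmap = map[j] - map[pj];
          if (std::fabs(dmol - dmap) > sizing_tol * dmap) continue;
          double sc = S[pc] + 1.0 - miss_penalty * ((i - pi - 1) + (j - pj - 1));
          if (sc > best) { best = sc; bi[c] = pi; bj[c] = pj; }
        }
      }
      S[c] = best;
    }
  }
  double best = R_NegInf;
  int ei = -1, ej = -1;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < q; ++j) {
      if (S[(size_t)i * q + j] == R_NegInf) continue;
      double sc = S[(size_t)i * q + j] - miss_penalty * (p - 1 - i);
      if (sc > best) { best = sc; ei = i; ej = j; }
    }
  if (ei < 0) return List::create(_["score"] = R_NegInf);
  std::vector<int> mi, mj;
  int i = ei, j = ej;
  while (i >= 0 && j >= 0) {
    mi.push_back(i + 1);  // 1-based for R
    mj.push_back(j + 1);
    size_t c = (size_t)i * q + j;
    int ni = bi[c], nj = bj[c];
    i = ni; j = nj;
  }
  std::reverse(mi.begin(), mi.end());
  std::reverse(mj.begin(), mj.end());
  return List::create(_["score"] = best,
                      _["n_matched"] = (int)mi.size(),
                      _["mol_idx"] = wrap(mi),
                      _["map_idx"] = wrap(mj));
}
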