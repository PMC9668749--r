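// Sequence-level error injection and random DNA, driven by R's RNG so that
// set.seed() fully determines output. Error positions are drawn by geometric
// skipping so cost scales with the number of errors, not sequence length.
#include <Rcpp.h>
#include <cmath>
#include <string>

using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export]]
CharacterVector cpp_random_dna(NumericVector lens) {
  CharacterVector out(lens.size());
  for (R_xlen_t i = 0; i < lens.size(); ++i) {
    R_xlen_t n = (R_xlen_t)lens[i];
    std::string s(n, 'A');
    for (R_xlen_t j = 0; j < n; ++j) s[j] = BASES[(int)(unif_rand() * 4) & 3];
    out[i] = s;
  }
  return out;
}

// Inject sequencing errors at per-base rate `err`: fraction sub_frac are
// substitutions, the rest split evenly between 1-bp insertions and deletions.
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double err, double sub_frac) {
  CharacterVector out(seqs.size());
  if (err <= 0) return clone(seqs);
  double log1m = std::log(1.0 - err);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, s));
    std::string o;
    o.reserve(n + 16);
    R_xlen_t i = 0;
    while (true) {
      // distance to next error ~ Geometric(err)
      double u = unif_rand();
      R_xlen_t skip = (u <= 0) ? n : (R_xlen_t)std::floor(std::log(u) / log1m);
      if (i + skip >= n) { o.append(p + i, n - i); break; }
      o.append(p + i, skip);
      i += skip;
      double t = unif_rand();
      if (t < sub_frac) {                      // substitution
        int b = (int)(unif_rand() * 3);
        char cur = p[i];
        int curbits = (cur == 'A') ? 0 : (cur == 'C') ? 1 : (cur == 'G') ? 2 : 3;
        int nb = (curbits + 1 + b) & 3;
        o.push_back(BASES[nb]);
        ++i;
      } else if (t < sub_frac + (1.0 - sub_frac) / 2.0) {  // insertion before i
        o.push_back(BASES[(int)(unif_rand() * 4) & 3]);
        // current base emitted on next append
      } else {                                 // deletion of base i
        ++i;
      }
      if (i >= n) break;
    }
    out[s] = o;
  }
  return out;
}
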