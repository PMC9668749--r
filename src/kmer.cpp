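// Canonical k-mer kernels. Keys are 2-bit packed canonical k-mers held in
// uint64 and bit-cast into R doubles (opaque payloads: R never interprets
// them numerically). All key vectors are kept sorted in uint64 order so set
// algebra and membership are binary searches.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline double u2d(uint64_t x) { double d; std::memcpy(&d, &x, 8); return d; }
static inline uint64_t d2u(double d) { uint64_t x; std::memcpy(&x, &d, 8); return x; }

// Scan one sequence, calling f(canonical_code, position) for each valid k-mer.
template <typename F>
static void scan_kmers(const char* s, R_xlen_t n, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run >= k) f(fwd < rev ? fwd : rev, i - k + 1);
  }
}

static std::vector<uint64_t> keys_from_R(const NumericVector& v) {
  std::vector<uint64_t> out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = d2u(v[i]);
  return out;
}

static inline bool key_present(const std::vector<uint64_t>& keys, uint64_t x) {
  return std::binary_search(keys.begin(), keys.end(), x);
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  std::unordered_map<uint64_t, uint32_t> tab;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, s));
    scan_kmers(p, n, k, [&](uint64_t key, R_xlen_t) { ++tab[key]; });
  }
  std::vector<uint64_t> keys;
  keys.reserve(tab.size());
  for (auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  NumericVector key_out(keys.size());
  IntegerVector cnt_out(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    key_out[i] = u2d(keys[i]);
    cnt_out[i] = (int)tab[keys[i]];
  }
  return List::create(_["key"] = key_out, _["count"] = cnt_out);
}

// Instance-level support check: total valid k-mer instances in seqs and how
// many of them are absent from `keys` (sorted). Backbone of the QV estimate.
// [[Rcpp::export]]
NumericVector cpp_kmer_instances(CharacterVector seqs, int k, NumericVector keys) {
  std::vector<uint64_t> ks = keys_from_R(keys);
  double total = 0, missing = 0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, s));
    scan_kmers(p, n, k, [&](uint64_t key, R_xlen_t) {
      total += 1;
      if (!key_present(ks, key)) missing += 1;
    });
  }
  return NumericVector::create(total, missing);
}

// Per-sequence instance hit counts against two sorted key sets (hapmers).
// [[Rcpp::export]]
IntegerMatrix cpp_seq_hits(CharacterVector seqs, int k,
                           NumericVector keys_a, NumericVector keys_b) {
  std::vector<uint64_t> ka = keys_from_R(keys_a), kb = keys_from_R(keys_b);
  IntegerMatrix out(seqs.size(), 2);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, s));
    int na = 0, nb = 0;
    scan_kmers(p, n, k, [&](uint64_t key, R_xlen_t) {
      if (key_present(ka, key)) ++na;
      else if (key_present(kb, key)) ++nb;
    });
    out(s, 0) = na;
    out(s, 1) = nb;
  }
  return out;
}

// Marker positions (0-based k-mer starts) of hapmer occurrences on a contig.
// label: 1 = first set, 2 = second set.
// [[Rcpp::export]]
List cpp_marker_positions(CharacterVector seq, int k,
                          NumericVector keys_a, NumericVector keys_b) {
  std::vector<uint64_t> ka = keys_from_R(keys_a), kb = keys_from_R(keys_b);
  std::vector<double> pos;
  std::vector<int> lab;
  const char* p = CHAR(STRING_ELT(seq, 0));
  R_xlen_t n = LENGTH(STRING_ELT(seq, 0));
  scan_kmers(p, n, k, [&](uint64_t key, R_xlen_t at) {
    if (key_present(ka, key)) { pos.push_back((double)at); lab.push_back(1); }
    else if (key_present(kb, key)) { pos.push_back((double)at); lab.push_back(2); }
  });
  return List::create(_["pos"] = wrap(pos), _["label"] = wrap(lab));
}

// Positions (0-based) in seq of k-mers that are unique within `keys`'s source
// (caller passes the subset of keys with count == 1 in both sequences).
// Returns position and the key itself, for anchor chaining.
// [[Rcpp::export]]
List cpp_anchor_positions(CharacterVector seq, int k, NumericVector keys) {
  std::vector<uint64_t> ks = keys_from_R(keys);
  std::vector<double> pos, key_out;
  const char* p = CHAR(STRING_ELT(seq, 0));
  R_xlen_t n = LENGTH(STRING_ELT(seq, 0));
  scan_kmers(p, n, k, [&](uint64_t key, R_xlen_t at) {
    if (key_present(ks, key)) { pos.push_back((double)at); key_out.push_back(u2d(key)); }
  });
  return List::create(_["pos"] = wrap(pos), _["key"] = wrap(key_out));
}

// match positions of each element of a in b (sorted uint64); 0 if absent, 1-based.
// [[Rcpp::export]]
IntegerVector cpp_key_match(NumericVector a, NumericVector b) {
  std::vector<uint64_t> kb = keys_from_R(b);
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    uint64_t x = d2u(a[i]);
    auto it = std::lower_bound(kb.begin(), kb.end(), x);
    out[i] = (it != kb.end() && *it == x) ? (int)(it - kb.begin()) + 1 : 0;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(NumericVector keys, int k) {
  CharacterVector out(keys.size());
  const char* bases = "ACGT";
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    uint64_t x = d2u(keys[i]);
    for (int j = k - 1; j >= 0; --j) { buf[j] = bases[x & 3]; x >>= 2; }
    out[i] = buf;
  }
  return out;
}

// Canonical keys of given k-mer strings (NA for invalid); unsorted.
// [[Rcpp::export]]
NumericVector cpp_encode_kmers(CharacterVector kmers, int k) {
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* p = CHAR(STRING_ELT(kmers, i));
    R_xlen_t n = LENGTH(STRING_ELT(kmers, i));
    bool done = false;
    if (n == k) {
      scan_kmers(p, n, k, [&](uint64_t key, R_xlen_t) { out[i] = u2d(key); done = true; });
    }
    if (!done) out[i] = NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_key_sort(NumericVector a) {
  std::vector<uint64_t> ks = keys_from_R(a);
  std::sort(ks.begin(), ks.end());
  ks.erase(std::unique(ks.begin(), ks.end()), ks.end());
  NumericVector out(ks.size());
  for (size_t i = 0; i < ks.size(); ++i) out[i] = u2d(ks[i]);
  return out;
}
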