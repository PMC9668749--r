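// Global affine-gap alignment (Gotoh) between two inter-anchor segments,
// returning run-length op lists (=, X, I, D). I = base present in query but
// not reference; D = base present in reference only. Segments larger than
// the cell guard are reported as a block replacement (D then I) — callers
// decide whether such blocks are structural (e.g. inversions).
#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

static List run_list(const std::vector<char>& ops) {
  std::vector<std::string> op;
  std::vector<int> len;
  for (size_t i = 0; i < ops.size();) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    op.push_back(std::string(1, ops[i]));
    len.push_back((int)(j - i));
    i = j;
  }
  return List::create(_["op"] = wrap(op), _["len"] = wrap(len));
}

// [[Rcpp::export]]
List cpp_nw_ops(std::string ref, std::string qry,
                int match, int mismatch, int gap_open, int gap_ext,
                double max_cells) {
  R_xlen_t n = ref.size(), m = qry.size();
  std::vector<char> ops;
  if (n == 0 && m == 0) return run_list(ops);
  if (n == 0) { ops.assign(m, 'I'); return run_list(ops); }
  if (m == 0) { ops.assign(n, 'D'); return run_list(ops); }
  if ((double)(n + 1) * (double)(m + 1) > max_cells) {
    ops.assign(n, 'D');
    ops.insert(ops.end(), m, 'I');
    List out = run_list(ops);
    out["fallback"] = true;
    return out;
  }
  const int NEG = std::numeric_limits<int>::min() / 4;
  size_t W = m + 1;
  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // X: gap in query (D run); Y: gap in ref (I run)
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W), tbY((n + 1) * W);
  M[0] = 0;
  for (R_xlen_t j = 1; j <= m; ++j) {
    Y[j] = gap_open + gap_ext * (int)j;
    tbY[j] = (j == 1) ? 0 : 2;  // 0: came from M, 2: extend Y
  }
  for (R_xlen_t i = 1; i <= n; ++i) {
    X[i * W] = gap_open + gap_ext * (int)i;
    tbX[i * W] = (i == 1) ? 0 : 1;
    for (R_xlen_t j = 1; j <= m; ++j) {
      size_t c = i * W + j, up = (i - 1) * W + j, lf = i * W + j - 1, dg = (i - 1) * W + j - 1;
      int s = (ref[i - 1] == qry[j - 1]) ? match : mismatch;
      int bm = M[dg], which = 0;
      if (X[dg] > bm) { bm = X[dg]; which = 1; }
      if (Y[dg] > bm) { bm = Y[dg]; which = 2; }
      M[c] = bm + s; tbM[c] = (unsigned char)which;
      int xo = M[up] + gap_open + gap_ext, xe = X[up] + gap_ext;
      if (xo >= xe) { X[c] = xo; tbX[c] = 0; } else { X[c] = xe; tbX[c] = 1; }
      int yo = M[lf] + gap_open + gap_ext, ye = Y[lf] + gap_ext;
      if (yo >= ye) { Y[c] = yo; tbY[c] = 0; } else { Y[c] = ye; tbY[c] = 2; }
    }
  }
  // traceback from best of three at (n, m)
  size_t end = n * W + m;
  int state = 0, best = M[end];
  if (X[end] > best) { best = X[end]; state = 1; }
  if (Y[end] > best) { best = Y[end]; state = 2; }
  R_xlen_t i = n, j = m;
  std::vector<char> rev;
  while (i > 0 || j > 0) {
    size_t c = i * W + j;
    if (state == 0) {
      rev.push_back(ref[i - 1] == qry[j - 1] ? '=' : 'X');
      state = tbM[c]; --i; --j;
    } else if (state == 1) {
      rev.push_back('D');
      state = tbX[c]; --i;
    } else {
      rev.push_back('I');
      state = tbY[c]; --j;
    }
  }
  ops.assign(rev.rbegin(), rev.rend());
  return run_list(ops);
}
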