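#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh). A gap run of length g
// scores gap_open + g * gap_extend. Trace-back is deterministic: prefer the
// diagonal (match/mismatch) state, then "up" (gap in b, consuming a), then
// "left" (gap in a). Scores are multiples of 0.5 within float's exact range
// for any realistic sequence length.
//
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, double match_score,
                  double mismatch_score, double gap_open, double gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  const float NEG = -std::numeric_limits<float>::infinity();
  const float go = (float) gap_open, ge = (float) gap_extend;
  const size_t W = (size_t) m + 1;
  // state 0 = M (diagonal), 1 = X (gap in b / up), 2 = Y (gap in a / left)
  std::vector<float> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // predecessor state for each cell of each state matrix
  std::vector<unsigned char> pM((n + 1) * W), pX((n + 1) * W),
      pY((n + 1) * W);
  M[0] = 0.0f;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = go + ge * i;
    pX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = go + ge * j;
    pY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
             l = i * W + (j - 1);
      float s = (a[i - 1] == b[j - 1]) ? (float) match_score
                                       : (float) mismatch_score;
      // M: best predecessor state at (i-1, j-1); prefer M, X, Y on ties
      float bv = M[d]; unsigned char bp = 0;
      if (X[d] > bv) { bv = X[d]; bp = 1; }
      if (Y[d] > bv) { bv = Y[d]; bp = 2; }
      M[c] = bv + s; pM[c] = bp;
      // X: consume a[i-1], gap in b
      bv = M[u] + go + ge; bp = 0;
      if (X[u] + ge > bv) { bv = X[u] + ge; bp = 1; }
      if (Y[u] + go + ge > bv) { bv = Y[u] + go + ge; bp = 2; }
      X[c] = bv; pX[c] = bp;
      // Y: consume b[j-1], gap in a
      bv = M[l] + go + ge; bp = 0;
      if (X[l] + go + ge > bv) { bv = X[l] + go + ge; bp = 1; }
      if (Y[l] + ge > bv) { bv = Y[l] + ge; bp = 2; }
      Y[c] = bv; pY[c] = bp;
    }
  }
  size_t endc = (size_t) n * W + m;
  float best = M[endc]; unsigned char state = 0;
  if (X[endc] > best) { best = X[endc]; state = 1; }
  if (Y[endc] > best) { best = Y[endc]; state = 2; }
  std::string oa, ob;
  oa.reserve(n + m); ob.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t c = (size_t) i * W + j;
    if (state == 0 && i > 0 && j > 0) {
      oa.push_back(a[i - 1]); ob.push_back(b[j - 1]);
      state = pM[c]; --i; --j;
    } else if (state == 1 && i > 0) {
      oa.push_back(a[i - 1]); ob.push_back('-');
      state = pX[c]; --i;
    } else if (state == 2 && j > 0) {
      oa.push_back('-'); ob.push_back(b[j - 1]);
      state = pY[c]; --j;
    } else {
      // boundary rows/columns: forced gap
      if (i > 0) { oa.push_back(a[i - 1]); ob.push_back('-'); state = pX[c]; --i; }
      else       { oa.push_back('-'); ob.push_back(b[j - 1]); state = pY[c]; --j; }
    }
  }
  std::reverse(oa.begin(), oa.end());
  std::reverse(ob.begin(), ob.end());
  return List::create(_["a"] = oa, _["b"] = ob, _["score"] = (double) best);
}
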