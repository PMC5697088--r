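// Pairwise alignment kernels: global (linear gap), local (affine gap),
// ungapped x-drop extension, and a Hamming-distance prefilter.
// Tracebacks break ties deterministically (diagonal > up > left; match
// state preferred over gap states) so outputs are bit-reproducible.
#include <Rcpp.h>
#include <array>
#include <string>
#include <vector>
using namespace Rcpp;

static std::array<int, 256> residue_lookup(const IntegerMatrix& S) {
  std::array<int, 256> idx;
  idx.fill(-1);
  CharacterVector rn = rownames(S);
  for (int i = 0; i < rn.size(); ++i) {
    std::string r = as<std::string>(rn[i]);
    if (r.size() != 1) stop("scoring matrix row names must be single characters");
    idx[(unsigned char)r[0]] = i;
  }
  return idx;
}

static inline int subst(const IntegerMatrix& S, const std::array<int, 256>& idx,
                        char a, char b) {
  int ia = idx[(unsigned char)a], ib = idx[(unsigned char)b];
  if (ia < 0 || ib < 0)
    stop("residue not covered by the scoring matrix: '%s'/'%s'",
         std::string(1, a), std::string(1, b));
  return S(ia, ib);
}

// prefer_up = false: traceback ties resolved diagonal > up > left (the
// documented default). prefer_up = true: up > diagonal > left, which among
// equal-score alignments places gap-in-b columns as late as possible --
// used by the compression stage so that a short redundant sequence aligned
// against a longer representative suffix keeps its matched region as a
// clean alignment prefix with the unmatched representative tail as
// trailing deletions.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, IntegerMatrix S, int gap,
                  bool prefer_up = false) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence in global alignment");
  std::array<int, 256> idx = residue_lookup(S);
  std::vector<int> H((size_t)(n + 1) * (m + 1));
  const int W = m + 1;
  for (int i = 0; i <= n; ++i) H[(size_t)i * W] = -gap * i;
  for (int j = 0; j <= m; ++j) H[j] = -gap * j;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = H[(size_t)(i - 1) * W + (j - 1)] + subst(S, idx, ai, b[j - 1]);
      int u = H[(size_t)(i - 1) * W + j] - gap;
      int l = H[(size_t)i * W + (j - 1)] - gap;
      int best = d >= u ? d : u;
      if (l > best) best = l;
      H[(size_t)i * W + j] = best;
    }
  }
  // traceback, preferring diagonal, then up (consume a), then left
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int h = H[(size_t)i * W + j];
    bool can_diag = i > 0 && j > 0 &&
        h == H[(size_t)(i - 1) * W + (j - 1)] + subst(S, idx, a[i - 1], b[j - 1]);
    bool can_up = i > 0 && h == H[(size_t)(i - 1) * W + j] - gap;
    if (prefer_up && can_up) can_diag = false;
    if (can_diag) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
    } else if (can_up) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = H[(size_t)n * W + m],
                      _["aligned_a"] = ra, _["aligned_b"] = rb);
}

// Gotoh affine-gap local alignment. A gap of length k costs open + k * extend.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix S,
                  int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence in local alignment");
  std::array<int, 256> idx = residue_lookup(S);
  const int NEG = INT_MIN / 4;
  const int W = m + 1;
  std::vector<int> M((size_t)(n + 1) * W, 0), X((size_t)(n + 1) * W, NEG),
      Y((size_t)(n + 1) * W, NEG);
  // traceback codes: for M, 0 = start, 1 = from M, 2 = from X, 3 = from Y;
  // for X/Y, 1 = opened from M, 2 = extended
  std::vector<unsigned char> tM((size_t)(n + 1) * W, 0), tX((size_t)(n + 1) * W, 0),
      tY((size_t)(n + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t c = (size_t)i * W + j, du = c - W, dl = c - 1, dd = du - 1;
      // X: gap in b (consume a)
      int xo = M[du] - gap_open - gap_extend;
      int xe = X[du] == NEG ? NEG : X[du] - gap_extend;
      if (xo >= xe) { X[c] = xo; tX[c] = 1; } else { X[c] = xe; tX[c] = 2; }
      // Y: gap in a (consume b)
      int yo = M[dl] - gap_open - gap_extend;
      int ye = Y[dl] == NEG ? NEG : Y[dl] - gap_extend;
      if (yo >= ye) { Y[c] = yo; tY[c] = 1; } else { Y[c] = ye; tY[c] = 2; }
      // M: diagonal from the best previous state, floored at zero
      int s = subst(S, idx, ai, b[j - 1]);
      int vm = M[dd], vx = X[dd], vy = Y[dd];
      int v = vm; unsigned char t = 1;
      if (vx > v) { v = vx; t = 2; }
      if (vy > v) { v = vy; t = 3; }
      v += s;
      if (v <= 0) { M[c] = 0; tM[c] = 0; } else { M[c] = v; tM[c] = t; }
      if (M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["aligned_a"] = "", _["aligned_b"] = "",
                        _["a_start"] = 0, _["a_end"] = 0, _["b_start"] = 0,
                        _["b_end"] = 0);
  std::string ra, rb;
  int i = bi, j = bj;
  int state = 1;  // local alignments start and end in the match state
  while (!(state == 1 && tM[(size_t)i * W + j] == 0)) {
    const size_t c = (size_t)i * W + j;
    if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      state = tM[c];
      --i; --j;
      if (state == 0) break;  // alignment started at this cell
    } else if (state == 2) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      state = tX[c] == 1 ? 1 : 2;
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      state = tY[c] == 1 ? 1 : 3;
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = best, _["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj);
}

// Ungapped extension left and right of an anchored exact/approximate match.
// A direction stops once the running score drops more than xdrop below its
// running maximum; the best-scoring prefix of each direction is kept.
// [[Rcpp::export(name = ".xdrop_extend_cpp")]]
List xdrop_extend_cpp(std::string a, std::string b, int a_anchor, int b_anchor,
                      int anchor_len, IntegerMatrix S, int xdrop) {
  const int n = (int)a.size(), m = (int)b.size();
  if (a_anchor < 1 || b_anchor < 1 || anchor_len < 1 ||
      a_anchor + anchor_len - 1 > n || b_anchor + anchor_len - 1 > m)
    stop("anchor out of bounds");
  std::array<int, 256> idx = residue_lookup(S);
  int anchor_score = 0;
  for (int k = 0; k < anchor_len; ++k)
    anchor_score += subst(S, idx, a[a_anchor - 1 + k], b[b_anchor - 1 + k]);
  // rightward
  int run = 0, bestR = 0, extR = 0;
  for (int i = a_anchor + anchor_len, j = b_anchor + anchor_len;
       i <= n && j <= m; ++i, ++j) {
    run += subst(S, idx, a[i - 1], b[j - 1]);
    if (run > bestR) { bestR = run; extR = i - (a_anchor + anchor_len) + 1; }
    if (run < bestR - xdrop) break;
  }
  // leftward
  run = 0;
  int bestL = 0, extL = 0;
  for (int i = a_anchor - 1, j = b_anchor - 1; i >= 1 && j >= 1; --i, --j) {
    run += subst(S, idx, a[i - 1], b[j - 1]);
    if (run > bestL) { bestL = run; extL = a_anchor - i; }
    if (run < bestL - xdrop) break;
  }
  return List::create(
      _["score"] = anchor_score + bestR + bestL,
      _["a_start"] = a_anchor - extL, _["a_end"] = a_anchor + anchor_len - 1 + extR,
      _["b_start"] = b_anchor - extL, _["b_end"] = b_anchor + anchor_len - 1 + extR);
}

// All (query, reference) string pairs with Hamming distance <= maxd.
// Strings must share one common length; indices returned are 1-based.
// [[Rcpp::export(name = ".hamming_pairs_cpp")]]
DataFrame hamming_pairs_cpp(CharacterVector q, CharacterVector r, int maxd) {
  std::vector<std::string> qs(q.size()), rs(r.size());
  for (int i = 0; i < q.size(); ++i) qs[i] = as<std::string>(q[i]);
  for (int j = 0; j < r.size(); ++j) rs[j] = as<std::string>(r[j]);
  size_t len = qs.empty() ? (rs.empty() ? 0 : rs[0].size()) : qs[0].size();
  for (const auto& s : qs) if (s.size() != len) stop("seed length mismatch");
  for (const auto& s : rs) if (s.size() != len) stop("seed length mismatch");
  std::vector<int> qi, ri, dd;
  for (size_t i = 0; i < qs.size(); ++i) {
    const std::string& x = qs[i];
    for (size_t j = 0; j < rs.size(); ++j) {
      const std::string& y = rs[j];
      int d = 0;
      for (size_t k = 0; k < len; ++k) {
        if (x[k] != y[k] && ++d > maxd) break;
      }
      if (d <= maxd) {
        qi.push_back((int)i + 1);
        ri.push_back((int)j + 1);
        dd.push_back(d);
      }
    }
  }
  return DataFrame::create(_["qi"] = qi, _["ri"] = ri, _["d"] = dd);
}
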