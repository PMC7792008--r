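#include "graph.h"
#include <cstdint>
#include <climits>

using namespace Rcpp;

// ---- blocked bit-parallel edit distance (Myers/Hyyro), distance only ----
//
// Computes unit-cost edit distance between pattern a (rows) and text b
// (columns). mode_global = true: Needleman-Wunsch distance D[m][n].
// mode_global = false: infix / semi-global distance min_j D[m][j] with
// D[0][j] = 0, i.e. gaps at both text ends are unpenalized.

static inline int char_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return 4;  // N or other: matches nothing
}

int edit_dist_bits(const std::string& a, const std::string& b, bool mode_global) {
  int m = (int)a.size(), n = (int)b.size();
  if (m == 0) return mode_global ? n : 0;
  if (n == 0) return m;
  int W = (m + 63) / 64;
  std::vector<uint64_t> Peq(5 * W, 0);
  for (int i = 0; i < m; ++i)
    Peq[char_code(a[i]) * W + i / 64] |= (uint64_t)1 << (i % 64);
  std::vector<uint64_t> Pv(W, ~(uint64_t)0), Mv(W, 0);
  int score = m;
  uint64_t high = (uint64_t)1 << ((m - 1) % 64);
  int best = INT_MAX;
  for (int j = 0; j < n; ++j) {
    int cc = char_code(b[j]);
    int hin = mode_global ? 1 : 0;
    for (int w = 0; w < W; ++w) {
      uint64_t Eq = (cc < 4) ? Peq[cc * W + w] : 0;
      uint64_t Pv0 = Pv[w], Mv0 = Mv[w];
      uint64_t Xv = Eq | Mv0;
      if (hin < 0) Eq |= 1;
      uint64_t Xh = (((Eq & Pv0) + Pv0) ^ Pv0) | Eq;
      uint64_t Ph = Mv0 | ~(Xh | Pv0);
      uint64_t Mh = Pv0 & Xh;
      uint64_t hb = (w == W - 1) ? high : ((uint64_t)1 << 63);
      int hout = 0;
      if (Ph & hb) hout = 1;
      else if (Mh & hb) hout = -1;
      Ph <<= 1; Mh <<= 1;
      if (hin < 0) Mh |= 1;
      else if (hin > 0) Ph |= 1;
      Pv[w] = Mh | ~(Xv | Ph);
      Mv[w] = Ph & Xv;
      hin = hout;
    }
    score += hin;  // hout of the last block
    if (!mode_global && score < best) best = score;
  }
  return mode_global ? score : std::min(best, score);
}

// [[Rcpp::export]]
int cpp_edit_dist(std::string a, std::string b, bool global_mode) {
  return edit_dist_bits(a, b, global_mode);
}

// ---- banded global alignment with deterministic traceback ----
//
// Unit match/mismatch/gap costs (0/1/1). Traceback preference: diagonal,
// then up (consume a, op 'I'), then left (consume b, op 'D'). Returns the
// distance and the expanded operation string over columns of the alignment.

struct AlignResult {
  int dist;
  std::string ops;  // one of M/I/D per alignment column
};

static bool nw_banded(const std::string& a, const std::string& b, int W, AlignResult& res) {
  int m = (int)a.size(), n = (int)b.size();
  int shift_lo = std::min(0, n - m), shift_hi = std::max(0, n - m);
  auto lo = [&](int i) { return std::max(0, i - W + shift_lo); };
  auto hi = [&](int i) { return std::min(n, i + W + shift_hi); };
  int width = (hi(0) - lo(0)) + 2 * W + shift_hi - shift_lo + 2;
  width = 2 * W + (shift_hi - shift_lo) + 2;
  const int INF = INT_MAX / 4;
  std::vector<int> prev(width, INF), cur(width, INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * width, 0);
  // row 0
  for (int j = lo(0); j <= hi(0); ++j) {
    prev[j - lo(0)] = j;
    tb[j - lo(0)] = 3;  // left
  }
  for (int i = 1; i <= m; ++i) {
    int l = lo(i), h = hi(i), pl = lo(i - 1), ph = hi(i - 1);
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = l; j <= h; ++j) {
      int best = INF; uint8_t op = 0;
      if (j >= 1 && j - 1 >= pl && j - 1 <= ph) {  // diagonal
        int v = prev[j - 1 - pl] + (a[i - 1] == b[j - 1] ? 0 : 1);
        if (v < best) { best = v; op = 1; }
      }
      if (j >= pl && j <= ph) {  // up: consume a
        int v = prev[j - pl] + 1;
        if (v < best) { best = v; op = 2; }
      }
      if (j - 1 >= l) {  // left: consume b
        int v = cur[j - 1 - l] + 1;
        if (v < best) { best = v; op = 3; }
      }
      if (i >= 1 && j == 0) {  // first column
        int v = i;
        if (v < best) { best = v; op = 2; }
      }
      cur[j - l] = best;
      tb[(size_t)i * width + (j - l)] = op;
    }
    std::swap(prev, cur);
  }
  int dist = (hi(m) >= n && lo(m) <= n) ? prev[n - lo(m)] : INF;
  if (dist > W && dist != 0) return false;  // band may have clipped the optimum
  if (dist >= INF) return false;
  // traceback
  std::string ops;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    uint8_t op = tb[(size_t)i * width + (j - lo(i))];
    if (op == 1) { ops.push_back('M'); --i; --j; }
    else if (op == 2) { ops.push_back('I'); --i; }
    else if (op == 3) { ops.push_back('D'); --j; }
    else return false;
  }
  std::reverse(ops.begin(), ops.end());
  res.dist = dist;
  res.ops = ops;
  return true;
}

AlignResult nw_align(const std::string& a, const std::string& b) {
  int m = (int)a.size(), n = (int)b.size();
  AlignResult res;
  if (m == 0) { res.dist = n; res.ops = std::string(n, 'D'); return res; }
  if (n == 0) { res.dist = m; res.ops = std::string(m, 'I'); return res; }
  int W = std::max(16, std::abs(n - m) + 8);
  int maxW = std::max(m, n);
  while (true) {
    if (nw_banded(a, b, W, res)) return res;
    if (W >= maxW) {
      // full band guaranteed to succeed
      nw_banded(a, b, maxW + 1, res);
      return res;
    }
    W = std::min(maxW, W * 2);
  }
}

// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b) {
  AlignResult res = nw_align(a, b);
  return List::create(_["dist"] = res.dist, _["ops"] = res.ops);
}
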