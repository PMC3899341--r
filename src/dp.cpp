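// Affine-gap dynamic programming kernels with full traceback.
//
// Conventions: the read indexes rows (i = 1..m), the genome region indexes
// columns (j = 1..w). E holds alignments ending in a deletion (ref consumed,
// CIGAR D), F alignments ending in an insertion (read consumed, CIGAR I).
// A gap of length g costs gap_open + g*gap_extend. Ties prefer the diagonal
// over deletion over insertion, and gap openings over extensions; among
// equal-scoring end cells the smallest reference coordinate wins.
#include "core.h"
#include <algorithm>

static const int NEG = INT_MIN / 4;

namespace {
struct Mats {
  std::vector<int> H, E, F;
  std::vector<uint8_t> tbH, tbE, tbF;  // tbH: 0 stop, 1 diag, 2 from E, 3 from F
  void resize(size_t sz) {
    H.assign(sz, 0); E.assign(sz, NEG); F.assign(sz, NEG);
    tbH.assign(sz, 0); tbE.assign(sz, 0); tbF.assign(sz, 0);
  }
};

void traceback(const Mats& M, const uint8_t* q, const uint8_t* r,
               int w, int bi, int bj, bool local, int m, AlnOut& out) {
  const size_t W = (size_t)w + 1;
  std::vector<std::pair<char,int>> rev;
  auto push = [&](char op) {
    if (!rev.empty() && rev.back().first == op) rev.back().second++;
    else rev.emplace_back(op, 1);
  };
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || (state != 0)) {
    size_t at = (size_t)i * W + j;
    if (state == 0) {
      uint8_t t = M.tbH[at];
      if (t == 0) break;  // local start
      if (t == 1) {
        bool mt = q[i - 1] < 4 && r[j - 1] < 4 && q[i - 1] == r[j - 1];
        if (mt) out.matches++; else out.mismatches++;
        push('M'); i--; j--;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {   // deletion run
      push('D'); out.del++;
      uint8_t t = M.tbE[at];
      j--;
      if (!t) state = 0;
    } else {                   // insertion run
      push('I'); out.ins++;
      uint8_t t = M.tbF[at];
      i--;
      if (!t) state = 0;
    }
    if (!local && i == 0 && state == 0) break;
  }
  out.ref_start = j;
  out.sclip_l = i;
  out.sclip_r = m - bi;
  out.cig.clear();
  if (out.sclip_l > 0) out.cig.emplace_back('S', out.sclip_l);
  for (auto it = rev.rbegin(); it != rev.rend(); ++it) out.cig.push_back(*it);
  if (out.sclip_r > 0) out.cig.emplace_back('S', out.sclip_r);
  out.empty = rev.empty();
}
}  // namespace

void local_align(const uint8_t* q, int m, const uint8_t* r, int w,
                 const Scoring& sc, AlnOut& out) {
  out = AlnOut();
  static thread_local Mats M;
  const size_t W = (size_t)w + 1;
  M.resize((size_t)(m + 1) * W);
  const int go = sc.gap_open + sc.gap_extend, ge = sc.gap_extend;

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; i++) {
    size_t row = (size_t)i * W, prow = row - W;
    for (int j = 1; j <= w; j++) {
      int eo = M.H[row + j - 1] + go, ee = M.E[row + j - 1] + ge;
      int e = eo >= ee ? (M.tbE[row + j] = 0, eo) : (M.tbE[row + j] = 1, ee);
      int fo = M.H[prow + j] + go, fe = M.F[prow + j] + ge;
      int f = fo >= fe ? (M.tbF[row + j] = 0, fo) : (M.tbF[row + j] = 1, fe);
      bool mt = q[i - 1] < 4 && r[j - 1] < 4 && q[i - 1] == r[j - 1];
      int diag = M.H[prow + j - 1] + (mt ? sc.match : sc.mismatch);
      int h = 0; uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      M.H[row + j] = h; M.E[row + j] = e; M.F[row + j] = f;
      M.tbH[row + j] = src;
      if (h > best || (h == best && h > 0 && (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }
  out.score = best;
  if (best <= 0) { out.score = 0; out.empty = true; return; }
  traceback(M, q, r, w, bi, bj, true, m, out);
}

void semiglobal_align(const uint8_t* q, int m, const uint8_t* r, int w,
                      const Scoring& sc, AlnOut& out) {
  out = AlnOut();
  static thread_local Mats M;
  const size_t W = (size_t)w + 1;
  M.resize((size_t)(m + 1) * W);
  const int go = sc.gap_open + sc.gap_extend, ge = sc.gap_extend;

  // row 0: free reference prefix; column 0: read aligned against nothing
  for (int i = 1; i <= m; i++) {
    size_t at = (size_t)i * W;
    M.F[at] = sc.gap_open + i * ge;
    M.H[at] = M.F[at];
    M.tbH[at] = 3; M.tbF[at] = i > 1;
  }
  for (int i = 1; i <= m; i++) {
    size_t row = (size_t)i * W, prow = row - W;
    for (int j = 1; j <= w; j++) {
      int eo = M.H[row + j - 1] + go, ee = M.E[row + j - 1] + ge;
      int e = eo >= ee ? (M.tbE[row + j] = 0, eo) : (M.tbE[row + j] = 1, ee);
      int fo = M.H[prow + j] + go, fe = M.F[prow + j] + ge;
      int f = fo >= fe ? (M.tbF[row + j] = 0, fo) : (M.tbF[row + j] = 1, fe);
      bool mt = q[i - 1] < 4 && r[j - 1] < 4 && q[i - 1] == r[j - 1];
      int diag = M.H[prow + j - 1] + (mt ? sc.match : sc.mismatch);
      int h = diag; uint8_t src = 1;
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      M.H[row + j] = h; M.E[row + j] = e; M.F[row + j] = f;
      M.tbH[row + j] = src;
    }
  }
  int best = NEG, bj = 0;
  size_t lrow = (size_t)m * W;
  for (int j = 0; j <= w; j++)
    if (M.H[lrow + j] > best) { best = M.H[lrow + j]; bj = j; }
  out.score = best;
  traceback(M, q, r, w, m, bj, false, m, out);
  out.sclip_l = out.sclip_r = 0;
  out.empty = false;
}
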