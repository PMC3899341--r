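#include "core.h"
#include <algorithm>
#include <cmath>
#include <stdexcept>

int Cfg::margin(int L) const { return (int)std::ceil(0.1 * L) + 10; }

void FM::build(int sa_sample_rate) {
  sa_rate = sa_sample_rate;
  const int64_t m = (int64_t)n + 1;
  std::vector<int32_t> s(m);
  for (int32_t i = 0; i < n; i++) s[i] = text[i] + 1;
  s[n] = 0;
  std::vector<int32_t> SA(m);
  sais(s.data(), SA.data(), (int32_t)m, 5);

  bwt.assign(m, 0);
  for (int64_t i = 0; i < m; i++)
    bwt[i] = SA[i] == 0 ? 0 : (uint8_t)s[SA[i] - 1];

  int64_t cc[7] = {0};
  for (int64_t i = 0; i < m; i++) cc[bwt[i] + 1]++;
  C[0] = 0;
  for (int c = 1; c <= 6; c++) C[c] = C[c - 1] + cc[c];

  // occ checkpoints every OCC_BLK rows for symbols 1..5
  const int64_t nb = (m + OCC_BLK - 1) / OCC_BLK + 1;
  occ.assign(nb * 5, 0);
  { int64_t run[6] = {0};
    for (int64_t i = 0; i < m; i++) {
      if (i % OCC_BLK == 0) {
        int64_t b = i / OCC_BLK;
        for (int c = 1; c <= 5; c++) occ[b * 5 + c - 1] = (int32_t)run[c];
      }
      run[bwt[i]]++;
    }
    int64_t b = (m + OCC_BLK - 1) / OCC_BLK;
    for (int c = 1; c <= 5; c++) occ[b * 5 + c - 1] = (int32_t)run[c];
  }

  // sample SA values at text positions divisible by sa_rate (plus the ends so
  // every LF-walk terminates); marked rows + rank directory
  const int64_t mb = (m + 63) / 64;
  mark.assign(mb, 0);
  mrank.assign(mb + 1, 0);
  std::vector<int32_t> vals;
  for (int64_t i = 0; i < m; i++) {
    int32_t v = SA[i];
    if (v % sa_rate == 0 || v == n) {
      mark[i >> 6] |= 1ULL << (i & 63);
      vals.push_back(v);
    }
  }
  ssa = std::move(vals);
  int32_t acc = 0;
  for (int64_t b = 0; b < mb; b++) {
    mrank[b] = acc;
    acc += __builtin_popcountll(mark[b]);
  }
  mrank[mb] = acc;
}

int64_t FM::rank(uint8_t sym, int64_t i) const {
  const int64_t b = i / OCC_BLK;
  int64_t r = occ[b * 5 + sym - 1];
  for (int64_t k = b * OCC_BLK; k < i; k++) if (bwt[k] == sym) r++;
  return r;
}

int64_t FM::lf(int64_t row) const {
  uint8_t c = bwt[row];
  if (c == 0) return 0;
  return C[c] + rank(c, row);
}

void FM::search(const uint8_t* pat, int len, int64_t& lo, int64_t& hi) const {
  lo = 0; hi = (int64_t)n + 1;
  for (int i = len - 1; i >= 0; i--) {
    uint8_t sym = pat[i] + 1;
    if (pat[i] >= 4) { hi = lo; return; }  // N and pads never match
    lo = C[sym] + rank(sym, lo);
    hi = C[sym] + rank(sym, hi);
    if (lo >= hi) { hi = lo; return; }
  }
}

int32_t FM::locate(int64_t row) const {
  int32_t steps = 0;
  while (!(mark[row >> 6] & (1ULL << (row & 63)))) {
    row = lf(row);
    steps++;
  }
  int32_t idx = mrank[row >> 6] +
    __builtin_popcountll(mark[row >> 6] & ((1ULL << (row & 63)) - 1));
  return ssa[idx] + steps;
}

int FM::contig_of(int64_t gpos) const {
  int lo = 0, hi = (int)cstart.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if ((int64_t)cstart[mid] <= gpos) lo = mid; else hi = mid - 1;
  }
  return lo;
}

int compute_mapq_core(int best, int second, int n_best, bool has_second) {
  if (n_best >= 2) return 0;
  if (!has_second) return 60;
  if (best <= 0) return 0;
  double q = 60.0 * (double)(best - second) / (double)best;
  int m = (int)std::lround(q);
  if (m < 0) m = 0;
  if (m > 60) m = 60;
  return m;
}
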