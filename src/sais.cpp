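// Linear-time suffix array construction by induced sorting (SA-IS).
#include "core.h"
#include <algorithm>
#include <cstring>

typedef int32_t si;

static void get_counts(const si* s, si* cnt, si n, si K) {
  std::memset(cnt, 0, sizeof(si) * (K + 1));
  for (si i = 0; i < n; i++) cnt[s[i]]++;
}

static void get_buckets(const si* cnt, si* bkt, si K, bool end) {
  si sum = 0;
  for (si i = 0; i <= K; i++) { sum += cnt[i]; bkt[i] = end ? sum : sum - cnt[i]; }
}

static void induce(const si* s, si* SA, si n, si K,
                   const std::vector<bool>& t, const si* cnt, si* bkt) {
  // induce L-type from sorted LMS/S, left to right
  get_buckets(cnt, bkt, K, false);
  for (si i = 0; i < n; i++) {
    si j = SA[i] - 1;
    if (SA[i] > 0 && !t[j]) SA[bkt[s[j]]++] = j;
  }
  // induce S-type, right to left
  get_buckets(cnt, bkt, K, true);
  for (si i = n - 1; i >= 0; i--) {
    si j = SA[i] - 1;
    if (SA[i] > 0 && t[j]) SA[--bkt[s[j]]] = j;
  }
}

void sais(const si* s, si* SA, si n, si K) {
  if (n == 1) { SA[0] = 0; return; }
  std::vector<bool> t(n);
  t[n - 1] = true;
  for (si i = n - 2; i >= 0; i--)
    t[i] = (s[i] < s[i + 1]) || (s[i] == s[i + 1] && t[i + 1]);
  auto isLMS = [&](si i) { return i > 0 && t[i] && !t[i - 1]; };

  std::vector<si> cnt(K + 1), bkt(K + 1);
  get_counts(s, cnt.data(), n, K);

  // stage 1: approximately sort LMS suffixes by induction
  get_buckets(cnt.data(), bkt.data(), K, true);
  std::fill(SA, SA + n, -1);
  for (si i = n - 1; i >= 1; i--) if (isLMS(i)) SA[--bkt[s[i]]] = i;
  induce(s, SA, n, K, t, cnt.data(), bkt.data());

  // compact sorted LMS positions into SA[0..n1)
  si n1 = 0;
  for (si i = 0; i < n; i++) if (SA[i] > 0 && isLMS(SA[i])) SA[n1++] = SA[i];

  // name LMS substrings into SA[n1..n)
  std::fill(SA + n1, SA + n, -1);
  si name = 0, prev = -1;
  for (si i = 0; i < n1; i++) {
    si pos = SA[i];
    bool diff = false;
    if (prev < 0 || s[pos] != s[prev]) diff = true;
    else {
      for (si d = 1;; d++) {
        bool lp = isLMS(pos + d), lq = isLMS(prev + d);
        if (lp && lq) break;
        if (lp != lq || s[pos + d] != s[prev + d]) { diff = true; break; }
      }
    }
    if (diff) { name++; prev = pos; }
    SA[n1 + pos / 2] = name - 1;
  }
  for (si i = n - 1, j = n - 1; i >= n1; i--)
    if (SA[i] >= 0) SA[j--] = SA[i];

  // solve the reduced problem
  si* SA1 = SA;
  si* s1 = SA + n - n1;
  if (name < n1) sais(s1, SA1, n1, name - 1);
  else for (si i = 0; i < n1; i++) SA1[s1[i]] = i;

  // map reduced SA back to LMS positions
  for (si i = 1, j = 0; i < n; i++) if (isLMS(i)) s1[j++] = i;
  for (si i = 0; i < n1; i++) SA1[i] = s1[SA1[i]];

  // stage 2: induce the full SA from exactly sorted LMS
  std::fill(SA + n1, SA + n, -1);
  get_buckets(cnt.data(), bkt.data(), K, true);
  for (si i = n1 - 1; i >= 0; i--) {
    si p = SA[i]; SA[i] = -1;
    SA[--bkt[s[p]]] = p;
  }
  induce(s, SA, n, K, t, cnt.data(), bkt.data());
}
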