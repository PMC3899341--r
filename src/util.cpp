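// Small vectorized helpers: reverse complement, di-base color encoding and
// the substitution error model used by the read simulator.
#include <Rcpp.h>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); i++) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) c = comp(c);
    out[i] = r;
  }
  return out;
}

static inline int bidx(char c) {
  switch (c) {
    case 'A': case 'a': return 0; case 'C': case 'c': return 1;
    case 'G': case 'g': return 2; case 'T': case 't': return 3;
    default: return -1;
  }
}

// di-base code: 0 same base; 1 A<->C, G<->T; 2 A<->G, C<->T; 3 A<->T, C<->G
// (XOR of the 2-bit base codes)
// [[Rcpp::export]]
CharacterVector cpp_encode_colors(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); i++) {
    std::string s = as<std::string>(seqs[i]);
    if (s.size() < 2) stop("sequence of length < 2 cannot be color-encoded");
    std::string c(s.size() - 1, '.');
    for (size_t j = 0; j + 1 < s.size(); j++) {
      int a = bidx(s[j]), b = bidx(s[j + 1]);
      if (a >= 0 && b >= 0) c[j] = (char)('0' + (a ^ b));
    }
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_colors(CharacterVector primers, CharacterVector colors) {
  static const char* bases = "ACGT";
  CharacterVector out(colors.size());
  for (int i = 0; i < colors.size(); i++) {
    std::string p = as<std::string>(primers[i]);
    std::string c = as<std::string>(colors[i]);
    int cur = bidx(p[0]);
    std::string s(c.size(), 'N');
    for (size_t j = 0; j < c.size(); j++) {
      if (cur < 0 || c[j] < '0' || c[j] > '3') { cur = -1; continue; }
      cur = cur ^ (c[j] - '0');
      s[j] = bases[cur];
    }
    out[i] = s;
  }
  return out;
}

// Substitute symbols at the given per-symbol error rate, drawing replacements
// uniformly from the other alphabet letters. Uses R's RNG stream.
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double err, std::string alphabet) {
  CharacterVector out(seqs.size());
  const int A = (int)alphabet.size();
  for (int i = 0; i < seqs.size(); i++) {
    std::string s = as<std::string>(seqs[i]);
    for (auto& ch : s) {
      if (unif_rand() >= err) continue;
      size_t at = alphabet.find(ch);
      if (at == std::string::npos) continue;
      int k = (int)(unif_rand() * (A - 1));
      if (k >= A - 1) k = A - 2;
      ch = alphabet[(at + 1 + k) % A];
    }
    out[i] = s;
  }
  return out;
}
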