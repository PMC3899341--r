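#ifndef HYBRIDALN_CORE_H
#define HYBRIDALN_CORE_H

#include <vector>
#include <string>
#include <cstdint>
#include <climits>

// Suffix array (SA-IS). s has values 0..K with a unique smallest sentinel 0 at
// s[n-1]; SA receives the n suffix start positions in lexicographic order.
void sais(const int32_t* s, int32_t* SA, int32_t n, int32_t K);

// Reference text codes: 0=A 1=C 2=G 3=T 4=N/pad (pad separates contigs; code 4
// never matches anything, so no seed or extension crosses a contig boundary).
// BWT symbols are text codes + 1, with 0 as the sentinel.
struct FM {
  int32_t n = 0;                      // text length (without sentinel)
  std::vector<uint8_t> text;          // concatenated contigs + pads
  std::vector<std::string> names;
  std::vector<int32_t> cstart, clen;  // global start/length per contig
  std::vector<uint8_t> bwt;           // length n+1
  int64_t C[7] = {0};                 // C[c] = #symbols < c in bwt
  std::vector<int32_t> occ;           // checkpoints every OCC_BLK rows, 5 syms
  int sa_rate = 8;
  std::vector<uint64_t> mark;         // rows whose SA value is sampled
  std::vector<int32_t> mrank;         // rank of mark at each 64-row block
  std::vector<int32_t> ssa;           // sampled SA values in row order

  static const int OCC_BLK = 64;

  void build(int sa_sample_rate);
  int64_t rank(uint8_t sym, int64_t i) const;   // #sym in bwt[0..i), sym in 1..5
  int64_t lf(int64_t row) const;
  // backward search; returns [lo, hi) over rows, empty interval when absent
  void search(const uint8_t* pat, int len, int64_t& lo, int64_t& hi) const;
  int32_t locate(int64_t row) const;
  int contig_of(int64_t gpos) const;            // binary search over cstart
};

struct Scoring {
  int match = 1, mismatch = -3, gap_open = -5, gap_extend = -2;
  // gap of length g costs gap_open + g*gap_extend
};

struct AlnOut {
  int score = 0;
  int ref_start = 0;                  // 0-based offset of leftmost aligned ref base in region
  std::vector<std::pair<char,int>> cig;  // ops among M/I/D/S, merged runs
  int matches = 0, mismatches = 0, ins = 0, del = 0;
  int sclip_l = 0, sclip_r = 0;
  bool empty = true;
};

// read = rows (fully indexed by q), region = columns.
void local_align(const uint8_t* q, int m, const uint8_t* r, int w,
                 const Scoring& sc, AlnOut& out);
void semiglobal_align(const uint8_t* q, int m, const uint8_t* r, int w,
                      const Scoring& sc, AlnOut& out);

struct Cfg {
  Scoring sc;
  double min_id_local = 90.0, min_id_global = 65.0, min_afrac = 0.8;
  int min_mem_len = 17, kmer = 13, max_occ = 1000;
  int max_seeds_extend = 20, max_reported = 10;
  double min_seed_score = 30.0;
  int rescue_min_mapq = 20, max_top_seeds = 100;
  double insert_nsd = 4.0;
  int max_pairs_extend = 256;
  bool color = false;        // color space: "reverse complement" = plain reverse
  bool orient_ff = false;    // FF mate-pair layout instead of FR
  bool en_sg_rescue = true, en_mate_rescue = true, en_kmer = true;
  int margin(int L) const;
};

int compute_mapq_core(int best, int second, int n_best, bool has_second);

#endif
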