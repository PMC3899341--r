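// Seed-and-extend alignment engine: hybrid seeding (MEM, k-mer, variable
// length), single-end and paired-end pipelines, mate rescue and MAPQ.
#include <Rcpp.h>
#include "core.h"
#include <unordered_set>
#include <map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------- encoding ----------

static inline uint8_t code_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}
static inline uint8_t code_color(char c) {
  if (c >= '0' && c <= '3') return (uint8_t)(c - '0');
  return 4;
}

static std::vector<uint8_t> encode_seq(const std::string& s, bool color) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); i++)
    v[i] = color ? code_color(s[i]) : code_base(s[i]);
  return v;
}

// reverse complement; in color space complementation is the identity, so the
// reverse strand of a color read is the plain reversal
static std::vector<uint8_t> rc_codes(const std::vector<uint8_t>& v, bool color) {
  std::vector<uint8_t> r(v.rbegin(), v.rend());
  if (!color)
    for (auto& c : r) if (c < 4) c = 3 - c;
  return r;
}

// ---------- config ----------

static Cfg cfg_from_list(List l) {
  Cfg c;
  c.sc.match = as<int>(l["match"]);
  c.sc.mismatch = as<int>(l["mismatch"]);
  c.sc.gap_open = as<int>(l["gap_open"]);
  c.sc.gap_extend = as<int>(l["gap_extend"]);
  c.min_id_local = as<double>(l["min_id_local"]);
  c.min_id_global = as<double>(l["min_id_global"]);
  c.min_afrac = as<double>(l["min_align_frac"]);
  c.min_mem_len = as<int>(l["min_mem_len"]);
  c.kmer = as<int>(l["kmer"]);
  c.max_occ = as<int>(l["max_occ"]);
  c.max_seeds_extend = as<int>(l["max_seeds_extend"]);
  c.max_reported = as<int>(l["max_reported"]);
  c.min_seed_score = as<double>(l["min_seed_score"]);
  c.rescue_min_mapq = as<int>(l["rescue_min_mapq"]);
  c.max_top_seeds = as<int>(l["max_top_seeds"]);
  c.insert_nsd = as<double>(l["insert_nsd"]);
  c.color = as<bool>(l["color"]);
  c.orient_ff = as<bool>(l["orient_ff"]);
  c.en_sg_rescue = as<bool>(l["semiglobal_rescue"]);
  c.en_mate_rescue = as<bool>(l["mate_rescue"]);
  c.en_kmer = as<bool>(l["kmer_reseed"]);
  return c;
}

// ---------- seeds ----------

struct SeedC { int roff; int64_t gpos; int len; int strand; int kind; };

static void find_mems_strand(const FM& fm, const std::vector<uint8_t>& ori,
                             int strand, int minlen, int maxocc,
                             std::vector<SeedC>& out) {
  const int L = (int)ori.size();
  if (L < minlen) return;
  std::unordered_set<int64_t> seen;
  for (int i = 0; i + minlen <= L; i++) {
    bool ok = true;
    for (int t = i; t < i + minlen; t++) if (ori[t] >= 4) { ok = false; break; }
    if (!ok) continue;
    int64_t lo, hi;
    fm.search(ori.data() + i, minlen, lo, hi);
    if (lo >= hi) continue;
    int64_t take = std::min<int64_t>(hi - lo, maxocc);
    for (int64_t r = lo; r < lo + take; r++) {
      int64_t p = fm.locate(r);
      // extend the window to a maximal exact match at this occurrence
      int a = i; int64_t b = p;
      while (a > 0 && b > 0 && fm.text[b - 1] < 4 && ori[a - 1] == fm.text[b - 1]) { a--; b--; }
      int er = i + minlen; int64_t gr = p + minlen;
      while (er < L && gr < fm.n && fm.text[gr] < 4 && ori[er] == fm.text[gr]) { er++; gr++; }
      int64_t key = b * 512 + a;
      if (seen.insert(key).second)
        out.push_back({a, b, er - a, strand, 0});
    }
  }
}

static void find_kmers_strand(const FM& fm, const std::vector<uint8_t>& ori,
                              int strand, int k, int maxocc,
                              std::vector<SeedC>& out) {
  const int L = (int)ori.size();
  for (int i = 0; i + k <= L; i += k) {
    bool ok = true;
    for (int t = i; t < i + k; t++) if (ori[t] >= 4) { ok = false; break; }
    if (!ok) continue;
    int64_t lo, hi;
    fm.search(ori.data() + i, k, lo, hi);
    if (lo >= hi) continue;
    int64_t take = std::min<int64_t>(hi - lo, maxocc);
    for (int64_t r = lo; r < lo + take; r++)
      out.push_back({i, fm.locate(r), k, strand, 1});
  }
}

// ---------- per-read context, regions and extension ----------

struct Reg {
  int strand; int64_t rs, re;   // clamped region [rs, re)
  int64_t ipos;                 // seed-implied leftmost read placement
  double q = -1.0;              // optimal local score of read vs region
  bool scored = false;
  AlnOut loc;
  bool sg_tried = false; AlnOut sg; bool sg_ok = false;
  int64_t sg_rs = 0;            // start of the recomputed semi-global region
  int fin = -1;                 // -1 unknown, 0 local, 1 semiglobal, 2 none
};

struct Cand {
  int strand; int64_t gstart; int score; int mode;  // 0 local, 1 sg, 2 rescued
  AlnOut a;
  int edit() const { return a.mismatches + a.ins + a.del; }
  int refspan() const { return a.matches + a.mismatches + a.del; }
};

struct ReadCtx {
  std::vector<uint8_t> ori[2];
  int L = 0;
  std::vector<Reg> regs;
  std::map<std::pair<int, int64_t>, int> ridx;
  bool mem_done = false, kmer_done = false;
  std::vector<Cand> cands;          // all qualified candidates seen
  bool se_done = false;
  std::vector<int> rep;             // indices into cands, ranked
  int mapq = 0;
};

static void init_ctx(ReadCtx& ctx, const std::string& s, bool color) {
  ctx.ori[0] = encode_seq(s, color);
  ctx.ori[1] = rc_codes(ctx.ori[0], color);
  ctx.L = (int)ctx.ori[0].size();
}

static void add_regions(const FM& fm, ReadCtx& ctx, const std::vector<SeedC>& seeds,
                        const Cfg& cfg) {
  const int L = ctx.L, mg = cfg.margin(L);
  for (const auto& s : seeds) {
    int c = fm.contig_of(s.gpos);
    int64_t cs = fm.cstart[c], ce = cs + fm.clen[c];
    int64_t rs = s.gpos - s.roff - mg;
    int64_t re = s.gpos + (L - s.roff) + mg;
    if (rs < cs) rs = cs;
    if (re > ce) re = ce;
    if (re - rs < 1) continue;
    auto key = std::make_pair(s.strand, rs);
    auto it = ctx.ridx.find(key);
    if (it == ctx.ridx.end()) {
      Reg r; r.strand = s.strand; r.rs = rs; r.re = re;
      r.ipos = s.gpos - s.roff;
      ctx.ridx[key] = (int)ctx.regs.size();
      ctx.regs.push_back(std::move(r));
    }
  }
}

static void score_regions(const FM& fm, ReadCtx& ctx, const Cfg& cfg) {
  for (auto& r : ctx.regs) {
    if (r.scored) continue;
    local_align(ctx.ori[r.strand].data(), ctx.L,
                fm.text.data() + r.rs, (int)(r.re - r.rs), cfg.sc, r.loc);
    r.q = r.loc.score;
    r.scored = true;
  }
}

static std::vector<int> rank_regions(const ReadCtx& ctx) {
  std::vector<int> ord(ctx.regs.size());
  for (size_t i = 0; i < ord.size(); i++) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    const Reg &x = ctx.regs[a], &y = ctx.regs[b];
    if (x.q != y.q) return x.q > y.q;
    if (x.rs != y.rs) return x.rs < y.rs;
    return x.strand < y.strand;
  });
  return ord;
}

static bool qual_aln(const AlnOut& a, int L, bool global, const Cfg& c) {
  int albases = a.matches + a.mismatches + a.ins;
  if (albases <= 0 || a.empty) return false;
  double id = 100.0 * a.matches / albases;
  double af = (double)(L - a.sclip_l - a.sclip_r) / L;
  double thr = global ? c.min_id_global : c.min_id_local;
  return id >= thr - 1e-9 && af >= c.min_afrac - 1e-9;
}

// semi-global rescue from a region's best local alignment (variable-length seed)
static bool try_semiglobal(const FM& fm, ReadCtx& ctx, Reg& r, const Cfg& cfg) {
  if (r.sg_tried) return r.sg_ok;
  r.sg_tried = true;
  r.sg_ok = false;
  if (r.loc.empty || r.loc.score <= 0) return false;
  const int L = ctx.L, mg = cfg.margin(L);
  int64_t anchor = r.rs + r.loc.ref_start;
  int64_t pos0 = anchor - r.loc.sclip_l;     // implied full-read placement
  int c = fm.contig_of(anchor);
  int64_t cs = fm.cstart[c], ce = cs + fm.clen[c];
  int64_t vrs = std::max(pos0 - mg, cs);
  int64_t vre = std::min(pos0 + L + mg, ce);
  if (vre - vrs < 1) return false;
  semiglobal_align(ctx.ori[r.strand].data(), L,
                   fm.text.data() + vrs, (int)(vre - vrs), cfg.sc, r.sg);
  r.sg_rs = vrs;
  r.sg_ok = qual_aln(r.sg, L, true, cfg);
  return r.sg_ok;
}

// finalize one region the SE way: qualified local, else semi-global rescue
static int finalize_region(const FM& fm, ReadCtx& ctx, int ri, const Cfg& cfg,
                           Cand& out) {
  Reg& r = ctx.regs[ri];
  if (r.fin == 2) return 0;
  if (r.fin == 0 || (r.fin == -1 && qual_aln(r.loc, ctx.L, false, cfg))) {
    r.fin = 0;
    out.strand = r.strand; out.mode = 0; out.a = r.loc;
    out.gstart = r.rs + r.loc.ref_start; out.score = r.loc.score;
    return 1;
  }
  if (cfg.en_sg_rescue && try_semiglobal(fm, ctx, r, cfg)) {
    r.fin = 1;
    out.strand = r.strand; out.mode = 1; out.a = r.sg;
    out.gstart = r.sg_rs + r.sg.ref_start; out.score = r.sg.score;
    return 1;
  }
  r.fin = 2;
  return 0;
}

static void push_cand(ReadCtx& ctx, const Cand& c) {
  for (auto& e : ctx.cands)
    if (e.strand == c.strand && e.gstart == c.gstart) {
      if (c.score > e.score) e = c;
      return;
    }
  ctx.cands.push_back(c);
}

static void rank_cands(ReadCtx& ctx, const Cfg& cfg) {
  std::vector<int> ord(ctx.cands.size());
  for (size_t i = 0; i < ord.size(); i++) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    const Cand &x = ctx.cands[a], &y = ctx.cands[b];
    if (x.score != y.score) return x.score > y.score;
    if (x.edit() != y.edit()) return x.edit() < y.edit();
    if (x.gstart != y.gstart) return x.gstart < y.gstart;
    return x.strand < y.strand;
  });
  ctx.rep.assign(ord.begin(),
                 ord.begin() + std::min<size_t>(ord.size(), cfg.max_reported));
  if (ctx.cands.empty()) { ctx.mapq = 0; return; }
  int best = ctx.cands[ord[0]].score;
  int n_best = 0;
  for (auto i : ord) if (ctx.cands[i].score == best) n_best++;
  bool has_second = ord.size() >= 2;
  int second = has_second ? ctx.cands[ord[1]].score : 0;
  ctx.mapq = compute_mapq_core(best, second, n_best, has_second);
}

// full single-end pipeline on a context (reusable from the PE pipeline)
static void se_align(const FM& fm, ReadCtx& ctx, const Cfg& cfg) {
  if (ctx.se_done) return;
  ctx.se_done = true;
  std::vector<SeedC> seeds;
  if (!ctx.mem_done) {
    for (int st = 0; st < 2; st++)
      find_mems_strand(fm, ctx.ori[st], st, cfg.min_mem_len, cfg.max_occ, seeds);
    add_regions(fm, ctx, seeds, cfg);
    ctx.mem_done = true;
  }
  for (int stage = 0; stage < 2; stage++) {
    score_regions(fm, ctx, cfg);
    std::vector<int> ord = rank_regions(ctx);
    int n_new = 0;
    int limit = std::min<int>((int)ord.size(), cfg.max_seeds_extend);
    for (int t = 0; t < limit && n_new < cfg.max_reported; t++) {
      Reg& r = ctx.regs[ord[t]];
      if (qual_aln(r.loc, ctx.L, false, cfg)) {
        r.fin = 0;
        Cand c; c.strand = r.strand; c.mode = 0; c.a = r.loc;
        c.gstart = r.rs + r.loc.ref_start; c.score = r.loc.score;
        push_cand(ctx, c);
        n_new++;
      }
    }
    if (ctx.cands.empty() && cfg.en_sg_rescue && !ord.empty()) {
      Reg& r = ctx.regs[ord[0]];
      if (try_semiglobal(fm, ctx, r, cfg)) {
        r.fin = 1;
        Cand c; c.strand = r.strand; c.mode = 1; c.a = r.sg;
        c.gstart = r.sg_rs + r.sg.ref_start; c.score = r.sg.score;
        push_cand(ctx, c);
      }
    }
    if (!ctx.cands.empty()) break;
    if (stage == 0 && cfg.en_kmer && !ctx.kmer_done && ctx.L >= cfg.kmer) {
      seeds.clear();
      for (int st = 0; st < 2; st++)
        find_kmers_strand(fm, ctx.ori[st], st, cfg.kmer, cfg.max_occ, seeds);
      add_regions(fm, ctx, seeds, cfg);
      ctx.kmer_done = true;
    } else break;
  }
  rank_cands(ctx, cfg);
}

// ---------- result rows ----------

struct Rows {
  std::vector<int> read, end, rank, strand, ctg, mapq, score, mode, nm;
  std::vector<double> pos, identity, afrac;
  std::vector<std::string> cigar;
  std::vector<int> proper, ncand;

  void add(const FM& fm, int rd, int en, int rk, const Cand& c, int mq,
           int L, bool prop, int nc) {
    int cg = fm.contig_of(c.gstart);
    read.push_back(rd); end.push_back(en); rank.push_back(rk);
    strand.push_back(c.strand); ctg.push_back(cg + 1);
    pos.push_back((double)(c.gstart - fm.cstart[cg]));
    score.push_back(c.score); mode.push_back(c.mode);
    std::string cig;
    for (auto& p : c.a.cig) cig += std::to_string(p.second) + p.first;
    cigar.push_back(cig);
    nm.push_back(c.edit());
    int albases = c.a.matches + c.a.mismatches + c.a.ins;
    identity.push_back(albases ? 100.0 * c.a.matches / albases : 0.0);
    afrac.push_back((double)(L - c.a.sclip_l - c.a.sclip_r) / L);
    mapq.push_back(mq);
    proper.push_back(prop ? 1 : 0);
    ncand.push_back(nc);
  }

  List to_list() const {
    return List::create(
      _["read"] = read, _["end"] = end, _["rank"] = rank,
      _["strand"] = strand, _["contig"] = ctg, _["pos"] = pos,
      _["score"] = score, _["mode"] = mode, _["cigar"] = cigar,
      _["nm"] = nm, _["identity"] = identity, _["aligned_frac"] = afrac,
      _["mapq"] = mapq, _["proper"] = proper, _["n_candidates"] = ncand);
  }
};

// ---------- exported: index ----------

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int sa_rate,
                     bool color = false) {
  FM* fm = new FM();
  int64_t total = 0;
  for (int i = 0; i < seqs.size(); i++) total += LENGTH(STRING_ELT(seqs, i)) + 1;
  fm->text.reserve(total);
  for (int i = 0; i < seqs.size(); i++) {
    if (i > 0) fm->text.push_back(4);  // contig separator
    fm->names.push_back(as<std::string>(names[i]));
    fm->cstart.push_back((int32_t)fm->text.size());
    std::string s = as<std::string>(seqs[i]);
    fm->clen.push_back((int32_t)s.size());
    for (char ch : s) fm->text.push_back(color ? code_color(ch) : code_base(ch));
  }
  fm->n = (int32_t)fm->text.size();
  fm->build(sa_rate);
  return XPtr<FM>(fm, true);
}

// [[Rcpp::export]]
List cpp_index_info(SEXP ptr) {
  XPtr<FM> fm(ptr);
  return List::create(
    _["names"] = fm->names,
    _["starts"] = IntegerVector(fm->cstart.begin(), fm->cstart.end()),
    _["lengths"] = IntegerVector(fm->clen.begin(), fm->clen.end()),
    _["text_length"] = fm->n,
    _["sa_sample_rate"] = fm->sa_rate);
}

// [[Rcpp::export]]
std::string cpp_index_bwt(SEXP ptr) {
  XPtr<FM> fm(ptr);
  static const char* sym = "$ACGTN";
  std::string out(fm->bwt.size(), ' ');
  for (size_t i = 0; i < fm->bwt.size(); i++) out[i] = sym[fm->bwt[i]];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_backward_search(SEXP ptr, std::string pattern, bool color) {
  XPtr<FM> fm(ptr);
  std::vector<uint8_t> p = encode_seq(pattern, color);
  int64_t lo, hi;
  if (p.empty()) stop("empty pattern");
  fm->search(p.data(), (int)p.size(), lo, hi);
  return IntegerVector::create((int)lo, (int)hi);
}

// [[Rcpp::export]]
IntegerVector cpp_locate_range(SEXP ptr, int lo, int hi, int max_occ) {
  XPtr<FM> fm(ptr);
  std::vector<int> out;
  int64_t take = std::min<int64_t>((int64_t)hi - lo, max_occ);
  for (int64_t r = lo; r < lo + take; r++) out.push_back(fm->locate(r));
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export]]
std::string cpp_extract_text(SEXP ptr, double start, int len, bool color = false) {
  XPtr<FM> fm(ptr);
  const char* sym = color ? "0123." : "ACGTN";
  int64_t s = (int64_t)start;
  if (s < 0 || s + len > fm->n) stop("extraction outside text bounds");
  std::string out(len, ' ');
  for (int i = 0; i < len; i++) out[i] = sym[fm->text[s + i]];
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_find_seeds(SEXP ptr, std::string read, int minlen, int max_occ,
                         bool kmers, bool color) {
  XPtr<FM> fm(ptr);
  ReadCtx ctx; init_ctx(ctx, read, color);
  std::vector<SeedC> seeds;
  for (int st = 0; st < 2; st++) {
    if (kmers) find_kmers_strand(*fm, ctx.ori[st], st, minlen, max_occ, seeds);
    else find_mems_strand(*fm, ctx.ori[st], st, minlen, max_occ, seeds);
  }
  int n = (int)seeds.size();
  IntegerVector roff(n), len(n), strand(n);
  NumericVector gpos(n);
  CharacterVector kind(n);
  for (int i = 0; i < n; i++) {
    roff[i] = seeds[i].roff; gpos[i] = (double)seeds[i].gpos;
    len[i] = seeds[i].len; strand[i] = seeds[i].strand;
    kind[i] = seeds[i].kind == 0 ? "MEM" : "KMER";
  }
  return DataFrame::create(
    _["read_offset"] = roff, _["genome_pos"] = gpos, _["length"] = len,
    _["strand"] = strand, _["kind"] = kind, _["stringsAsFactors"] = false);
}

// ---------- exported: DP kernels ----------

static List aln_to_list(const AlnOut& a) {
  std::string cig;
  for (auto& p : a.cig) cig += std::to_string(p.second) + p.first;
  return List::create(
    _["score"] = a.score, _["ref_start"] = a.ref_start, _["cigar"] = cig,
    _["matches"] = a.matches, _["mismatches"] = a.mismatches,
    _["insertions"] = a.ins, _["deletions"] = a.del,
    _["sclip_left"] = a.sclip_l, _["sclip_right"] = a.sclip_r,
    _["empty"] = a.empty);
}

// [[Rcpp::export]]
List cpp_local_align(std::string read, std::string region, List scoring, bool color) {
  Scoring sc;
  sc.match = as<int>(scoring["match"]); sc.mismatch = as<int>(scoring["mismatch"]);
  sc.gap_open = as<int>(scoring["gap_open"]); sc.gap_extend = as<int>(scoring["gap_extend"]);
  std::vector<uint8_t> q = encode_seq(read, color), r = encode_seq(region, color);
  AlnOut a;
  local_align(q.data(), (int)q.size(), r.data(), (int)r.size(), sc, a);
  return aln_to_list(a);
}

// [[Rcpp::export]]
List cpp_semiglobal_align(std::string read, std::string region, List scoring, bool color) {
  Scoring sc;
  sc.match = as<int>(scoring["match"]); sc.mismatch = as<int>(scoring["mismatch"]);
  sc.gap_open = as<int>(scoring["gap_open"]); sc.gap_extend = as<int>(scoring["gap_extend"]);
  std::vector<uint8_t> q = encode_seq(read, color), r = encode_seq(region, color);
  AlnOut a;
  semiglobal_align(q.data(), (int)q.size(), r.data(), (int)r.size(), sc, a);
  return aln_to_list(a);
}

// ---------- exported: SE batch ----------

// [[Rcpp::export]]
List cpp_align_se_batch(SEXP ptr, CharacterVector reads, List cfgl) {
  XPtr<FM> fm(ptr);
  Cfg cfg = cfg_from_list(cfgl);
  Rows rows;
  for (int i = 0; i < reads.size(); i++) {
    ReadCtx ctx;
    init_ctx(ctx, as<std::string>(reads[i]), cfg.color);
    se_align(*fm, ctx, cfg);
    for (size_t k = 0; k < ctx.rep.size(); k++)
      rows.add(*fm, i + 1, 0, (int)k + 1, ctx.cands[ctx.rep[k]], ctx.mapq,
               ctx.L, false, (int)ctx.cands.size());
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return rows.to_list();
}

// ---------- paired-end ----------

struct SeedPairC { int r1, r2; double w; int64_t ip1; };
struct APairC {
  Cand c1, c2; double w; int edit_sum;
  int64_t ins;
};

static bool pair_geometry(const Cfg& cfg, const Cand& c1, const Cand& c2,
                          const FM& fm, int64_t& ins) {
  if (fm.contig_of(c1.gstart) != fm.contig_of(c2.gstart)) return false;
  int64_t l1 = c1.gstart, r1 = c1.gstart + c1.refspan();
  int64_t l2 = c2.gstart, r2 = c2.gstart + c2.refspan();
  if (cfg.orient_ff) {
    if (c1.strand != c2.strand) return false;
    ins = l2 >= l1 ? r2 - l1 : r1 - l2;
  } else {
    if (c1.strand == c2.strand) return false;
    if (c1.strand == 0) { if (l2 < l1) return false; ins = r2 - l1; }
    else { if (l1 < l2) return false; ins = r1 - l2; }
  }
  return true;
}

// geometry on seed-implied placements (before extension)
static bool seed_geometry(const Cfg& cfg, const FM& fm, const Reg& a, int La,
                          const Reg& b, int Lb, int64_t& ins) {
  if (fm.contig_of(a.rs) != fm.contig_of(b.rs)) return false;
  int64_t l1 = a.ipos, r1 = a.ipos + La, l2 = b.ipos, r2 = b.ipos + Lb;
  if (cfg.orient_ff) {
    if (a.strand != b.strand) return false;
    ins = l2 >= l1 ? r2 - l1 : r1 - l2;
  } else {
    if (a.strand == b.strand) return false;
    if (a.strand == 0) { if (l2 < l1) return false; ins = r2 - l1; }
    else { if (l1 < l2) return false; ins = r1 - l2; }
  }
  return true;
}

static std::vector<int> hq_regions(const ReadCtx& ctx, const Cfg& cfg) {
  std::vector<int> ord = rank_regions(ctx);
  std::vector<int> hq;
  for (int i : ord) {
    if (ctx.regs[i].q >= cfg.min_seed_score) hq.push_back(i);
    if ((int)hq.size() >= cfg.max_top_seeds) break;
  }
  return hq;
}

static std::vector<SeedPairC> make_seed_pairs(const FM& fm, const Cfg& cfg,
                                              ReadCtx& c1, ReadCtx& c2,
                                              double ilo, double ihi) {
  std::vector<SeedPairC> out;
  std::vector<int> h1 = hq_regions(c1, cfg), h2 = hq_regions(c2, cfg);
  const double denom = (double)cfg.sc.match * (c1.L + c2.L);
  for (int a : h1) for (int b : h2) {
    int64_t ins;
    if (!seed_geometry(cfg, fm, c1.regs[a], c1.L, c2.regs[b], c2.L, ins)) continue;
    if (ins < ilo || ins > ihi) continue;
    SeedPairC sp;
    sp.r1 = a; sp.r2 = b;
    sp.w = (c1.regs[a].q + c2.regs[b].q) / denom;
    sp.ip1 = c1.regs[a].ipos;
    out.push_back(sp);
  }
  // max-heap order: non-increasing weight, deterministic ties
  std::sort(out.begin(), out.end(), [](const SeedPairC& x, const SeedPairC& y) {
    if (x.w != y.w) return x.w > y.w;
    if (x.ip1 != y.ip1) return x.ip1 < y.ip1;
    return x.r1 < y.r1;
  });
  return out;
}

static void add_kmer_seeds(const FM& fm, ReadCtx& ctx, const Cfg& cfg) {
  if (ctx.kmer_done || ctx.L < cfg.kmer) { ctx.kmer_done = true; return; }
  std::vector<SeedC> seeds;
  for (int st = 0; st < 2; st++)
    find_kmers_strand(fm, ctx.ori[st], st, cfg.kmer, cfg.max_occ, seeds);
  add_regions(fm, ctx, seeds, cfg);
  score_regions(fm, ctx, cfg);
  ctx.kmer_done = true;
}

// rescue the mate inside the window implied by an anchored alignment
static bool rescue_mate_core(const FM& fm, const Cfg& cfg, const Cand& anchor,
                             int La, ReadCtx& mate, double ilo, double ihi,
                             Cand& out) {
  const int Lm = mate.L, mg = cfg.margin(Lm);
  int mstrand = cfg.orient_ff ? anchor.strand : 1 - anchor.strand;
  int cg = fm.contig_of(anchor.gstart);
  int64_t cs = fm.cstart[cg], ce = cs + fm.clen[cg];
  int64_t wlo, whi;  // candidate window for the mate's leftmost position
  if (cfg.orient_ff) {
    wlo = anchor.gstart - (int64_t)ihi - mg;
    whi = anchor.gstart + (int64_t)ihi + mg;
  } else if (anchor.strand == 0) {
    wlo = anchor.gstart + (int64_t)ilo - Lm - mg;
    whi = anchor.gstart + (int64_t)ihi + mg;
  } else {
    int64_t r = anchor.gstart + anchor.refspan();
    wlo = r - (int64_t)ihi - mg;
    whi = r - (int64_t)ilo + Lm + mg;
  }
  wlo = std::max(wlo, cs);
  whi = std::min(whi, ce);
  if (whi - wlo < 1) return false;
  AlnOut a;
  semiglobal_align(mate.ori[mstrand].data(), Lm,
                   fm.text.data() + wlo, (int)(whi - wlo), cfg.sc, a);
  if (!qual_aln(a, Lm, true, cfg)) return false;
  out.strand = mstrand; out.mode = 2; out.a = a;
  out.gstart = wlo + a.ref_start; out.score = a.score;
  return true;
}

// per-end MAPQ from its accumulated candidate set
static int end_mapq(ReadCtx& ctx, const Cfg& cfg) {
  rank_cands(ctx, cfg);
  return ctx.mapq;
}

// [[Rcpp::export]]
List cpp_align_pe_batch(SEXP ptr, CharacterVector r1, CharacterVector r2,
                        double insert_mean, double insert_sd, List cfgl) {
  XPtr<FM> fm(ptr);
  Cfg cfg = cfg_from_list(cfgl);
  if (r1.size() != r2.size()) stop("read files have different numbers of records");
  const double ilo = std::max(0.0, insert_mean - cfg.insert_nsd * insert_sd);
  const double ihi = insert_mean + cfg.insert_nsd * insert_sd;
  Rows rows;

  for (int i = 0; i < r1.size(); i++) {
    ReadCtx c1, c2;
    init_ctx(c1, as<std::string>(r1[i]), cfg.color);
    init_ctx(c2, as<std::string>(r2[i]), cfg.color);
    std::vector<SeedC> seeds;
    for (int st = 0; st < 2; st++) find_mems_strand(*fm, c1.ori[st], st, cfg.min_mem_len, cfg.max_occ, seeds);
    add_regions(*fm, c1, seeds, cfg); c1.mem_done = true;
    seeds.clear();
    for (int st = 0; st < 2; st++) find_mems_strand(*fm, c2.ori[st], st, cfg.min_mem_len, cfg.max_occ, seeds);
    add_regions(*fm, c2, seeds, cfg); c2.mem_done = true;
    score_regions(*fm, c1, cfg); score_regions(*fm, c2, cfg);

    // weighted seed pairing with iterative k-mer re-seeding
    std::vector<SeedPairC> pairs = make_seed_pairs(*fm, cfg, c1, c2, ilo, ihi);
    while (pairs.empty() && cfg.en_kmer && (!c1.kmer_done || !c2.kmer_done)) {
      ReadCtx* pick;
      if (c1.kmer_done) pick = &c2;
      else if (c2.kmer_done) pick = &c1;
      else {
        size_t n1 = hq_regions(c1, cfg).size(), n2 = hq_regions(c2, cfg).size();
        pick = n2 < n1 ? &c2 : &c1;
      }
      add_kmer_seeds(*fm, *pick, cfg);
      pairs = make_seed_pairs(*fm, cfg, c1, c2, ilo, ihi);
    }

    // extend seed pairs into qualified alignment pairs
    std::vector<APairC> apairs;
    int examined = 0;
    const double denom = (double)cfg.sc.match * (c1.L + c2.L);
    for (const auto& sp : pairs) {
      if (examined++ >= cfg.max_pairs_extend) break;
      Cand a1, a2;
      if (!finalize_region(*fm, c1, sp.r1, cfg, a1)) continue;
      if (!finalize_region(*fm, c2, sp.r2, cfg, a2)) continue;
      int64_t ins;
      if (!pair_geometry(cfg, a1, a2, *fm, ins)) continue;
      if (ins < ilo || ins > ihi) continue;
      push_cand(c1, a1); push_cand(c2, a2);
      APairC ap;
      ap.c1 = a1; ap.c2 = a2; ap.ins = ins;
      ap.w = (double)(a1.score + a2.score) / denom;
      ap.edit_sum = a1.edit() + a2.edit();
      apairs.push_back(ap);
      if ((int)apairs.size() >= 4 * cfg.max_reported) break;
    }
    std::sort(apairs.begin(), apairs.end(), [](const APairC& x, const APairC& y) {
      if (x.w != y.w) return x.w > y.w;
      if (x.edit_sum != y.edit_sum) return x.edit_sum < y.edit_sum;
      return x.c1.gstart < y.c1.gstart;
    });
    { // dedup identical placements
      std::vector<APairC> ded;
      for (auto& ap : apairs) {
        bool dup = false;
        for (auto& e : ded)
          if (e.c1.gstart == ap.c1.gstart && e.c2.gstart == ap.c2.gstart &&
              e.c1.strand == ap.c1.strand) { dup = true; break; }
        if (!dup) ded.push_back(ap);
        if ((int)ded.size() >= cfg.max_reported) break;
      }
      apairs = std::move(ded);
    }

    int rescued_end = 0, anchor_mapq_used = 0;
    if (apairs.empty() && cfg.en_mate_rescue) {
      se_align(*fm, c1, cfg); se_align(*fm, c2, cfg);
      struct Anchor { int end; int rank; int mapq; };
      std::vector<Anchor> anchors;
      for (size_t k = 0; k < c1.rep.size(); k++)
        if (c1.mapq >= cfg.rescue_min_mapq) anchors.push_back({1, (int)k, c1.mapq});
      for (size_t k = 0; k < c2.rep.size(); k++)
        if (c2.mapq >= cfg.rescue_min_mapq) anchors.push_back({2, (int)k, c2.mapq});
      std::stable_sort(anchors.begin(), anchors.end(),
                       [](const Anchor& a, const Anchor& b) { return a.mapq > b.mapq; });
      int tried = 0;
      for (const auto& an : anchors) {
        if (tried++ >= cfg.max_top_seeds) break;
        ReadCtx& actx = an.end == 1 ? c1 : c2;
        ReadCtx& mctx = an.end == 1 ? c2 : c1;
        const Cand& acand = actx.cands[actx.rep[an.rank]];
        Cand res;
        if (!rescue_mate_core(*fm, cfg, acand, actx.L, mctx, ilo, ihi, res)) continue;
        int64_t ins;
        Cand cc1 = an.end == 1 ? acand : res;
        Cand cc2 = an.end == 1 ? res : acand;
        if (!pair_geometry(cfg, cc1, cc2, *fm, ins) || ins < ilo || ins > ihi) continue;
        push_cand(mctx, res);
        APairC ap;
        ap.c1 = cc1; ap.c2 = cc2; ap.ins = ins;
        ap.w = (double)(cc1.score + cc2.score) / denom;
        ap.edit_sum = cc1.edit() + cc2.edit();
        apairs.push_back(ap);
        rescued_end = an.end == 1 ? 2 : 1;
        anchor_mapq_used = an.mapq;
        break;
      }
    }

    if (!apairs.empty()) {
      int mq1 = end_mapq(c1, cfg), mq2 = end_mapq(c2, cfg);
      if (rescued_end == 1) mq1 = std::min(mq1, anchor_mapq_used);
      if (rescued_end == 2) mq2 = std::min(mq2, anchor_mapq_used);
      for (size_t k = 0; k < apairs.size(); k++) {
        rows.add(*fm, i + 1, 1, (int)k + 1, apairs[k].c1, mq1, c1.L, true,
                 (int)c1.cands.size());
        rows.add(*fm, i + 1, 2, (int)k + 1, apairs[k].c2, mq2, c2.L, true,
                 (int)c2.cands.size());
      }
    } else {
      // unpaired: report best SE alignments per end, if any
      se_align(*fm, c1, cfg); se_align(*fm, c2, cfg);
      for (size_t k = 0; k < c1.rep.size(); k++)
        rows.add(*fm, i + 1, 1, (int)k + 1, c1.cands[c1.rep[k]], c1.mapq,
                 c1.L, false, (int)c1.cands.size());
      for (size_t k = 0; k < c2.rep.size(); k++)
        rows.add(*fm, i + 1, 2, (int)k + 1, c2.cands[c2.rep[k]], c2.mapq,
                 c2.L, false, (int)c2.cands.size());
    }
    if (i % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  return rows.to_list();
}

// [[Rcpp::export]]
List cpp_rescue_mate(SEXP ptr, double anchor_gstart, int anchor_strand,
                     int anchor_refspan, int anchor_mapq, std::string mate,
                     double insert_mean, double insert_sd, List cfgl) {
  XPtr<FM> fm(ptr);
  Cfg cfg = cfg_from_list(cfgl);
  if (anchor_mapq < cfg.rescue_min_mapq)
    return List::create(_["rescued"] = false, _["reason"] = "anchor MAPQ below threshold");
  const double ilo = std::max(0.0, insert_mean - cfg.insert_nsd * insert_sd);
  const double ihi = insert_mean + cfg.insert_nsd * insert_sd;
  Cand anchor;
  anchor.strand = anchor_strand; anchor.gstart = (int64_t)anchor_gstart;
  anchor.score = 0; anchor.mode = 0;
  anchor.a.matches = anchor_refspan;  // refspan() = matches+mismatches+del
  ReadCtx mctx; init_ctx(mctx, mate, cfg.color);
  Cand res;
  if (!rescue_mate_core(*fm, cfg, anchor, anchor_refspan, mctx, ilo, ihi, res))
    return List::create(_["rescued"] = false, _["reason"] = "no qualified alignment in window");
  int cg = fm->contig_of(res.gstart);
  std::string cig;
  for (auto& p : res.a.cig) cig += std::to_string(p.second) + p.first;
  int albases = res.a.matches + res.a.mismatches + res.a.ins;
  return List::create(
    _["rescued"] = true, _["contig"] = cg + 1,
    _["pos"] = (double)(res.gstart - fm->cstart[cg]),
    _["strand"] = res.strand, _["score"] = res.score, _["cigar"] = cig,
    _["nm"] = res.edit(),
    _["identity"] = albases ? 100.0 * res.a.matches / albases : 0.0);
}

// [[Rcpp::export]]
int cpp_compute_mapq(int best, int second, int n_best, bool has_second) {
  return compute_mapq_core(best, second, n_best, has_second);
}
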