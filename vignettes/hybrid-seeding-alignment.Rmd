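---
title: "Hybrid-seeding short-read alignment: model, parameters and design notes"
author: "hybridaln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-seeding short-read alignment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridaln)
```

## The alignment model

`hybridaln` is a seed-and-extend short-read aligner. A read is anchored on the
genome by short exact matches found through an FM-index (a Burrows–Wheeler
transform with a rank structure and a sampled suffix array), and each anchor is
then extended into a full alignment by dynamic programming. What distinguishes
the pipeline is that it draws on three seed types with different
failure modes:

* **MEM seeds** — maximal exact matches between either strand of the read and
  the genome, extendable in neither direction. They are long and specific but
  disappear when sequencing errors fall densely.
* **Exact-match k-mer seeds** — the read is tiled into `floor(L/k)`
  non-overlapping k-mers; each window with at least one exact occurrence
  seeds the re-seeding stage. Short windows survive error densities that
  destroy every long MEM.
* **Variable-length seeds** — when no *local* extension qualifies, the best
  local alignment itself is reused as an anchor: the full-read placement it
  implies defines a fresh window, and the read is re-aligned *semi-globally*
  (end-to-end, free gaps at the window edges). This path captures reads with
  long contiguous mismatch blocks or long indels, which local alignment
  prefers to clip away because the match reward is smaller than the mismatch
  and gap penalties.

The single-end pipeline runs exactly in this order: MEM seeding on both
strands; scoring of every seed by the optimal local alignment of the read
against the seed's mapping region; extension of the top-ranked seeds, keeping
qualified local alignments; otherwise one semi-global rescue from the best
local alignment; otherwise one round of k-mer re-seeding followed by the same
extension and rescue; otherwise the read is reported unaligned.

An alignment **qualifies** when its percent identity (matches over aligned
read bases, i.e. M+I columns) reaches the mode-specific threshold — 90% for
local, 65% for semi-global — and at least 80% of the read's bases are aligned
rather than soft-clipped. The looser semi-global identity floor is what lets
the rescue path accept alignments the local constraints reject; the coverage
floor is trivially satisfied there because semi-global alignment never clips.

## Paired-end alignment

Both ends are seeded and scored as above. Seeds with score at least
`min_seed_score` (30 under the default scoring) are **paired**: every
high-quality seed combination in the proper orientation whose implied insert
falls inside the window `mean ± 4·sd` receives the weight

$$ w = \frac{q_1 + q_2}{m\,(L_1 + L_2)}, $$

where $q_i$ is the optimal local alignment score of end $i$ against its
mapping region, $m$ the match score and $L_i$ the read lengths; $w \in [0,1]$
and is monotone in each $q_i$. Candidate pairs are held in a max-heap keyed on
$w$ and extended in non-increasing weight order. While no qualified seed pair
exists and some end has not yet been re-seeded, that end (the one with fewer
high-quality seeds first) receives k-mer seeds, the lists are merged,
re-ranked and re-paired. Extended **alignment pairs** must again satisfy the
insert-size constraint on their actual mapping positions; they are ranked by
the same weight recomputed from the final scores (which may be semi-global
scores), with smaller edit-distance sums breaking ties, and further ties going
to the leftmost coordinate for determinism.

When no alignment pair emerges, **mate rescue** takes over: every reported
alignment of either end with MAPQ ≥ 20 serves, in decreasing MAPQ order and
bounded by `max_top_seeds`, as an anchor; the mate is aligned semi-globally
inside the window the anchor and the insert distribution imply, and accepted
under the semi-global qualification rules. Reads that still remain unpaired
are reported through their best single-end alignments.

## Color space

SOLiD reads arrive as a primer base plus one color per base, each color
encoding a di-base transition (the XOR of the 2-bit base codes). The genome
is color-encoded contig by contig and indexed; because the code is
complement-invariant, the reverse strand of a color sequence is its plain
reversal, and the same engine runs with complementation disabled. The primer
and its adjacent first color are stripped before seeding (they are the only
symbols tied to the sequencing chemistry rather than the genome). A qualified
color alignment is translated to nucleotides by dynamic programming over the
four possible bases per position: transitions inconsistent with the observed
color cost 1, emitting a base that contradicts the aligned reference base
costs 2, missing colors (`.`) are free, and the chain is anchored at the
primer. The asymmetric costs encode that an isolated color mismatch is far
more likely a sequencing error than a variant; with exact reference guidance a
single color error is absorbed as one color correction rather than cascading
through every downstream base (we verified the dynamic program against
exhaustive enumeration over all $4^L$ base strings for short reads). The
translated read is finally re-aligned in base space with the same mode as its
parent color alignment, and only base-space alignments are reported.
Mate-paired color reads use the FF layout.

## MAPQ

The mapping quality of a read is derived from its candidate list: 0 when two
or more candidates are co-optimal, 60 when no runner-up exists, otherwise
`round(60·(best − second)/best)` clamped to [0, 60]. All alignments reported
for one read share the primary's MAPQ, and secondary records carry the SAM
0x100 flag. A rescued mate cannot exceed its anchor's MAPQ. This gap-ratio
rule is a deliberate, documented design choice: it is PHRED-like in spirit
(larger separation, higher confidence) and well-behaved for downstream tools,
but it is not calibrated as a posterior error probability.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `match / mismatch / gap_open / gap_extend` | 1 / −3 / −5 / −2 | affine scoring; penalties exceed the match reward so dense-error regions score poorly locally and route into the semi-global rescue; a gap of length *g* costs `gap_open + g·gap_extend` |
| `min_mem_len` | `min(17, ⌈log₄ G⌉ + 3)` | below ~`log₄ G` a random seed hits everywhere; +3 keeps spurious MEMs rare while a 6%-error read still carries a long-enough clean stretch most of the time (15 on the 10-Mb study genome) |
| `kmer` | 13 | a 13-mer window is error-free with probability 0.94¹³ ≈ 0.45 at 6% error, and ⌊100/13⌋ = 7 windows per strand give several chances per read |
| `max_occ` | 1000 | deterministic cap on repeat explosions: the first `max_occ` positions in suffix-array order |
| `min_id_local / min_id_global / min_align_frac` | 90 / 65 / 0.80 | the qualification constraints described above |
| `max_seeds_extend` | 20 | extension stops early once `max_reported` qualified alignments are found |
| `max_reported` | 10 | up to 10 alignments (or pairs) per read: one primary plus ≤ 9 secondary records |
| `min_seed_score` | 30·match | entry bar into seed pairing, rescaled with the match score |
| `insert_nsd` | 4 | insert window half-width in standard deviations |
| `rescue_min_mapq / max_top_seeds` | 20 / 100 | anchor confidence gate and work bound for mate rescue |
| `sa_sample_rate` | 8 | suffix-array sampling; memory/speed trade-off, exactness unaffected |

## Numerical and tie-breaking choices

All coordinates are 0-based half-open internally; conversion to 1-based
happens only at SAM emission. The DP kernels use full matrices (no banding,
no heuristics), so their scores are the reference semantics; tie-breaking is
fixed — diagonal over deletion over insertion, gap openings over extensions,
and among equal-scoring end cells the smallest reference coordinate — which
makes every alignment, and therefore the entire tool, deterministic for fixed
inputs. Identity is computed over aligned read bases (M+I columns); `N` is
excluded from the index alphabet, never matches anything, and separator
symbols between contigs guarantee that no seed or extension crosses a contig
boundary. Alignment lists are ordered by descending score, then ascending
edit distance, then leftmost coordinate; this ordering also defines the
"first alignment occurrence" that the evaluator's strict recall uses.

## The simulator and what passing tests mean

The built-in simulator mirrors the classic whole-genome-shotgun read
simulator's default behaviour: fragment loci uniform over the genome, insert
sizes from N(μ, σ) (N(500, 50) for the Illumina-like study sets, N(200, 20)
for color mate-pairs), FR orientation (FF for color), and substitution-only
errors at a uniform per-base rate, injected after the true positions are
recorded. Optional indel-carrying reads for the rescue analyses are
constructed explicitly in the tests. The study conditions used throughout the
package's benchmark are a 10-Mb uniform-random genome and 50,000 100-bp pairs
per error rate (2% and 6%), sizes at which every run completes in about a
minute on one core.

A uniform-random genome is repeat-free at seed scale, so the benchmark is
easier than a mammalian genome: recall losses from repetitive placements,
low-complexity regions, true indels and non-uniform error profiles are not
exercised. Passing these benchmarks therefore demonstrates the machinery —
seeding sensitivity, extension correctness, pairing and rescue logic, metric
definitions — not field performance on real libraries. The property-based
tests (brute-force MEM enumeration, full-matrix DP oracles, exhaustive
translation search, exhaustive seed-pair enumeration) are the stronger
correctness evidence, because they hold for arbitrary inputs in the tested
size range.

The mate-rescue ablation deserves one sizing note: at 6% substitution error a
read loses *every* seed (no clean run ≥ 15 and no clean 13-mer window) with
probability ≈ 0.0017, so demonstrating that disabling rescue strictly drops
the paired fraction needs a few thousand pairs for the event to occur at all;
the tests use sample sizes chosen from that calculation.

## Worked example

```{r example}
genome <- simulate_genome(200000, seed = 1)
idx <- build_index(genome)
sim <- simulate_pe_reads(genome, n_pairs = 500, read_len = 100,
                         err_rate = 0.06, insert_mean = 500, insert_sd = 50,
                         seed = 2)
pe <- align_pairs(idx, sim$reads1, sim$reads2)
evaluate_alignments(pe, sim$truth)
```

## Known limitations

* The MAPQ rule is uncalibrated (see above); ROC curves built on it order
  alignments sensibly but the values are not error probabilities.
* Repeat handling is bounded (`max_occ`) but not optimized: heavy repeat
  families cost time linearly in the cap.
* Only substitution errors are simulated by default; the aligner itself
  handles indels (affine gaps end-to-end), but the simulator does not model
  platform-specific indel profiles.
* SAM/BAM as *read input*, RF mate-pair base-space libraries, multiple insert
  populations, and banded/SIMD kernels are out of scope.
* The FM-index targets desk-scale genomes (tens of megabases); it uses plain
  32-bit structures rather than the compressed representations a 3-Gb genome
  would require.
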