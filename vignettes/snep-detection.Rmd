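---
title: "Detecting single-nucleosome epi-polymorphisms from two-strain tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single-nucleosome epi-polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Two unrelated *Saccharomyces cerevisiae* strains (a laboratory strain, "BY",
and a vineyard-derived strain, "RM") can differ not only in DNA sequence but
in the histone-modification state of individual nucleosomes. `snepr`
implements the full computational path from raw tiling-microarray
hybridization signal to a genome-wide catalogue of such differences —
single-nucleosome epi-polymorphisms (SNEPs) — for a mark such as H3K14
acetylation, assayed by ChIP on mononucleosomal DNA alongside a
nucleosome-mapping (MNase protection) hybridization.

The pipeline has four statistical stages, each exposed as ordinary R
functions and exercised end to end on synthetic data:

1. **Probe preparation** — select probes usable in both genomes and
   quantile-normalize all arrays together.
2. **Nucleosome calling** — a duration-structured hidden Markov model per
   strain.
3. **Cross-strain alignment** — project one strain's calls onto the other's
   coordinates through whole-genome alignment blocks and pair up the two
   nucleosome maps.
4. **SNEP testing** — a per-nucleosome ANOVA whose strain × assay-type
   interaction is the quantity of interest, under Benjamini–Hochberg FDR
   control.

# Probe preparation

Hybridization intensity is only comparable between strains where the exact
same 25-mer has a unique perfect match in both genomes. `select_dual_probes()`
keeps probes that (i) match uniquely in both genomes, (ii) whose RM match,
lifted through the alignment blocks onto BY coordinates, lies within ±3 bp
of the BY match (the slack absorbs micro-ambiguity at block edges), and
(iii) whose footprint contains no BY/RM polymorphism, since even a single
mismatch biases hybridization efficiency. Probes whose RM match is not fully
contained in one alignment block are excluded: block boundaries are
indel-adjacent and the lifted coordinate is ill-defined there.

Indel handling in rule (iii) needs a convention. SNPs and BY-side insertions
occupy their reference footprint; a deletion (sequence absent from BY) is
projected to the 1 bp junction it leaves in BY, so a probe spanning the
breakpoint is excluded. This is the narrowest reading that still catches
every probe whose target sequence differs between the strains.

`quantile_normalize()` implements rank-mean quantile normalization over all
arrays jointly: the value at rank *r* in every array is replaced by the mean
of the rank-*r* values across arrays. Missing values are excluded from the
ranking and restored afterwards; when arrays have unequal numbers of
observed values, the reference distribution is read off at proportion points
(type-7 quantiles), which reduces to the exact rank-mean in the balanced
case. Ties keep their input order, preserving the exact-multiset property of
the normalized columns. Missing intensities are never imputed here — the HMM
downstream marginalizes over them.

# The nucleosome-calling HMM

## Model

Three macro-states describe the mapping-assay signal: **linker** (L),
**well-positioned nucleosome** (W), and **delocalized (fuzzy) nucleosome**
(D). Emissions are Gaussian per macro-state on the log2 scale. Nucleosome
geometry enters through the transition structure rather than the emissions:

* W is a chain of `d_W = round(147 / spacing)` sub-states — a well-positioned
  nucleosome protects ~147 bp, so at 4 bp probe spacing the state lasts
  exactly 37 probes;
* D is a chain of `d_Dmin = round(100 / spacing)` sub-states followed by a
  geometric self-loop whose continuation probability is set so the mean
  delocalized length is ~160 bp;
* L has a free self-loop and free entry probabilities into W and D,
  re-estimated by EM.

Missing probes contribute emission likelihood 1, i.e. they are marginalized
out; state probabilities at missing positions are driven entirely by their
neighbors through the transition structure.

## Fitting and decoding

Hybridization signal drifts along the chromosome on scales much larger than
a nucleosome, so a single genome-wide emission model would be misspecified.
The HMM is therefore fitted by EM independently in overlapping 1 kb windows
(~250 probes at 4 bp spacing) stepped by half a window, so every interior
probe is covered by two windows. Per probe, all window parameters and
posteriors are then averaged, and one global Viterbi pass plus one global
forward–backward pass per chromosome segment decode the averaged,
position-specific model. Averaging-then-one-decode was chosen over
re-decoding each window because it yields a single consistent path and
avoids stitching artifacts at window seams.

Numerical choices worth knowing:

* EM initialization is deterministic and scale-adaptive: state means start
  at the window's 25th/60th/90th signal percentiles, all state sds at the
  segment's MAD. An optional seeded jitter (`jitter_sd`) exists for
  sensitivity analysis and is off by default.
* After each M-step the three states are relabeled so that
  mean(W) ≥ mean(D) ≥ mean(L); sds have a floor of 0.01 log2 units and
  emission densities a floor of 1e-290, so one extreme outlier cannot zero
  the forward recursion.
* Convergence at |Δ log-likelihood| < 1e-4 or 50 iterations; windows with
  fewer than 30 informative probes are skipped; probe gaps over 500 bp
  split a chromosome into independently decoded segments.
* Viterbi ties are broken toward the linker state.

Calls are maximal runs of W (category "well-positioned") or D
("delocalized"), spanning from the first probe's footprint start to the last
probe's footprint end; runs shorter than 100 bp are dropped. The call
posterior is the mean merged nucleosome posterior (W + D) over the run. The
reported category comes directly from the decoded macro-state, not from any
post-hoc fuzziness score.

On simulations with emission SNR (mean_W − mean_L)/sd = 2 at 4 bp tiling,
calls are recovered with recall and precision above 0.99 at ±20 bp midpoint
tolerance (the package's acceptance suite runs this on a 1 Mb genome with
roughly 5,000 nucleosomes).

# Cross-strain alignment

RM calls are projected onto BY coordinates through the alignment blocks
(offset arithmetic, mirrored for `-` orientation blocks). Calls spanning
block boundaries are dropped with a logged count; splitting them instead
would manufacture two half-nucleosomes with no evidential basis.

`align_maps()` then pairs the two maps per chromosome:

1. **Anchor pass.** Two nucleosomes are unambiguously aligned when their
   midpoint distance is below half their average size, i.e.
   `(len_BY + len_RM) / 4`, *and* they are mutually nearest. The mutual
   nearest condition is an addition: the distance rule alone can anchor one
   call twice in crowded regions.
2. **Recursion.** Between consecutive anchors the remaining calls are
   assigned by the maximum-cardinality, order-preserving one-to-one matching
   minimizing the summed midpoint distances (`match_min_cost()`, a dynamic
   program). For midpoints on a line an order-preserving optimum is a global
   optimum, so the assignment equals the exhaustive minimum over all
   one-to-one matchings; ties break toward the leftmost pairing for
   determinism.
3. Unmatched BY calls are insertions, unmatched RM calls deletions (with
   respect to BY).

Each pair carries likelihood annotations built from the mean merged
nucleosome posterior of each strain over the pair footprint:
`L(aligned) = B_n·R_n`, `L(insertion) = B_n·R_l`, `L(deletion) = B_l·R_n`,
with `B_l = 1 − B_n`. These are annotations of local alignment quality, not
filters — every pair is retained.

Note that the anchor rule deliberately departs from pure cost minimization:
when one strain has an extra nucleosome *and* the other is missing one
nearby, the anchor semantics produce an insertion plus a deletion rather
than forcing a distant match. The oracle-equivalence guarantee therefore
attaches to the recursion's assignment step.

# SNEP testing

For every aligned pair sharing at least 15 dual-match probes entirely
covered by both calls, the observations are the normalized log2 intensities
`y_ijkl` of probe *k* on replicate *l* of strain *i* (BY/RM) in assay type
*j* (nucleosome mapping / ChIP), modeled by ordinary least squares as

```
y = u + a_i + b_j + c_k + d_ij + e
```

A nucleosome equally acetylated in the two strains can differ in occupancy
(a_i) or in overall ChIP efficiency (b_j) without producing an interaction;
only a strain-specific mark level makes `d_ij ≠ 0`. The interaction is
tested by model comparison against the additive model with an F statistic on
1 numerator degree of freedom; with a single 2×2 interaction this coincides
with the Type-III test (asserted by test, not assumed). p-values are floored
at 1e-300. Each pair is fitted independently — no variance pooling or
shrinkage across nucleosomes — and the unbalanced replication (3 nucleosome
+ 6 ChIP replicates per strain) is handled by OLS as-is.

Probes observed in only one (strain, type) cell are dropped before fitting;
if the design collapses the pair is skipped with a reason.

Benjamini–Hochberg step-up over the full p-vector controls the FDR (default
level 1e-4); the run report includes the implied genome-wide nominal cutoff
`k·α/m`. Direction and fold-change come from cell means over the shared
probes: `Δ = [mean(chip,BY) − mean(nuc,BY)] − [mean(chip,RM) − mean(nuc,RM)]`,
direction BYac if Δ > 0, fold `2^|Δ|` ≥ 1. With balanced data this equals
the fitted interaction contrast; with missing values it matches the
displayed quantity log(acBY/nucBY) − log(acRM/nucRM) exactly, which is why
cell means rather than coefficients are used.

`snep_power_sim()` simulates pairs under the model's own assumptions and is
the calibration harness: at the defaults (20 probes, noise sd 0.25 log2
units) the null type-I error at nominal 0.05 is within Monte-Carlo error of
0.05 and the null p-value distribution passes a KS uniformity test at
n = 10,000.

# Gene-anchored profiles and enrichment statistics

* `metagene_profiles()` — per gene, 10 equal coding-sequence bins flanked by
  100 bp bins; signal is the replicate-mean per-probe `log2(ac/nuc)`
  restricted to intra-nucleosomal probes (so profiles are corrected for
  nucleosome abundance), log base 2 throughout. SNEP fractions per bin count
  nucleosomes overlapping the bin at least partially. Genes with under half
  their bins populated are excluded (threshold exposed). Flanks are fixed
  length and not truncated at neighboring genes.
* `tss_occupancy_matrix()` — ±300 bp around the TSS in 60 strand-oriented
  10 bp bins, averaging the merged nucleosome posterior per bin.
* `cluster_promoters()` — best-of-25-restarts K-means (Euclidean), K = 6 by
  default, with a between/within variance-ratio sweep over K = 1..10 as the
  model-choice diagnostic.
* `promoter_dissimilarity()` — per gene `1 − Spearman(R_BY, R_RM)` over the
  60-bin profiles, in [0, 2]; genes with constant profiles are flagged NA.
* Enrichment statistics (`snep_density_map()`, `upstream_enrichment()`,
  `local_correlation()`, `category_enrichment()`, `expression_association()`,
  `ranked_gene_enrichment()`, `remodeled_enrichment()`) share conventions:
  nucleosome-to-bin assignment by midpoint, except "fully covers" for the
  conserved-regulatory-site category and remodeled regions, and "overlaps at
  least partially" for metagene SNEP fractions; chi-square without
  continuity correction (a flag enables it); Wilson 95% intervals for
  fractions; permutation controls with a mandatory seed (default 100–1,000
  permutations depending on the analysis). Gene "beginning/middle/end"
  regions default to transcript thirds — a package convention, exposed as a
  parameter, since no canonical boundary exists.

# The synthetic-data generator

`simulate_dataset()` produces every input the pipeline consumes, plus truth
tables, from one seed:

* a reference genome and a derived query genome (SNP rate 0.4%/bp, indel
  rate 2×10⁻⁴/bp with geometric lengths of mean 8 bp — the rates implied by
  a ~52k-polymorphism budget on a 12 Mb genome), with alignment blocks and
  the polymorphism table emitted from the same edit script;
* gene models at 0.5 genes/kb with a 140 bp nucleosome-depleted region at
  each TSS and phased 147 bp nucleosomes with 15–25 bp linkers elsewhere
  (~165 bp repeat length, typical for yeast); 20% of nucleosomes are
  simulated as delocalized;
* 25-mer probes tiled every 4 bp (7 bp in the SNEP-recovery setting, giving
  ~20 probes per nucleosome), with query-side coordinates lifted through the
  edit script; probes overlapping polymorphisms are emitted with a
  hybridization penalty on query-strain arrays, and a few query-ambiguous
  probes are injected, so the filtering stage has real work to do;
* intensities on the log2 scale: state-dependent Gaussian emissions for the
  mapping assay (linker −1, delocalized 0.85, well-positioned 1.0, sd 0.5 by
  default), and ChIP signal adding a per-nucleosome acetylation offset
  (0.6 ± 0.15 log2 units, shared between strains). Injected SNEPs shift that
  offset by log2(fold) in one strain; folds default to 1.2–1.5 with a
  41.5%/58.5% BYac/RMac mix, the quantitative regime of interest. Replicate
  noise is independent; 1% of values are set missing.

The two strains share one nucleosome landscape up to indel-induced
coordinate shifts (nucleosomes hit by an indel junction are dropped from the
query strain). This isolates mark-level differences from positioning
differences by construction. The generator therefore does **not** emulate:
strain-specific positioning shifts, MNase or amplification bias, spatial
array artifacts, probe-sequence affinity, or correlated replicate noise.
Passing tests demonstrate correctness of the algorithms under the stated
model, not robustness to these real-data complications.

Problem sizes in the test and acceptance harnesses are chosen to keep the
full suite in the minutes range while leaving no algorithmic path
unexercised: 1 Mb / ~5,000 nucleosomes for positioning recovery, 200 kb /
~1,000 nucleosomes / 100 injected SNEPs for end-to-end recovery, 10,000
simulated pairs for test calibration, 500 random intervals for the
alignment oracle.

# Known limitations

* The emission family is a single Gaussian per state; heavy-tailed probe
  noise would call for a mixture or a robust emission, which the window
  averaging partly absorbs but does not model.
* Alignment assumes block-resolved, non-overlapping genome alignments as
  input; it does not attempt to split calls across block boundaries.
* The per-pair OLS has modest power for folds near 1.1 at realistic noise;
  no moderation across pairs is attempted by design (each nucleosome is its
  own experiment).
* Direction assignment for pairs with strong missingness imbalance leans on
  cell means; a pathological missingness pattern could bias Δ even when the
  F-test is valid.
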