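---
title: "Methods: downstream 3D-genome analysis of STAG paralog switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream 3D-genome analysis of STAG paralog switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

Cohesin rings contain either STAG1 or STAG2. When STAG2 is lost — as it
frequently is in melanoma and other cancers — STAG1 can take its place at
a subset of the vacated binding sites. This package implements the
downstream, desk-scale part of that analysis: it consumes upstream-caller
outputs (peak sets with per-condition signal, TAD calls, binned contact
matrices, HiChIP loop calls with replicate read support, expression
tables) and quantifies what changes between a wild-type (WT) and a
STAG2-knockdown (KD) condition:

1. **Binding switches.** For each site that loses STAG2, the per-factor
   signal change is `delta = log2((kd + eps) / (wt + eps))`. Sites are
   split into *switch* and *non-switch* groups by 1-D k-means (k = 2) on
   the STAG1 delta; the cluster with the larger mean STAG1 gain is the
   switch group. The *degree of switch* `D = delta[STAG1] + delta[STAG2]`
   is positive when the STAG1 gain over-compensates the STAG2 loss.
2. **TAD dynamics.** TAD edges extended by a 10-kb flank form boundary
   regions; overlapping or touching regions merge into one big boundary.
   WT and KD boundaries whose midpoints lie within a 10-kb tolerance are
   *stable* pairs, the rest *variable*. Per-TAD changes are classified as
   expanded / shrinked (a boundary moved outward / inward beyond the
   tolerance), with variable changes subcategorized as merged (one KD TAD
   covers >= 80% of two or more WT TADs), new-boundary (the moved KD
   boundary region overlaps no WT boundary region) or shifted.
3. **Contact metrics.** The contact-probability decay curve P(s) is the
   mean contact count at separation s divided by the chromosome's
   first-off-diagonal mean (so P(1) = 1), averaged across chromosomes
   with equal weight; a compartment-stratified variant pools A-A, A-B and
   B-B bin pairs under the same normalization. Insulation is the
   Crane-style sliding square: the log2 ratio of the mean contact count
   crossing each bin (window x window) to the chromosome-wide mean of
   those square means.
4. **Differential loops.** After removing self-ligated loops, loops with
   caller FDR > 0.01, and loops supported >= 5 reads in one replicate but
   0 in another of the same condition, each loop's counts are fit as an
   over-dispersed Poisson GLM of condition with a log library-size
   offset; BH-corrected Wald tests at FDR < 1% split loops into enhanced
   (stronger in KD) and impaired. Loops are further labeled PP/PE/EE by
   anchor annotation (promoter wins ties) and within/across/outside TADs
   by anchor midpoints.
5. **Super-enhancers.** H3K27ac peaks within 12.5 kb stitch together;
   stitched regions are ranked by total signal, both axes are min-max
   rescaled, and regions above the slope-1 tangency point of the ranked
   curve are super-enhancers. Condition sets are compared by reciprocal
   overlap (>= 50% of the shorter region) into gained / lost /
   maintained.
6. **Direct targets.** A gene is a direct target when it is
   differentially expressed (FDR < 0.05), its promoter (TSS +/- 2 kb)
   overlaps a lost-STAG2 peak, and its promoter overlaps an anchor of a
   differential loop. The cohort-style validation regresses the response
   expression on a confounder (e.g. STAT1) by OLS and Spearman-correlates
   the predictor with the residuals.

## Key parameters

| parameter | default | unit | why |
|---|---|---|---|
| `epsilon` | 0.5 | RPM | bounds log-ratios at zero-signal sites; symmetric in both conditions |
| `flank` | 10,000 | bp | boundary region half-width |
| `tolerance` | 10,000 | bp | stable/variable midpoint rule |
| `merge_coverage` | 0.8 | fraction | minimum coverage of each constituent WT TAD for a merge call |
| `stitch_distance` | 12,500 | bp | enhancer stitching gap (edge-to-edge) |
| `loop_fdr` | 0.01 | — | BH threshold for enhanced/impaired calls |
| `promoter_flank` | 2,000 | bp | promoter half-width around the TSS |
| `n_perm` | 1,000 | — | permutations for interval enrichment |
| `insulation_window` | 4 | bins | sliding-square half-width |

Where the underlying procedure is described in the literature without an
operational constant (pseudocount, merge coverage, self-ligation
distance, promoter width), the value above is this package's declared
choice and is exposed as a function argument.

## Numerical and design choices

- **Coordinates** are 0-based half-open (BED convention) everywhere;
  touching intervals merge, so adjacent TADs sharing an edge produce one
  boundary region.
- **Boundary matching** is a per-chromosome sweep in genomic order: each
  WT boundary takes the leftmost unmatched KD midpoint within tolerance.
  For points on a line with a distance threshold this greedy attains the
  maximum number of stable pairs, and ties break deterministically
  leftmost.
- **k-means** on a single feature with 10 restarts is effectively exact;
  a fixed seed makes labels reproducible and order-invariant. For inputs
  too small for `stats::kmeans`, the exact 1-D minimum within-cluster-SS
  split is used. All-identical features are a reported error, not a
  silent one-cluster result.
- **Loop dispersion.** With two replicates per condition a per-loop
  Pearson dispersion has 2 degrees of freedom; its estimates sit at the
  floor often enough that nominal FDR control fails badly. The package
  therefore pools Pearson residuals across all loops into one common
  over-dispersion (floored at 1, never under-dispersed) and uses it in
  every Wald test. The trade-off: under a negative-binomial world the
  variance of unusually high-count loops is understated. Power remains
  limited by the design itself: with mean-20 counts, dispersion 0.1 and
  2+2 replicates, the standard deviation of the estimated log fold
  change is about 0.37, so even an oracle test recovers only about half
  of 3-fold effects at FDR < 1%. Fold-change estimates for loops with an
  all-zero condition use a Haldane-style half-count on group totals;
  all-zero loops report p = 1 and class unchanged.
- **Super-enhancer cutoff.** The slope-1 point is computed as the argmax
  of (scaled rank − scaled signal) on the ascending curve — the tangency
  point of a unit-slope line for a convex curve — with ties taken at the
  lowest signal, so any non-constant input yields at least one
  super-enhancer. The cutoff is scale-invariant but, like any
  rescaled-rank rule, sensitive to the extremes of the signal
  distribution; comparisons between conditions are most stable when both
  curves share their top range.
- **Permutation null** re-places each site uniformly on its own
  chromosome with length preserved and overlaps among placed sites
  allowed — the simplest exchangeable null consistent with a
  "simulated overlap" description. Empirical p-values use the add-one
  (Phipson–Smyth) form and never report zero. All permutations are drawn
  in one vectorized pass.
- **Decay curves** are truncated at half the number of bins, where pair
  counts keep sampling error small; bins with all-zero rows (unmappable)
  are excluded from every mean. The compartment-stratified variant
  covers cis matrices; with single-chromosome inputs there is no trans
  pool.

## The synthetic scenario

`generate_scenario()` emits a complete paired WT/KD bundle with planted
truth on one 20-Mb chromosome, sized so the whole pipeline runs in
seconds: 100 TADs (120–200 kb, uniform gaps) of which 30 expand, 20
shrink and 10 adjacent pairs merge in KD, with boundary moves of
15–28 kb (beyond the 10-kb tolerance, within the inter-TAD gaps);
contact matrices at 20-kb bins with a power-law decay, a 2x within-TAD
boost and Poisson counts; 1000 lost-STAG2 sites of which 40% switch
(STAG1 delta ~ Normal(1.5, 0.3) vs Normal(0, 0.3)); 1000 loops (15%
enhanced, 15% impaired at 3x fold, NB dispersion 0.1, 2+2 replicates,
mean 20, 80% within TADs, enhanced loops planted longer); and 200 genes
of which 20 are wired as direct targets.

Deliberate generator choices worth knowing:

- Matrix bins default to 20 kb, not the 100 kb used on full-size
  genomes: on a 20-Mb toy chromosome with ~160-kb TADs, 100-kb bins
  would leave under two bins per TAD and no resolvable insulation
  structure; 20-kb bins restore a realistic ~8 bins per TAD.
- The KD condition has a slightly shallower decay exponent (0.9 vs 1.0)
  in addition to its TAD merges, planting the long-range contact gain
  that the method is meant to detect; without it the KD-vs-WT decay
  comparison beyond TAD scale would be pure noise.
- Weak (variable) boundaries are planted as contact *leak across* the
  boundary (cross-boundary bin pairs multiplied by 1 + leak within 4
  bins), not as weaker within-TAD blocks, so the first-off-diagonal
  normalization stays balanced between conditions while insulation
  minima at variable boundaries are shallower.
- Enhanced-loop counts multiply the KD mean by the fold change and
  impaired-loop counts multiply the WT mean, so per-replicate totals
  stay balanced in expectation and total-count library normalization is
  composition-unbiased.
- The 20 target-gene promoter loops are planted at high depth with
  Poisson noise and an 8x fold (half enhanced, half impaired): target
  recovery is meant to test the integration logic end to end, not the
  borderline power of the differential test, which is assessed
  separately by the calibration/power study.
- H3K27ac signal contains three planted tiers: scattered switch sites
  with a modest KD gain (0.4 log2 units), 20 quiet "hotspot" clusters
  that activate ~7-fold in KD (new super-enhancers), and 12 stable
  clusters — three of them very strong — that pin the top of the
  signal-rank curve identically in both conditions, keeping the
  rescaled slope-1 cutoff comparable between WT and KD.

What the generator does **not** emulate: genome sequence content,
replication/mappability artifacts, matrix balancing (ICE), trans
contacts, realistic anchor annotation density (most simulated loop
anchors fall outside the promoter/enhancer sets, so PP/PE/EE labels
cover only a minority of loops), and correlated noise between factors.
Passing the planted-recovery tests therefore demonstrates that the
implementations are correct and calibrated under their own model
assumptions, not that real data meet those assumptions.

## Problem sizes and runtime

The default test-and-acceptance scale — a 20-Mb chromosome, 1000 bins,
1000 sites, ~1000 loops, 200 genes, 1000 permutations, 200 null runs and
100 power-study runs for the loop test — was chosen so the full suite
and the acceptance script each complete in well under a minute of
compute per stage on a single core.

## Known limitations

- The stable/variable boundary rule uses region midpoints; analyses that
  anchored the 10-kb rule on edges or overlap would shift counts.
- The common loop dispersion is a deliberate bias/variance trade-off;
  with >= 4 replicates per condition a tagwise (per-loop, moderated)
  dispersion would be preferable.
- `merge_coverage = 0.8` separating merges from large shifts, the
  self-ligation rule (anchor gap smaller than one anchor width), and the
  promoter width are conventions, not derived quantities; all are
  arguments.
- The permutation null preserves site lengths and chromosome assignment
  but not local covariates (GC, mappability); enrichment against
  features that track such covariates will be anti-conservative on real
  data.
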