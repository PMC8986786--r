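# loopswitch

Downstream 3D-genome analysis of cohesin STAG-paralog switching.

STAG2, a core cohesin subunit, is recurrently inactivated in melanoma and
other cancers. When STAG2 is depleted, its paralog STAG1 takes over a
subset of the vacated cohesin sites, and the genome's folding changes
with it: TADs enlarge, long-range contact probability rises, and
H3K27ac-associated enhancer–promoter loops are rewired. `loopswitch`
implements the downstream analyses that quantify these effects from
standard upstream-caller outputs (peak sets, TAD calls, binned contact
matrices, HiChIP loop tables, differential-expression tables), for
computational biologists studying cohesin perturbations — no alignment,
peak calling or loop calling is performed here.

## What it computes

- **Switch classification** — per-site signal change
  Δ = log₂((KD + ε)/(WT + ε)); k-means (k = 2) on ΔSTAG1 at lost-STAG2
  sites separates *switch* from *non-switch* sites; the degree of switch
  D = ΔSTAG1 + ΔSTAG2 measures over-/under-compensation. Permutation
  tests (uniform per-chromosome re-placement, 1000 permutations,
  add-one empirical p) score switch-site enrichment in genomic features.
- **TAD dynamics** — boundary regions (edges ± 10 kb, merged when
  overlapping), stable vs variable boundaries (midpoints within 10 kb),
  expanded / shrinked / merged / new-boundary / shifted TAD changes, and
  Mann–Whitney TAD-size comparisons.
- **Contact metrics** — contact-probability decay P(s) normalized to the
  first off-diagonal (P(1) = 1, averaged across chromosomes), a
  compartment-stratified A-A/A-B/B-B variant, and Crane-style sliding
  square insulation scores.
- **Differential loops** — after self-ligation, caller-FDR and
  strong-vs-zero replicate filters, per-loop over-dispersed Poisson GLM
  with log library-size offsets (common pooled dispersion, floored at 1),
  BH-corrected Wald tests, enhanced/impaired classes, PP/PE/EE anchor
  types and within/across-TAD labels.
- **Super-enhancers** — 12.5-kb stitching of H3K27ac peaks, slope-1
  cutoff on the min-max-rescaled signal-rank curve, and
  gained/lost/maintained comparison between conditions.
- **Direct targets** — genes that are differentially expressed, lose
  STAG2 at their promoter, and sit at a differential-loop anchor; plus
  the covariate-adjusted Spearman correlation used for cohort-style
  validation.
- **Synthetic data** — `generate_scenario()` builds a complete paired
  WT/KD bundle with planted ground truth (switch labels, boundary moves,
  loop classes, target genes) on a 20-Mb toy chromosome, so the whole
  pipeline is testable without downloads.

## Worked example

The analysis is organised as numbered drivers over the package API:

```sh
Rscript analysis/01_simulate.R 1        # build the synthetic study
Rscript analysis/02_switch_binding.R
Rscript analysis/03_tad_dynamics.R
Rscript analysis/04_contact_metrics.R
Rscript analysis/05_loops_superenhancers.R
Rscript analysis/06_target_integration.R
```

Stage 2 prints, for seed 1:

```
400/1000 sites classified as switch; accuracy vs planted truth 0.990
H3K27ac gain: switch mean 0.92 vs non-switch 0.01 (p = 2.92e-83)
  switch sites vs tad_boundaries ratio 1.71  p_enrich 0.0010  p_deplete 1.0000
  switch sites vs tad_domains    ratio 0.97  p_enrich 0.9171  p_deplete 0.1119
```

meaning: k-means recovered 99% of the planted switch labels, classified
switch sites gained ~0.9 log₂ units of H3K27ac upon knockdown while
non-switch sites did not, and switch sites are 1.7× enriched at TAD
boundaries (empirical p = 0.001) but not in TAD interiors. Later stages
report, in the same style, the stable/variable boundary split, the
KD-over-WT contact-decay gain at long range, the enhanced/impaired loop
calls with their planted-truth sensitivity and false discovery
proportion, the longer median length of enhanced loops, the
gained/lost/maintained super-enhancer counts, and the exact recovery of
the 20 planted direct-target genes. Small result tables land in
`results/`, and the generated input bundle in `scratch/bundle/`.

Everything the drivers do is a plain function call — e.g.

```r
library(loopswitch)
b  <- generate_scenario(scenario_config(seed = 1), "scratch/bundle")
dl <- differential_loops(filter_loops(b$loops)$loops, fdr_threshold = 0.01)
table(dl$klass)
#>  enhanced  impaired unchanged
#>       109        94       817
```

`run_pipeline(pipeline_config("scratch/bundle", "out"))` executes all
stages in order and writes a machine-readable `summary.json`.

## Vignette

`vignettes/stag2-3d-genome-methods.Rmd` documents the models, the
parameter choices and their defaults, what the synthetic generator does
and does not emulate, and the package's numerical conventions.
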