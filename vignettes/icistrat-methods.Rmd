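---
title: "Methods: ex vivo anti-PD1 response stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ex vivo anti-PD1 response stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icistrat)
```

## The problem

Tumor histocultures keep fresh explant fragments of a resected tumor alive
for ~72 h with their immune microenvironment intact, so the response of an
individual patient's tumor to an immune checkpoint inhibitor (here anti-PD1,
with an optional anti-CTLA4 combination arm) can be read out *ex vivo*:
cytokine release into the medium (T-cell reinvigoration), histopathology and
viability (tumor cytotoxicity), flow cytometry (cell-type proportions),
NanoString-style mRNA counts, and multiplex-IHC cell coordinates (spatial
dynamics of cytotoxic T cells, CTLs, and regulatory T cells, Tregs).

`icistrat` implements the full analysis chain from raw per-arm readouts to
responder stratification, gene-expression signatures with clinical-style
validation, and spatial distance statistics — plus a synthetic-cohort
generator that states the world the analysis assumes, so every stage is
testable end-to-end with known ground truth.

## Normalization model

**Cytokines.** Each analyte's pg/ml series (T0, T24, T48, T72) is divided by
its own T0 value, removing between-arm differences in functional cell
content. The treated-vs-control fold change aggregates the T0-normalized
post-treatment values; because culture medium is replenished every 24 h, the
release is cumulative and the default aggregation is the **sum of
T24+T48+T72** (`"sum_T24_T72"`). The endpoint-only rule (`"T72_only"`) is
exposed in configuration; the source protocol does not state which rule
produced its figures, so both are first-class options and the choice is
recorded in every output header.

**Histology and viability.** Ratio fold changes treated/control. Tumor
content is re-oriented as `control/treated` so that *all* ten response
parameters share the single relevance rule "fold change > 1.2" (a decrease
in tumor content is a cytotoxicity signal). Comparisons with the 1.2
threshold are **strict**: a fold change of exactly 1.2 is not a relevant
change.

**Counts.** nSolver-style housekeeping normalization: each column is scaled
so the geometric mean of its housekeeping genes equals the cohort-wide mean
of those geometric means. A pseudocount of 0.5 is added before scaling so
zero counts survive a later log2 while perturbing typical count magnitudes
negligibly. The upstream vendor software's exact formula is unpublished;
geometric-mean equalization is the standard scheme for this platform.

**QC.** Samples with baseline tumor content below 10% are non-qualified
(strict: exactly 10% qualifies). The PD-L1 combined positive score is
`100 x positives / viable tumor cells`, capped at 100 as in clinical
practice.

## Stratification

The ten log2 fold changes (five cytokines — IFNg, IL10, TNFa, Perforin,
GranzymeB — tumor content, immune content, infiltration, cleaved caspase-3,
viability) are embedded in 2-D with t-SNE (perplexity 10, learning rate 100,
1000 iterations) and split into a responder cluster SC1 and the remainder
SC2 by 2-means; SC2 is subdivided by two boolean flags:

* **reinvigoration** — IFNg fold change > 1.2;
* **cytotoxicity** — any of tumor-content decrease, cleaved caspase-3,
  Perforin, GranzymeB fold change > 1.2 (OR semantics).

giving SC2a (both), SC2b (cytotoxicity only), SC2c (reinvigoration only) and
SC2d (neither — the non-responders). All eight (primary x flags)
combinations map to exactly one label.

Three implementation choices matter and were made for robustness, not to a
specific dataset:

1. **PCA initialization of t-SNE.** Random initialization scrambles the
   global arrangement of clusters, which makes any downstream 2-means split
   a coin flip between topologies. The first two principal components
   (rescaled to SD 1e-4, plus a tiny seeded jitter) are the default
   initialization of the field's reference implementations and preserve
   macro-structure. The seed remains part of the provenance.
2. **Step size during early exaggeration.** The gradient step is divided by
   the exaggeration factor (12) during the first 250 iterations. At cohort
   size (n = 55) the nominal learning rate of 100 applied to 12x-exaggerated
   attractive forces shatters the embedding into outliers; this scaling is
   the standard stabilization and leaves the advertised learning rate
   meaningful after the exaggeration phase.
3. **2-means as a constrained global optimum.** Every optimal 2-means
   partition is linearly separable, so on a 2-D embedding the global optimum
   is found exactly by enumerating projection directions and split points.
   Clusters must hold at least 3 samples — the same minimum the package's
   rank tests require per group — because the unconstrained optimum happily
   isolates a single embedding outlier, which is not a sub-cohort. The
   cluster with the higher mean IFNg log2 fold change is SC1 (ties: higher
   mean Perforin). Samples are processed in sorted-id order internally, so
   labels are invariant to input row order.

## Signatures

Differential expression is per-gene ordinary least squares of log2
normalized counts on a group indicator with a t-based Wald p (n-2 df) — a
stated simplification of the unpublished vendor model, recorded in all
provenance output. Gene filtering is strict unadjusted p < 0.05, matching
the source methodology (no multiple-testing correction). PCA on the
gene-standardized significant genes yields loadings (eigenvector x
sqrt(eigenvalue), the gene-component correlation); genes with loading > 0.7
enter the signature.

One deviation from a literal reading of the derivation: inside
`derive_signature()` the loading threshold is applied **signed**, after
orienting PC1 toward the responder group. The signature score (GES) is a
plain average of log2 counts, so selecting genes by |loading| would mix
responder-up genes with immunosuppression genes that are *higher in
non-responders*; the two sets cancel in the average and the signature loses
all discrimination (AUC drops to ~0.55 on the synthetic world). Signed
selection restores concordance ("higher score = responder"), which is also
the only orientation consistent with a survival split where higher scores
mean longer progression-free survival. The standalone
`pca_loading_select()` retains the absolute-value mode.

Validation follows the clinical chain: GES = mean log2 normalized counts
over the signature genes; ROC by the rank (Mann-Whitney) AUC with tie
correction; candidate cutoffs at midpoints between adjacent distinct scores;
the Youden cutoff is the smallest threshold maximizing
sensitivity + specificity - 1; membership in the "high" survival group is
score **strictly greater** than the cutoff. The Kaplan-Meier product-limit
curves are compared with the two-group log-rank (Mantel-Cox) test
(observed-vs-expected events over pooled event times, hypergeometric
variance, chi-square with 1 df).

Supporting statistics: Wilcoxon signed-rank (paired) and Mann-Whitney
(unpaired) with exact conditional distributions up to n = 25 per group
(computed by rank convolution, valid under ties) and tie-corrected normal
approximation beyond; Spearman correlation with exact permutation p for
n <= 9; row z-scores with the sample SD (n - 1), matching `scale()`;
Euclidean average-linkage hierarchical clustering.

## Spatial statistics

The pipeline ingests phenotype-labeled cell tables (µm coordinates, origin
at the field's top-left), not images. The panCK+ tumor region is the union
of disks of radius `r` (default 20 µm) around panCK cells; a CD8 cell's
distance to the region is `max(0, nearest panCK center - r)`, so infiltrated
cells contribute 0, and the per-sample statistic is the median. CTL-Treg
distance is nearest-neighbor (the proximity of the closest suppressor is the
biologically cited quantity). A treatment-induced shift is called by a
two-sided Mann-Whitney test on per-cell distances at alpha = 0.05, with the
direction from the median difference; the source colors such calls without
naming a test.

## The synthetic world

`cohort_config()` states the cohort the analysis assumes: 55 samples in
ground-truth classes R / M_a / M_b / M_c / NR with proportions 9/27/8/5/6
(the observed sub-cohort sizes), multiplicative lognormal noise with CV 0.1
on assay readouts, negative binomial counts (750 endogenous + 20
housekeeping genes, dispersion 0.1), and per-class treatment effects
(`default_effect_sizes()`).

Two properties of the defaults are deliberate:

* **Two clusters, not five.** The observed embedding separates *two*
  sub-cohorts; SC2a-d are defined by threshold flags within one cloud, not
  by their own positions. The four moderate/poor classes therefore share a
  common profile and differ only in the flag-relevant parameters (IFNg 1.6,
  cytotoxicity parameters 1.3-1.5), while R separates strongly on every
  axis (IFNg 8x, cytolytic proteins and caspase ~3x, tumor content halved,
  viability 0.65). An earlier draft that gave each class its own
  multi-parameter profile produced five separable blobs and made the
  primary split unstable — a misstatement of the world, since the source
  reports two.
* **Expectation contract.** Treated-arm expectations equal control-arm
  expectations times the configured effect; with noise off and all effects
  at 1 the treated readouts equal control exactly (shared baseline draws).
  With noise CV 0.1 the empirical mean fold change recovers the configured
  effect within Monte-Carlo error.

Cells are placed with a one-disk tumor nest (radius 150 µm in a 1 mm field);
CD8 and FoxP3 cells sit at exponential radial distances outside the nest
boundary (means 120 / 100 µm), and treatment shrinks the mean CD8 distance
by the homing shift (40 µm, fully in R, half in M_a, none otherwise). The
combination arm depletes Tregs and disperses them for the moderate
responders. Survival records are exponential with log hazard linear in the
*centered* GES score (centering keeps the baseline hazard interpretable at
the mean score; GES values live around 6-8, so an uncentered slope of
practical magnitude drives the hazard to zero).

The replicate-arm equivalence simulation draws fragments with between-
fragment lognormal heterogeneity (CV 0.40, a realistic between-fragment
spread of tumor content; the trend along the cutting axis is scaled by the
same CV so homogeneous fragments give exactly zero arm variation), deals
them into arms round-robin (every cross-section represented in every arm),
and reports the across-arm CV% of arm means against replicate counts
3/5/7/10. At the defaults the 7-replicate arms sit near 15% CV, inside the
20% design criterion, and CV is non-increasing in the replicate count.

What the generator does **not** emulate: batch and plate effects, assay
backgrounds and detection limits, gene-gene correlation beyond the two
responsive blocks, irregular tumor-nest shapes, segmentation errors, or
missing modalities. A green recovery test therefore establishes that the
pipeline is correct on its stated assumptions — not that those assumptions
exhaust real histoculture data.

## Numerical conventions

* Strict inequalities wherever the source text says "more than": relevance
  1.2, DE alpha 0.05, loading 0.7, QC "less than 10%", high-survival group
  "score > cutoff".
* Pseudocounts: 0.5 on counts before log2/normalization; 0 in `ges_score()`
  (normalized counts are already positive), so "counts 4 and 16 give GES 3"
  holds exactly.
* Youden ties break to the smallest qualifying threshold; z-scores use the
  sample SD; signed-rank/rank-sum two-sided p = min(1, 2 x min(lower,
  upper)) on the exact distribution.
* All generators and the embedding are seeded; seeds, configuration hashes
  and per-stage digests are written to `provenance.json` on every pipeline
  run.

## Known limitations

* The DE model is a deliberate simplification; gene lists derived from real
  data with the vendor's pipeline will not be reproduced verbatim.
* The primary split assumes the responder cluster is the most separated
  structure in the embedding; cohorts without a distinct responder group
  trigger a low-separation warning rather than a refusal.
* Spearman exact p enumerates up to 9! permutations; beyond n = 9 the t
  approximation is used.
* The external-validation loader reads uncompressed series-matrix files
  only, and gene-symbol alias resolution is the caller's responsibility.
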