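# icistrat

Ex vivo anti-PD1 response stratification for tumor histocultures.

## What this is for

Short-term histocultures of fresh tumor explants preserve the tumor
microenvironment well enough to read a patient's response to immune
checkpoint blockade *ex vivo*. A treated arm (anti-PD1, optionally plus
anti-CTLA4) is compared with an IgG control arm of the same tumor across
several modalities: cytokine release time courses, histopathology scores,
viability fluorescence, flow-cytometry proportions, NanoString-style mRNA
counts, and multiplex-IHC cell coordinates.

`icistrat` implements the complete analysis for people building or
evaluating such platforms:

* **Normalization** — T0-normalized cytokine series; treated-vs-control
  fold changes for the ten response parameters (IFNg, IL10, TNFa, Perforin,
  GranzymeB release; tumor content, oriented as `control/treated` so a
  decrease reads as cytotoxicity; immune content; infiltration; cleaved
  caspase-3; viability); housekeeping geometric-mean count normalization;
  baseline tumor-content QC (strict < 10% excluded); PD-L1 CPS.
* **Stratification** — seeded t-SNE (perplexity 10, learning rate 100,
  1000 iterations) of the log2 fold-change matrix; 2-means SC1/SC2 primary
  split (SC1 = cluster with higher mean IFNg); rule-based sub-cohorts from
  two flags at the strict fold-change threshold **> 1.2**:

  | label | reinvigoration (IFNg) | cytotoxicity (tumor dec. / caspase / Perforin / GranzymeB) |
  |-------|----------------------|------------------------------------------------------------|
  | SC2a  | yes                  | yes |
  | SC2b  | no                   | yes |
  | SC2c  | yes                  | no  |
  | SC2d  | no                   | no  |

* **Signatures** — Wald differential expression (per-gene OLS on log2
  normalized counts), strict p < 0.05 filter, PC1 loading > 0.7 selection,
  panel intersection, GES = mean log2 counts, ROC with Youden cutoff, and
  Kaplan-Meier / log-rank survival split at the cutoff.
* **Spatial** — panCK union-of-disks tumor region (r = 20 µm), per-CD8
  distances to the region, nearest-Treg distances, Mann-Whitney shift calls.
* **Synthetic cohorts** — a seeded generator with ground-truth response
  classes (default proportions 9/27/8/5/6 of 55), class-dependent effect
  sizes on every modality, lognormal assay noise, NB counts, and a
  replicate-arm equivalence simulation (round-robin plating, across-arm CV%
  versus 3/5/7/10 replicates).

## Worked example

```r
library(icistrat)

coh    <- generate_cohort(cohort_config(seed = 42))   # 55 synthetic samples
fcm    <- build_fc_matrix(coh)                        # 10-parameter log2 FC
labels <- stratify_cohort(fcm, tsne_params(seed = 42))
table(labels$sub)
#>  SC1 SC2a SC2b SC2c SC2d
#>    9   27   10    5    4
mean(class_to_subcohort()[true_class(coh)[labels$sample_id]] == labels$sub)
#> [1] 0.9636364
```

9 of 55 samples land in the responder sub-cohort SC1 and 96% of all labels
match the generator's hidden ground truth. Deriving and validating the
baseline signature (control-arm SC1 vs SC2d):

```r
cm  <- normalize_counts(attr(coh, "counts"))
ctl <- function(sub) cm$columns$column_id[cm$columns$arm == "Control" &
         cm$columns$sample_id %in% labels$sample_id[labels$sub == sub]]
sig <- derive_signature(cm, ctl("SC2d"), ctl("SC1"), name = "baseline")
sig
#> <gene_signature> baseline: 18 genes (71 significant -> 18 by PC1 loading > 0.7)

ids  <- cm$columns$sample_id[cm$columns$arm == "Control"]
keep <- ids %in% labels$sample_id[labels$sub %in% c("SC1", "SC2d")]
roc  <- roc_youden(sig$scores[cm$columns$arm == "Control"][keep],
                   as.integer(ids[keep] %in% labels$sample_id[labels$sub == "SC1"]))
roc
#> <roc_result> AUC 1.000; Youden cutoff 8.045 (J = 1.000)

rec <- generate_survival(sig$scores[cm$columns$arm == "Control"],
                         hazard_slope = -1.5, seed = 42)
km_logrank(rec, roc$youden_cutoff)
#> <km_logrank> groups high/low (n = 31/24); chi-square = 25.49, p = 4.446e-07
```

The derived signature separates responders from non-responders perfectly on
this synthetic world (AUC 1.0) and its Youden cutoff splits simulated
progression-free survival with log-rank p ~ 4e-7. The replicate-arm
equivalence simulation reproduces the design criterion that seven replicates
per arm keep across-arm variation under 20% CV:

```r
simulate_arm_equivalence(arm_equivalence_config(seed = 42))
#>   replicate_count cv_tumor_content cv_proliferating
#> 1               3         23.09121         22.63815
#> 2               5         17.40667         17.96039
#> 3               7         14.37736         14.05729
#> 4              10         11.60205         12.13931
```

The whole chain (simulate, QC, fold changes, stratify, both signature
chains, spatial summaries, provenance) is one call:

```r
res <- run_pipeline(run_config(out_dir = "run1", seed = 42))
```

or from a shell, with subcommands `simulate`, `stratify`,
`signature derive|validate`, `spatial`, `run-all`:

```sh
Rscript -e 'icistrat::run_cli()' run-all --out run1 --seed 42
```

## Documentation

Function-level documentation lives in the roxygen comments in `R/`; the
methods vignette (`vignettes/icistrat-methods.Rmd`) explains the models,
parameter defaults and units, what the synthetic generator does and does not
emulate, and every numerical convention (strict thresholds, pseudocounts,
tie-breaks).
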