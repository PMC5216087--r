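# lipidbreed

Supervised analysis of untargeted plasma lipidomics for discriminating
animal breeds under uncontrolled, owner-chosen diets.

Plasma lipidomes of home-based dogs carry two entangled signals: breed
physiology and habitual diet. When breeds cluster by the protein source
they are fed, the dominant axis of any supervised model is dietary, and
genuine inter-breed lipid differences are masked. `lipidbreed`
implements the complete workflow for untangling the two from a
peak-picked UHPLC-HRMS feature matrix (samples × accurate-mass
features):

* **Binning** of accurate masses to 0.01 amu half-open bins, with the
  intensity-weighted accurate m/z retained for annotation.
* **PC-LDA** — linear discriminant analysis on principal-component
  scores, with separation eigenvalues (Tw) from the generalized scatter
  eigenproblem `Sb v = λ Sw v`.
* **Bootstrapped random-forest classification** — 100 stratified
  2/3–1/3 splits, 1000 trees each; scored by the classification margin
  (vote fraction for the true class minus the best other class), AUC
  and accuracy; models are *adequate* when margin > 0.2 and AUC and/or
  ACC > 0.8.
* **Feature ranking** — RFIS (out-of-split permutation importance:
  the mean decrease in held-out accuracy when a feature is permuted),
  orientation-folded univariate AUC, and Welch t-tests with
  Benjamini–Hochberg FDR; |r| > 0.8 single-linkage correlation
  clusters group adducts, isotopologues and co-varying partners.
* **Confounder filtering** — iteratively lower the RFIS cutoff for the
  diet-confounded meta-class comparison, expanding each removal set by
  correlated features, until the meta-class model collapses
  (margin ≤ 0.2); return the filtered matrix and the full trajectory.
* **Discovery** — all-pairs breed models, an adequacy screen
  (≥6 adequate comparisons), and breed-unique signals: features
  clearing RFIS > 0.002 and p < 0.05 in every adequate comparison of
  one breed with consistent direction, shared by no other breed.
* **Annotation** — elemental-formula algebra with IUPAC monoisotopic
  masses and electron-mass correction; adduct and 13C-isotopologue
  rules; ppm matching; diagnostic head-group fragments (m/z 184.0733
  phosphocholine, −59.0735 trimethylamine, −141.0191
  phosphoethanolamine, −185.0089 phosphoserine losses).
* **Synthetic data** — a generator that emulates the statistical
  structure this analysis assumes (breed panel of 7–12 animals across
  9 breeds, 2500 features, correlated adduct clusters, a diet axis
  partially collinear with breed, a second breed axis, breed-unique
  features) together with a ground-truth ledger for parameter-recovery
  validation.

## Worked example

Annotate an observed ion and run the meta-class model on synthetic
data:

```r
library(lipidbreed)

adduct_mz("C39H78NO8P", adduct_rules()[["[M+H]1+"]])
#> [1] 720.5538

ppm_match(720.5525, lipid_formula_table(), window_ppm = 5)[,
  c("putative_name", "rule", "theoretical_mz", "ppm_error")]
#>   putative_name    rule theoretical_mz ppm_error
#> 1      PC(31:0) [M+H]1+       720.5538 -1.778556

sim <- generate_lipidome(synthetic_config(effect_log2fc = 2, seed = 1))
sim
#> lipidome_sim: 96 samples, 9 breeds, 2500 features (seed 1)

lg   <- log2_transform(sim$matrix)
md   <- sim$metadata
mlab <- ifelse(md$breed %in% sim$truth$group1_breeds, "group1", "group2")
mlab[md$breed == sim$truth$mixed_breed] <- NA   # mixed-diet breed omitted
keep <- which(!is.na(mlab))

sch <- bootstrap_scheme(n_bootstraps = 25, ntree = 200, seed = 1)
rf  <- rf_bootstrap_classify(subset_matrix(lg, samples = keep),
                             mlab[keep], sch,
                             comparison = "Ch+Da+Gh vs Be+CS+GR+GS+Ma")
rf
#> Ch+Da+Gh vs Be+CS+GR+GS+Ma: margin 0.603, AUC 0.926, ACC 0.917
#> (25 bootstraps) -> adequate

pc_lda(subset_matrix(lg, samples = keep), mlab[keep])
#> pc_lda: 74 PCs (95.3% variance), Tw = 18.085
```

The meta-class model is adequate (margin 0.603 ≫ 0.2) — but it is
driven by the planted diet confounder. The full pipeline ranks the
explanatory signals, filters them (with their |r| > 0.8 satellites)
until this model collapses, then rescans all 36 breed pairs on the
cleaned matrix and reports breed-unique signals with annotations:

```r
cfg <- run_config(seed = 1, n_bootstraps = 25, ntree = 200,
                  synthetic = list(effect_log2fc = 2))
man <- run_pipeline(cfg, "results/run1")
```

Every stage output (`matrix.tsv`, `ranked.tsv`, `filter_report.json`,
`grid.tsv`, `unique_signals.tsv`, `annotations.tsv`, …) lands in the
output directory with a `manifest.json` recording file checksums and
every threshold in force.

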