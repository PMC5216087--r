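---
title: "Discriminating breeds from plasma lipidomes under uncontrolled diets: models and methods"
author: "lipidbreed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating breeds from plasma lipidomes under uncontrolled diets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Untargeted UHPLC-HRMS lipidomics of plasma from client-owned animals
confounds two sources of variance that a breed study wants to separate:
genuine breed physiology, and habitual diet. When breeds cluster by the
protein source their owners feed (chicken versus red meat), the dominant
discriminant axis of a supervised model reflects the kitchen, not the
genome. `lipidbreed` implements a complete workflow for this situation:

1. accurate-mass binning of a peak-picked feature matrix (0.01 amu);
2. PC-LDA visualization with separation eigenvalues (Tw) and
   bootstrapped random-forest (RF) classification scored by margin, AUC
   and accuracy;
3. per-feature explanatory-signal ranking (RFIS, univariate AUC, Welch
   t-test with Benjamini-Hochberg FDR) and |r| > 0.8 correlation
   clustering;
4. iterative removal of diet-confounded signals until the confounded
   meta-class model collapses;
5. all-pairs breed modelling on the filtered matrix with breed-unique
   signal discovery;
6. rule-based accurate-mass annotation (adducts, isotopologues,
   head-group fragments).

Because raw data of this kind are rarely public, the package ships a
synthetic-data generator (`generate_lipidome()`) that reproduces the
statistical structure the analysis assumes together with a ground-truth
ledger, so every stage is validated by parameter recovery rather than by
eyeballing.

## Models and scores

**PC-LDA.** PCA on the mean-centred log2 matrix retains the smallest
number of components reaching 95% cumulative variance (capped at
n − g so the within-class scatter stays invertible). LDA then solves
`Sb v = λ Sw v` with Sw, Sb the within- and between-class scatter sums.
The eigenvalues Tw quantify between-to-within separation along each
discriminant function; under a permutation null at n = 50 they stay
well below 0.5, while separable classes give Tw in the tens. A singular
Sw (degenerate inputs) is ridge-regularized with a logged epsilon.

**Bootstrapped RF classification.** All supervised scores come from
repeated stratified 2/3 train / 1/3 test splits (default 100 rounds)
with a fresh forest per round (default 1000 trees). Per test sample the
margin is the vote fraction for the true class minus the largest vote
fraction for any other class; AUC is the rank statistic of the vote
fractions; ACC is majority-vote accuracy. A model is *adequate* when
margin > 0.2 and AUC and/or ACC > 0.8.

Two forest settings depart from textbook defaults, both forced by the
regime p ≈ 2500 ≫ n ≈ 15–25 per comparison:

* *No tree-level bootstrap.* Resampling uncertainty is already carried
  by the outer 2/3–1/3 loop. An additional per-tree bootstrap of a
  10–16 sample training split leaves 1–4 distinct minority-class
  samples per tree, at which point hundreds of noise features separate
  the inbag perfectly and the forest degenerates to coin flips. Trees
  therefore see the full training split (`replace = FALSE`,
  `sample.fraction = 1`), with feature subsampling as the source of
  diversity. Vote leaves use `min.node.size = 1`, the classification
  standard.
* *n-adaptive candidate draw.* Classification forests draw the
  conventional mtry = sqrt(p) candidates per split, widened to p/3 when
  the training split falls below 30 samples. At a 9-16 sample training
  split, p x P(a noise feature separates the classes perfectly by
  chance) is of the same order as the number of genuinely informative
  features, and a sqrt(p) draw rarely even contains a real one; the
  wider draw restores the real features' chance of winning the split.
  At meta-class sizes (train around 56) chance separation is negligible
  and sqrt(p) behaves classically.
* *Ranking forests always draw mtry = p/3.* A feature can only
  register permutation importance if trees draw it; with sqrt(p) ≈ 50
  of 2500 most informative features are rarely seen and importances are
  sparse and noisy. The larger draw follows the random-forest
  variable-selection literature. Ranking trees subsample 3/4 of the
  training split so that a redundant block of co-varying signals shares
  credit across its members instead of concentrating it on one
  representative — a removal list must enumerate the whole block.

**RFIS.** The importance score is the mean decrease in classification
accuracy when a feature's values are permuted, estimated *out of
split*: forests are grown on the training two-thirds only and the
permutation is scored on the held-out third, averaged over the
bootstrap rounds. On meta-class comparisons (n ≈ 84) planted
explanatory signals score RFIS ≈ 0.003–0.03 and null features below
about 5e-4, which places the working thresholds (0.003 for meta-class
explanatory signals, 0.002 for pairwise discovery, down to 3e-4 for
confounder filtering) inside the dynamic range of the estimator.

**Ranking and clusters.** Welch's unequal-variance t-test is used
(vectorized over features; unit tests pin it to `stats::t.test` at
1e-12) with Benjamini–Hochberg adjustment; the univariate AUC is
orientation-folded to [0.5, 1]. Correlation clusters are the
single-linkage components of the |r| > 0.8 Pearson graph — the grouping
that captures chains of adducts, isotopologues and breakdown products
of one metabolite.

## The confounder filter

`filter_confounder()` walks a strictly decreasing RFIS cutoff schedule
(default log-uniform, 0.01 down to 1e-4; the documented heuristic
preset is 3e-4). At each cutoff the removal set is every feature whose
meta-class RFIS exceeds the cutoff, expanded once by all features
correlated at |r| > 0.8 with a directly removed feature (their isotopes,
adducts and co-varying partners). The meta-class RF is refit on the
reduced matrix; filtering stops at the first cutoff where the model is
no longer adequate — margin ≤ 0.2, the adequacy floor — which
operationalizes "the model collapsed". Tw is logged along the
trajectory but is not the stopping statistic, because no published
threshold exists for it. The filtered matrix is a column subset; no
intensity is modified.

## Unique-signal discovery

`pairwise_grid()` scores every unordered breed pair. Breeds with fewer
than 6 adequate comparisons are not pursued (the adequacy screen).
For each remaining breed, candidate features must clear RFIS > 0.002
and p < 0.05 *in every adequate comparison involving that breed*, with
a consistent direction relative to the focal breed (sign of the
log-intensity mean difference). A candidate shared by two breeds is a
common discriminating series, not breed-unique, and is discarded for
both. A `strict_all` flag intersects over all comparisons instead of
the adequate ones only; the default treats inadequate models as
uninformative.

## The synthetic-data generator

`synthetic_config()` defaults encode the emulated study: nine breeds
(Be 12, Ch 7, CS 12, Da 8, GR 12, Gh 12, GS 12, LR 12, Ma 9; 96
plasma profiles), 2500 accurate-mass features per ionisation mode, m/z
drawn from the lipid-relevant 200–1000 window with RT 60–600 s.
The intensity model on the log2 scale is

```
log2 I[s, f] = baseline(f) + breed effect + diet effect
             + shared latent(cluster or family) + N(0, noise_sd)
```

* **Baselines** are uniform on log2 10–20 (~3 orders of magnitude of
  dynamic range, standard for untargeted LC-MS).
* **Adduct/isotope clusters.** 300 base metabolites spawn 1–3
  satellites each (isotopologues at +1.00335 m/z with lower intensity,
  or NH4/Na adducts at +17.0265/+21.9819) sharing a per-sample latent
  of SD 2.5 × noise_sd, which puts within-cluster Pearson |r| near
  0.86.
* **Diet axis.** 60 base metabolites (plus their satellites, ≈134
  features) are elevated in red-meat eaters by `effect_log2fc`. They
  are grouped into 10 covarying "pathway" families sharing a weaker
  per-sample latent (SD = noise_sd): chemically distinct diet-derived
  lipids (triglyceride and phosphatidylcholine series) do co-vary in
  real profiles, which is exactly why the filter's correlated-feature
  expansion is meaningful. Group-1 breeds (Ch, Da, Gh) eat chicken
  with probability 0.9, the others red meat with probability 0.9, and
  LR is split 50/50 — the diet confounder is partially collinear with
  breed, with one breed mixed.
* **Second axis.** 18 base metabolites (≈40 features, 5 families) are
  reduced in Ch, Da, Ma and GR: a deliberately smaller signal family
  than the diet axis, so that once diet signals are removed this axis
  dominates the PC-LDA.
* **Breed-unique features.** Singleton features for Ch (5 decreased),
  GR (7 elevated) and Gh (1 decreased), mirroring the discovery
  targets.
* `noise_sd = 0.5` log2 units (~35–40% CV), `effect_log2fc = 1` by
  default; recovery experiments use 2.

What the generator does **not** emulate: chromatographic peak shapes,
retention-time drift, batch effects, missingness mechanisms,
heteroscedastic intensity-dependent noise, or breed-specific variance
differences. Passing recovery tests therefore demonstrate that the
pipeline's logic is sound under its stated assumptions, not that any
particular real dataset will behave as cleanly.

## Validation experiments and problem sizes

The test suite validates the workflow end to end at these sizes,
chosen so the full suite runs on a single CPU in well under half an
hour:

* *Mass algebra*: 1000 random compositions (C0–60 H0–120 N0–3 O0–10
  P0–2 S0–2) against an independent per-atom oracle with a separately
  sourced constants table (1e-6 relative), plus exact isotopologue and
  ammonium/proton spacing invariants, plus the eight published ion m/z
  values to ±1e-4.
* *Classification null*: permuted labels on a 24-sample pair of the
  default synthetic data, 100 bootstraps of 1000 trees, 10 seeds: mean
  margin within ±0.1, zero adequate models.
* *Recovery*: the full filter → grid → discovery chain on the default
  configuration at `effect_log2fc = 2`, 10 seeds, with 25 bootstraps of
  200 trees per forest. Averaged over seeds the filter removes ≥90% of
  planted diet features while retaining ≥90% of planted unique
  features, and discovery attains sensitivity ≥0.8 at FDR ≤0.2. The
  single planted Gh-unique feature is structurally unrecoverable at
  these settings — one informative feature cannot make Gh's pairwise
  models adequate — so the sensitivity ceiling is 12/13; this is the
  expected behaviour of the adequacy screen, not an estimator failure.
* *PC-LDA*: agreement with a dense generalized-eigenproblem oracle to
  1e-8 on ≤10-feature instances; permutation-null Tw below 0.5 at
  n = 50 (40 replicates, 3 MC standard errors).
* *FDR null*: on 20 pure-noise matrices the fraction of q < 0.05
  features stays within binomial noise of the nominal level.

## Numerical choices and degenerate inputs

* Bins are half-open intervals `[k·width, (k+1)·width)` anchored at
  zero; co-binned intensities are summed and the intensity-weighted
  mean m/z is kept alongside the bin label so annotation can use
  accurate masses from the un-binned view. A small epsilon keeps
  values sitting exactly on a lower edge in their own bin, making
  binning idempotent.
* Feature names round half to even (`M100T10` for m/z 100.5, RT 10.4).
* Zero-variance features get p = 1 and RFIS 0 and are flagged;
  constant features are excluded from correlation graphs with a
  warning.
* Ranking ties (equal RFIS) break by ascending p, then name.
* Monoisotopic masses are IUPAC values with mandatory electron-mass
  correction; the 13C−12C spacing is 1.00335483507 Da.
* Per-stage seeds in `run_pipeline()` derive from the master seed as
  `(seed · 101 + stage index) mod (2^31 − 1)`, so stages are
  independently reproducible.

## Known limitations

* The adequacy thresholds (margin 0.2, AUC/ACC 0.8) and RFIS presets
  (0.003 / 0.002 / 3e-4) are protocol constants, not estimated
  quantities; their calibration to other instruments or designs is the
  user's responsibility.
* Permutation importance of strongly redundant features is diluted by
  ensemble compensation; the ranking spreads credit across a block,
  so absolute RFIS values of cluster members should be read jointly
  (the correlation-cluster annotation exists for this reason).
* Breeds represented by very few animals (n ≈ 7) sit at the edge of
  what the pairwise models resolve; discovery for such breeds depends
  on at least one further breed sharing none of their signals.
* Annotation is putative (MSI level 2 with fragment evidence, level 3
  without); the bundled composition table is deliberately small and
  offline, and makes no chemical-identity claims.
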