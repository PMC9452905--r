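---
title: "Discovering ICB response signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering ICB response signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbsig)
```

## The problem

Immune checkpoint blockade (ICB) helps only a minority of clear cell renal
cell carcinoma (ccRCC) patients, and RECIST response (responder R vs
nonresponder NR) is only known after treatment. `icbsig` implements a
single-cell-informed workflow for building a pretreatment transcriptomic
predictor of nonresponse:

1. **Marker statistics** -- Wilcoxon rank-sum differential expression per
   cell subcluster with detection-rate (`min_pct = 0.1`) and fold-change
   (`|avg_log2FC| >= 0.25`) prefilters.
2. **Enrichment** -- hypergeometric over-representation of each
   subcluster's top-500 marker list against GMT collections (sets with
   fewer than 3 measured genes excluded; top 10 per collection at BH
   q < 0.05).
3. **Predictiveness screen** -- each enriched set becomes the gene panel of
   a nearest-centroid classifier evaluated by multiple random validation in
   a bulk ICB cohort; a DE list is called predictive when at least half of
   its enriched sets achieve ROC p < 0.05.
4. **Localization** -- single-sample gene-set variation scores place the
   predictive sets in the responsible subcluster.
5. **Candidate assembly** -- genes of the sets passing the BH-adjusted
   screen (union), intersected with per-subtype NR-vs-R fold-change gates
   and with the genes measured in the reference cohort.
6. **Cycle algorithm** -- greedy leave-one-out backward elimination: from a
   panel of k genes all k subsets of size k-1 are scored by validated AUC
   and the best survives, down to 3 genes; the signature is chosen from the
   trace.
7. **Validation** -- ROC/AUC with Welch t p-value and Wilson intervals,
   logistic conversion of prediction scores to nonresponse probabilities,
   and survival stratification (Kaplan-Meier / log-rank / maximally
   selected cutpoints / univariate Cox).

Every stage runs end-to-end on synthetic data with known ground truth, so
the whole chain is testable without access to patient-level cohorts.

## The classifier and its validation protocol

The classifier is deliberately simple: genes are standardized with
training-set means and SDs, each class is summarized by its centroid, and a
sample's continuous prediction score is

$$z = d(x, c_R) - d(x, c_{NR}),$$

the difference of Euclidean distances to the responder and nonresponder
centroids; larger z means closer to the nonresponder profile. Multiple
random validation repeats a stratified 2/3 train / 1/3 test split
(`n_rep = 100` by default), aggregates each sample's held-out scores by
their mean, and computes the ROC, midrank Mann-Whitney AUC (with a
stratified bootstrap percentile CI, 2,000 draws), Welch-t ROC p-value and
Youden-cutoff sensitivity/specificity with Wilson 95% intervals on the
aggregated scores.

Two properties of this protocol matter for interpretation:

* **The AUC is well calibrated.** Under label-free null data the AUC
  distribution is centered at 0.5 (checked by simulation in the test
  suite).
* **The Welch ROC p-value is anti-conservative under the null.** The
  aggregated per-sample scores are not independent -- every sample helps
  train the models that score the others -- and the Welch test ignores that
  correlation. In our null simulations 100 random decoy panels reject at
  roughly 15-20% instead of the nominal 5%, and the inflation does not
  vanish with cohort size. The screen therefore treats the ROC p as a
  *ranking* statistic (planted predictive sets beat decoys by many orders
  of magnitude), and any absolute calibration claim about it should be
  avoided. We keep the test because it is the convention of the
  nearest-centroid validation protocol this package emulates; the
  limitation is inherent to that convention, not an implementation detail.

## The cycle algorithm and signature selection

Within one elimination cycle every leave-one-out subset is evaluated by
`multiple_random_validation` under a deterministic seed derived from
`(seed, iteration, removed_gene)`, so a full trace is exactly reproducible
and insensitive to candidate input order (ties remove the
lexicographically smallest gene). A 209-gene candidate list costs
209 + 208 + ... + 4 = 21,945 validator runs; the split/score core is
implemented in C++ with its own counter-based RNG to keep that tractable
(a few tens of seconds on one CPU).

The elimination validator uses `n_rep = 50` splits per subset -- half the
reporting default -- because elimination only needs the *ordering* of
subset AUCs, and 50 splits keeps the full trace inside a desktop compute
budget. Each subset drawing independent splits has a side effect worth
knowing: the recorded per-cycle best AUC is a maximum over k noisy
evaluations, so it is upward-biased, and more so in early cycles (large k)
than late ones. Consequently the trace maximum tends to sit at larger
panels than the noise-free optimum, and the `delta` selection rule (the
smallest panel within `delta = 0.01` of the trace maximum) inherits that
noise: across repeated synthetic cohorts the selected panel size varies
substantially (roughly 6-30 genes under the default conditions), and with
it the fraction of truly informative genes in the panel. A `target_size`
override is provided for replicating a fixed published panel size.

## The synthetic ground truth

`generate_single_cell_dataset` draws negative-binomial counts (per-gene
dispersion 0.5) with log-normal baseline means; subcluster 1 carries a
planted *resistance* program and subcluster 2 a *response* program
(`n_marker_genes = 30` genes each, 4-fold up at the default
`marker_effect = 2` on the log2 scale). Cells from nonresponder patients
are over-represented in the resistance subcluster by
`abundance_shift = 1.5` logits. `generate_bulk_cohort` mixes the subtype
mean profiles with per-sample Dirichlet weights (the resistance fraction
logit-shifted for NR), adds Gaussian noise (`noise_sd = 0.3`) on the log
scale, and draws exponential survival with log-hazard
`hazard_coef = 0.7` per SD of the true resistance fraction, censored by
independent uniform times calibrated to `censor_rate = 0.2`. The default
cohort size (172 with 39 responders) mirrors a realistic integrated ICB
cohort; pipeline runs use 150 samples.

What this emulates -- and what it does not: the generator reproduces the
*statistical* structure the workflow relies on (subcluster marker programs,
outcome-linked subtype abundance, survival linked to the same factor). It
does not model doublets, ambient RNA, batch effects, compositional
interactions between cell types, or any biology beyond a single latent
abundance factor; all planted signal genes are correlated through that one
factor, which makes panel-level AUC saturate once a handful of signal genes
are present. Passing tests therefore demonstrate internal correctness and
recoverability under this model, not clinical performance.

## Numerical choices and edge cases

* Log-normalization uses a 10,000 scale factor and natural-log `log1p`;
  fold changes de-log (`expm1`), average, add a pseudocount of 1 and take
  log2 -- the modern single-cell convention -- so results are insensitive
  to the normalization log base.
* The Wilcoxon test uses the exact null distribution for
  `n1 + n2 <= 12` without ties, otherwise the normal approximation with
  tie and continuity corrections. Cluster markers are Bonferroni-adjusted
  (the emulated toolkit's default); everything else uses
  Benjamini-Hochberg.
* Over-representation uses the *measured* genes as the universe, not the
  collection's own gene space; set sizes are counted after restriction to
  that universe.
* The gene-set variation scorer implements the Gaussian-kernel branch only
  (bandwidth = per-gene SD/4), symmetric rank statistics, and the
  max-positive-plus-min-negative run statistic by default (`"absmax"`
  available); hit/miss increments are normalized to unit mass so scores
  are bounded in [-1, 1] without further scaling. Constant genes are
  excluded from ranking with a warning. Scores are invariant to increasing
  *affine* transforms of a gene's row; general monotone transforms alter
  the kernel CDF (bandwidth is variance-based), which is a known departure
  from pure rank methods.
* Preranked GSEA normalizes by the sign-matched mean of gene-label
  permutation scores (classic NES) with `p >= 1/(n_perm + 1)` enforced.
* Survival: Kaplan-Meier and Cox regression are delegated to the survival
  package (Breslow ties, so the score test at beta = 0 matches the
  log-rank chi-square); the log-rank statistic itself is computed in-house
  because the maximally-selected-cutpoint scan needs the signed
  standardized statistic at every candidate cutpoint. Median
  dichotomization sends ties to the "low" group; `maxstat` requires at
  least `minprop = 0.1` of samples on each side and its p-value is flagged
  as anti-conservative (the cutpoint maximizes the statistic). Monotone
  Cox likelihoods are flagged and the coefficient clipped; complete
  logistic separation likewise.
* NE (not evaluable) samples are excluded from classification but retained
  in survival analyses.

## Problem sizes used by the tests and the acceptance script

Module tests run on a 300-gene / 240-cell / 100-sample fixture; the
end-to-end pipeline test uses 250 genes, 220 cells and 70 samples; the
recovery analysis uses 150-sample cohorts with 30 planted signal genes
among 209 candidates (ten independent cohort draws), elimination at 50
splits per subset, and validation at 100 splits; null calibration uses
5,000 null genes for DE uniformity, 200 runs for AUC centering, 100 decoy
sets for the screen rate and 1,000 simulations for log-rank uniformity.
These sizes were chosen so that each statistical assertion has stable power
on a single desktop CPU.

## Known limitations

* The Welch ROC p inflation under the null, and the noise-driven
  variability of the delta-rule panel size, are both inherited from the
  emulated protocol (see above); under the default study conditions the
  selected panel contains a planted-gene majority and reaches held-out
  AUC >= 0.85 in only about 6 of 10 cohort draws, with the failures being
  either decoy-rich large panels or signal-poor small ones.
* Elimination AUCs are evaluated on the same cohort later used for the
  headline validation (resubstitution optimism), replicating the emulated
  workflow; use the reported *held-out* AUC for honest performance.
* Clustering/integration is out of scope: subcluster labels are inputs.
* The screen's BH family spans all (list, set) records of one screen;
  duplicated sets across lists share one validation result by design.
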