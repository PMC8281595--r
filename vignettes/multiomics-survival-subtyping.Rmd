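---
title: "Ensemble survival subtyping from multi-omics data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble survival subtyping from multi-omics data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsurv)
```

## The problem

Tumor cohorts profiled on several molecular layers — mRNA expression, miRNA
expression, DNA methylation — often hide subpopulations whose molecular
differences translate into different survival. `omicsurv` discovers such
*survival-ordered molecular subtypes* in a semi-supervised way: survival
information guides which latent molecular features are worth clustering on,
but the subtypes themselves come from unsupervised mixture modeling. A
supervised classifier then projects the subtypes onto new patients, including
patients with only a subset of the omics measured, and onto entirely
different cohorts sharing only part of the feature universe.

## The pipeline, step by step

One *submodel* runs the following stages, per omic layer:

1. **Rank/distance normalization.** The 100 highest-variance training
   features are kept (`top_k`, ties broken by feature id). Within each
   sample, the kept features are replaced by their within-sample rank divided
   by `top_k`, so the largest measurement scores 1. The Pearson correlation
   `r` between the rank profiles of every pair of samples is mapped to a
   distance `d = 1 - r`, and each sample's distances to the `n` training
   samples are rank-normalized to `[0, 1]` (closest sample scores 1, farthest
   0). Every sample — training or new, whatever its platform or feature
   subset — is thereby described by the same `n` "distance features". Two
   choices here are ours, because "distance" and tie handling are otherwise
   underdetermined: `1 - r` preserves correlation order, and a sample's
   self-distance (0) is included, taking the top score; ties are
   average-ranked, then rescaled so each row spans exactly `[0, 1]`.

2. **Autoencoder embedding.** A one-hidden-layer autoencoder
   (`tanh` activations, hidden size `h = 100`) is trained for 10 epochs with
   Adam (learning rate 1e-3, full batch up to 512 samples, gradient norm
   clipped at 5) and 50% dropout. The `tanh` output on `[0, 1]` inputs is
   inconsistent with a plain log-loss, so the output is mapped through
   `(y + 1)/2` and trained with element-wise binary cross-entropy; mean
   squared error is available behind a flag. Dropout is applied to input
   units by default; the reading of "50% of the weight coefficients set to 0"
   (DropConnect) is available as `dropout_mode = "weight"`. A PCA projector
   (`backend = "pca"`) is a drop-in linear alternative. Everything is
   deterministic given the seed.

3. **Survival-associated feature selection.** Every latent coordinate is
   screened with a univariate Cox proportional-hazards model; coordinates
   with likelihood-ratio p < 0.01 across all omics are pooled into the
   matrix `Z`. We use the likelihood-ratio p-value for continuous covariates
   and the K-group log-rank test for categorical cluster labels: the two
   statistics are each used for what they are defined for. Zero retained
   coordinates is a typed outcome consumed by the ensemble filter, not an
   error. For speed the screen solves the untied partial likelihood with
   vectorized Newton iterations across all columns at once; it matches
   `survival::coxph` (Efron ties) to numerical precision and falls back to it
   when event times are tied.

4. **Subtype detection.** A Gaussian mixture model with diagonal covariances
   clusters the rows of `Z` (at most 1000 EM iterations, best log-likelihood
   of 100 seeded initializations; k-means and an L1-penalized Cox median
   split are alternative backends). Clusters are relabeled `0..K-1` by
   Kaplan-Meier median survival, label 0 worst; when a KM curve never
   crosses 0.5 the restricted mean survival time substitutes, because naive
   medians of observed times are biased under censoring. Median ties are
   broken deterministically (smaller group first) with a warning.

5. **Classifier.** Per omic, the 50 distance features most discriminative of
   the subtype labels by Kruskal-Wallis p-value are combined into a matrix
   `M`, and a margin classifier is trained with a stratified 5-fold
   cross-validated grid search minimizing test-fold misclassification, ties
   preferring stronger regularization. No SVM implementation is available in
   the supported dependency set, so the margin classifier is a one-vs-rest
   L2-regularized logistic model (glmnet ridge over a fixed lambda grid
   `{1, 0.1, 0.01, 1e-3, 1e-4}`); its per-class logistic outputs are
   renormalized to a probability simplex, playing the role that Platt
   scaling plays for SVM decision scores. When a new sample lacks whole
   omics, a reduced classifier is re-fit on the training data restricted to
   the shared omics (cached per subset); missing *features* within an omic
   are absorbed earlier, by the common-feature re-ranking of stage 1.

## The ensemble

`fit_ensemble()` draws `n_models = 10` random subsamples of 80% of the
cohort, fits one submodel per draw, and eliminates submodels with no
survival-associated latent features or whose training labels fail the
log-rank test at 0.05. Predictions of the survivors are averaged with equal
weights — classes matched by the survival-ordered index, which is what makes
averaging meaningful — and the *risk score* of a sample is its aggregated
probability of the worst-survival subtype. For `K = 2` the final label is 0
when the risk score exceeds 0.5; for `K > 2` the argmax of the averaged
probabilities is used, with the risk score always reported alongside.
Weighting models by their hold-out concordance is available behind
`weight_by_c_index` and off by default, since the averaging rule is the
documented default behavior.

Hold-out evaluation is reported twice, because "performance on the hold-out
samples" has two defensible readings: the mean of per-model metrics (each
model scored on its own 20%), and pooled out-of-bag metrics where every
sample is scored by the average of the models that held it out. `select_K()`
fits the ensemble for each candidate `K` in `{2, 3, 4, 5}` and returns the
`K` with the best ensemble silhouette (mean per-model silhouette on `Z`),
ties broken by label stability (mean pairwise adjusted Rand index between
the models' full-cohort labelings). Silhouette is computed on `Z` — the
space the clustering actually sees — which is an assumption; the
complementary visual criterion, few crossovers between per-subtype
Kaplan-Meier curves, is deliberately not automated: the curves are exported
as TSV coordinates for inspection.

## Downstream interpretation

`differential_features()` contrasts the worst-survival group against all
others with a two-sided Wilcoxon rank-sum test per feature (default
threshold p < 0.001; the stricter 1e-4 sometimes used for signature work is
a parameter). Retained features get a univariate Cox p-value and a
per-dataset min-max normalized rank of `-log10 p`; `pan_dataset_rank()` sums
those ranks across datasets, so a feature recurrently prognostic across
cohorts accumulates a score up to the number of datasets.
`build_coexpression_network()` connects the top differential genes with edge
weights `|Spearman correlation|` (Spearman is robust to the pipeline's
rank-normalized inputs; Pearson behind a flag), normalized by the network
maximum; `consensus_network()` sums node and edge weights across cohorts,
keeps the 200 heaviest nodes, prunes each node to its 10 heaviest incident
edges — an edge survives if either endpoint keeps it, the more conservative
reading of per-gene pruning — and detects communities with the walktrap
random-walk algorithm. A tree-ensemble edge scorer for the pan-cohort
combination is out of scope; the correlation backend is a documented
substitution.

## The synthetic cohort generator

`generate_cohort()` draws a stated world in which every stage is testable:
subtypes assigned uniformly; per omic, `n_informative` features distributed
`Normal(effect_size * subtype, 1)` among `Normal(0, 1)` noise features;
survival times exponential with hazard `baseline * HR^subtype`; independent
exponential censoring with its rate calibrated by root finding to the target
censoring fraction. Methylation-like layers (tag `METH`) are squashed
through a logistic map to `(0, 1)` so per-omic normalization faces genuinely
different scales. Defaults are `n = 200` samples, `K = 2` subtypes, three
omics (RNA 500 features / 30 informative, miRNA 200/20, methylation 500/30),
effect size 1 SD, baseline hazard 1/1000 events/day, hazard ratio 3 per
subtype step, 20% censoring. Cohort size, hazard ratio, and censoring follow
the recovery conditions the package is tested under; feature counts and the
1-SD effect were chosen once as realistic desk-scale values (a moderate,
recoverable molecular signature) and are not tuned to test outcomes.

What the generator does *not* emulate: count noise of sequencing data
(negative binomial dispersion, library sizes), batch effects, correlated
feature blocks beyond the subtype signal, informative censoring, and
non-proportional hazards. A green test on this world therefore establishes
that the machinery recovers planted structure under its stated assumptions —
not that it will behave identically on real tumor cohorts.

## Numerical choices and degenerate inputs

* Missing cells are rejected at load time by default (per-feature median
  imputation behind a flag); duplicated feature ids keep the first
  occurrence with a warning; sample order is canonicalized (sorted) after
  alignment for run-to-run reproducibility.
* Variance ties in feature selection sort by `(-variance, feature id)`;
  constant rank profiles make correlations undefined and raise a typed error
  naming the sample.
* The GMM floors variances at `reg_covar = 1e-6` and stops when the mean
  per-sample log-likelihood changes by less than 1e-3; identical rows are
  rejected as degenerate rather than clustered.
* All-censored survival raises typed errors in the Cox, log-rank, and
  concordance kernels (no comparable pairs); empty label groups are dropped
  from the log-rank test with a warning and the degrees of freedom reduced.
* Every stochastic step takes an explicit seed and restores the caller's RNG
  state; a fitted ensemble serializes to a single archive with an embedded
  schema version, and load/save round-trips reproduce predictions
  bit-identically.

## Known limitations

* With `K = 2` subtypes at hazard ratio 3, the concordance index of even a
  perfect binary subtype predictor is bounded near 0.63, because
  within-subtype pairs carry no risk ordering; hold-out C-indices near that
  value are the ceiling of the stated world, not a deficiency of the fit.
* The model-elimination rule tests cluster labels on the same training
  samples used to select survival-associated features, so on cohorts with no
  survival signal it retains most models (the labels inherit the selection's
  optimism); out-of-bag metrics still sit at chance there. Filtering on
  hold-out labels would be stricter but is not the documented rule.
* Acceptance-scale checks that leave ensemble size unstated use 3-5 model
  ensembles for runtime; the documented default remains 10.
* The autoencoder's exact loss trajectory under an unstated learning rate is
  not reproducible across implementations; only qualitative properties
  (loss decrease, seed determinism, signal retention) are asserted.
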