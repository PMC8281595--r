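# omicsurv

Ensemble survival subtyping from multi-omics data.

`omicsurv` is for analysts who have several omics matrices (e.g. mRNA, miRNA,
DNA methylation; features × samples) and per-sample survival outcomes, and
who want to (a) discover molecular subtypes *ordered by survival* — subtype 0
is always the worst-surviving group — and (b) classify new samples into those
subtypes, even when the new samples carry only one of the training omics or a
subset of features.

## The method in brief

Each of an ensemble of submodels, fit on a random 80% subsample, runs per
omic layer:

1. **Normalization** — keep the `top_k = 100` highest-variance features;
   within each sample, replace values by within-sample ranks / `top_k`; then
   describe every sample by its rank-normalized correlation distances
   (`d = 1 − r`, Pearson) to the `n` training samples. This makes training
   and new samples comparable across platforms and feature subsets.
2. **Embedding** — a one-hidden-layer autoencoder
   (`f(v) = tanh(W′ · s(W v + b) + b′)`, `s = tanh`, `h = 100`, 10 epochs,
   Adam, 50% dropout), or PCA.
3. **Cox screening** — keep latent features with univariate Cox-PH
   likelihood-ratio `p < 0.01`; pool them across omics into `Z`.
4. **Subtyping** — diagonal-covariance Gaussian mixture on `Z` (best of 100
   initializations, ≤ 1000 EM iterations); relabel clusters by Kaplan-Meier
   median survival, worst first.
5. **Classification** — per omic, the 50 most label-discriminative features
   (Kruskal-Wallis); a regularized one-vs-rest logistic margin classifier
   chosen by 5-fold cross-validated grid search, probabilities renormalized
   to a simplex.

Submodels with no survival-associated latent features, or whose labels fail
the log-rank test at 0.05, are eliminated; the rest vote by averaging class
probabilities (classes matched by survival-ordered index). The **risk
score** of a sample is its averaged probability of subtype 0. Quality
metrics: log-rank p and Harrell's C-index on hold-out samples (per-model
mean and pooled out-of-bag), silhouette, and label stability (mean pairwise
adjusted Rand index across models); `select_K()` picks the number of
subtypes from `{2,3,4,5}` by silhouette.

Downstream, `differential_features()` (Wilcoxon rank-sum, worst subtype vs
rest), `pan_dataset_rank()` (summed min-max-normalized `−log10` Cox-p ranks
across datasets), and `build_coexpression_network()` /
`consensus_network()` (|Spearman| edge weights, top-200 nodes, top-10 edges
per node, walktrap communities) interpret the worst-survival subtype.

## Worked example

```r
library(omicsurv)

# A synthetic 200-sample cohort: 3 omics, 2 latent subtypes, hazard ratio 3,
# 20% censoring, known ground truth.
co  <- generate_cohort(cohort_spec(seed = 11))
ens <- fit_ensemble(co$dataset, K = 2, n_models = 10, seed = 42)
print(ens)
#> <omicsurv_ensemble> K = 2, 10/10 models retained
#>   pooled OOB: C-index 0.592, log-rank p 5.23e-07 (n = 176)
#>   per-model mean: C-index 0.605, log-rank p 0.086
#>   silhouette 0.235, stability ARI 0.867, K = 2, models retained = 10

pred <- predict_ensemble(ens, co$dataset$layers)
adjusted_rand_index(pred$labels[names(co$subtype)], co$subtype)
#> [1] 0.9799995
```

Reading the output: all 10 bagging submodels survived the
survival-association filter. Scoring each sample with the submodels that
held it out gives a log-rank p of 5×10⁻⁷ — the two predicted subtypes have
clearly different survival on data the models never saw — and a pooled
C-index of 0.59 (with a binary subtype at hazard ratio 3, even a perfect
predictor is bounded near 0.63, since within-subtype pairs carry no risk
ordering). The predicted labels agree with the planted subtypes at
ARI 0.98. Labels are survival-ordered: `"0"` is the worst-survival subtype,
and `pred$risk` is each sample's probability of belonging to it.

Classifying samples that only have RNA measurements needs no refitting call:

```r
rna_only <- predict_ensemble(ens, co$dataset$layers["RNA"])
mean(rna_only$labels[names(pred$labels)] == pred$labels)
#> [1] 0.99
```

A command-line front end (`inst/cli/omicsurv.R`) wraps the same functions as
`simulate`, `fit`, `evaluate`, `predict`, and `signatures` subcommands over
TSV inputs (matrices: header row of sample ids, first column of feature ids;
survival: `sample`, `days`, `event` columns).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch at the default
configuration — generates a synthetic cohort from the given seed, fits the
10-model ensemble, evaluates hold-out concordance and log-rank separation,
and extracts worst-subtype differential features — logging a summary line
and writing the JSON report to `--out`.
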