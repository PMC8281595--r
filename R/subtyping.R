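# Subtype discovery: pool survival-associated latent features across omics,
# cluster samples (diagonal GMM by default), order cluster labels by median
# survival (label 0 = worst), and score clusterings (silhouette, ARI,
# stability, K selection).

#' Select survival-associated latent features
#'
#' Screens every latent column of every omic with a univariate Cox
#' proportional-hazards model and keeps those with likelihood-ratio p < alpha,
#' concatenating the survivors from all omics into the matrix Z used for
#' clustering. Zero retained columns is a valid, typed outcome (consumed by
#' the ensemble filter), not an error.
#'
#' @param latents a `latent_matrix` or list of them (one per omic), sharing
#'   sample order with `survival`.
#' @param survival a [survival_table()].
#' @param alpha retention threshold on the Cox p-value (default 0.01).
#' @return An object of class `survival_feature_matrix` with fields `Z`
#'   (samples x p), `provenance` (data.frame: latent_id, omic_tag, p_value,
#'   coefficient), `n_retained`.
#' @export
select_survival_features <- function(latents, survival, alpha = 0.01) {
  if (inherits(latents, "latent_matrix")) latents <- list(latents)
  vals <- lapply(latents, function(l) {
    if (!identical(l$sample_ids, survival$sample_ids))
      abort_omicsurv("latent matrix sample order must match survival table",
                     "argument")
    l$values
  })
  Z_all <- do.call(cbind, vals)
  scr <- cox_screen(Z_all, survival)
  keep <- which(scr$p_value < alpha)
  structure(list(
    Z = Z_all[, keep, drop = FALSE],
    provenance = data.frame(
      latent_id = colnames(Z_all)[keep],
      omic_tag = sub("\\.[0-9]+$", "", colnames(Z_all)[keep]),
      p_value = scr$p_value[keep],
      coefficient = scr$coefficient[keep],
      stringsAsFactors = FALSE),
    n_retained = length(keep),
    alpha = alpha,
    sample_ids = survival$sample_ids
  ), class = "survival_feature_matrix")
}

#' @export
print.survival_feature_matrix <- function(x, ...) {
  cat(sprintf("<survival_feature_matrix> %d sample(s) x %d retained latent feature(s) (alpha = %g)\n",
              length(x$sample_ids), x$n_retained, x$alpha))
  invisible(x)
}

#' Cluster samples into K subtypes
#'
#' Default method is the diagonal-covariance Gaussian mixture model (best of
#' `n_init` initializations, up to `max_iter` EM iterations). `"kmeans"` and
#' `"lasso_cox"` (median split on the linear predictor of an L1-penalized Cox
#' fit; K = 2 only) are alternative backends.
#'
#' @param Z a `survival_feature_matrix` or plain samples x p matrix.
#' @param K number of subtypes (>= 2).
#' @param method `"gmm"` (default), `"kmeans"`, or `"lasso_cox"`.
#' @param seed RNG seed.
#' @param n_init,max_iter GMM/k-means initialization and iteration budget.
#' @param survival required for `method = "lasso_cox"`.
#' @return Integer vector of raw cluster labels in 1..K.
#' @export
cluster_subtypes <- function(Z, K, method = c("gmm", "kmeans", "lasso_cox"),
                             seed = 1, n_init = 100, max_iter = 1000,
                             survival = NULL) {
  method <- match.arg(method)
  X <- if (inherits(Z, "survival_feature_matrix")) Z$Z else as.matrix(Z)
  if (K < 2) abort_omicsurv("K must be >= 2", "argument")
  if (nrow(X) <= K)
    abort_omicsurv("need more samples than clusters", "argument")
  if (method == "gmm") {
    fit_gmm_diag(X, K, n_init = n_init, max_iter = max_iter, seed = seed)$labels
  } else if (method == "kmeans") {
    if (all(apply(X, 2, stats::sd) == 0))
      abort_omicsurv("degenerate input: all rows identical, clustering undefined",
                     "degenerate")
    with_seed(seed,
              stats::kmeans(X, centers = K, nstart = min(n_init, 50),
                            iter.max = max_iter)$cluster)
  } else {
    if (K != 2)
      abort_omicsurv("lasso_cox backend supports K = 2 only", "argument")
    if (is.null(survival))
      abort_omicsurv("lasso_cox backend needs the survival table", "argument")
    lp <- with_seed(seed, {
      cv <- glmnet::cv.glmnet(X, surv_object(survival), family = "cox",
                              nfolds = 5)
      as.numeric(stats::predict(cv, newx = X, s = "lambda.min"))
    })
    as.integer(lp > stats::median(lp)) + 1L   # high risk -> cluster 2 (raw)
  }
}

# Kaplan-Meier median survival of one group; restricted mean when the curve
# never crosses 0.5 (naive medians of observed times are biased under
# censoring).
km_median <- function(survival) {
  fit <- survival::survfit(surv_object(survival) ~ 1)
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  if (is.na(med)) unname(tab["rmean"]) else med
}

#' Order cluster labels by median survival
#'
#' Relabels raw clusters as 0..K-1 so that label 0 has the lowest median
#' survival (Kaplan-Meier median; restricted mean survival time when the KM
#' curve never reaches 0.5) and the last label the highest. Median ties are
#' broken deterministically (smaller group first) with a warning.
#'
#' @param raw_labels vector of cluster labels, one per sample.
#' @param survival a [survival_table()] in the same sample order.
#' @return An object of class `subtype_labeling` with fields `sample_ids`,
#'   `raw_labels`, `ordered_labels` (0-based), `K`,
#'   `median_survival_per_label` (non-decreasing, days).
#' @export
order_labels_by_survival <- function(raw_labels, survival) {
  if (length(raw_labels) != length(survival$sample_ids))
    abort_omicsurv("labels length must equal sample count", "argument")
  lv <- sort(unique(raw_labels))
  meds <- vapply(lv, function(l)
    km_median(subset_survival_idx(survival, raw_labels == l)), numeric(1))
  sizes <- vapply(lv, function(l) sum(raw_labels == l), numeric(1))
  if (anyDuplicated(meds))
    warning("median survival tie between clusters; smaller group ordered first")
  ord <- order(meds, sizes)                      # ascending; tie -> smaller group
  new_of_raw <- stats::setNames(seq_along(lv) - 1L, lv[ord])
  ordered <- unname(new_of_raw[as.character(raw_labels)])
  structure(list(sample_ids = survival$sample_ids,
                 raw_labels = raw_labels,
                 ordered_labels = as.integer(ordered),
                 K = length(lv),
                 median_survival_per_label = unname(meds[ord])),
            class = "subtype_labeling")
}

subset_survival_idx <- function(surv, keep) {
  survival_table(surv$sample_ids[keep], surv$time[keep], surv$event[keep])
}

#' @export
print.subtype_labeling <- function(x, ...) {
  cat(sprintf("<subtype_labeling> %d samples, K = %d; median survival by label: %s\n",
              length(x$sample_ids), x$K,
              paste(round(x$median_survival_per_label), collapse = ", ")))
  invisible(x)
}

#' Mean silhouette width
#'
#' Euclidean silhouette: per sample, (b - a) / max(a, b) where a is the mean
#' distance to its own cluster and b the smallest mean distance to another
#' cluster; singleton clusters contribute 0.
#'
#' @param Z samples x p matrix (or `survival_feature_matrix`).
#' @param labels cluster labels (>= 2 distinct).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(Z, labels) {
  X <- if (inherits(Z, "survival_feature_matrix")) Z$Z else as.matrix(Z)
  labels <- as.vector(labels)
  if (length(unique(labels)) < 2)
    abort_omicsurv("silhouette needs >= 2 clusters", "degenerate")
  D <- as.matrix(stats::dist(X))
  lv <- unique(labels)
  n <- nrow(X)
  # mean distance from every sample to every cluster
  md <- vapply(lv, function(l) rowSums(D[, labels == l, drop = FALSE]) /
                 pmax(sum(labels == l), 1), numeric(n))
  sizes <- vapply(lv, function(l) sum(labels == l), numeric(1))
  s <- vapply(seq_len(n), function(i) {
    k <- match(labels[i], lv)
    if (sizes[k] == 1) return(0)
    a <- md[i, k] * sizes[k] / (sizes[k] - 1)    # exclude self from own mean
    b <- min(md[i, -k])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions, computed
#' from the contingency table; 1 = identical partitions, ~0 = random.
#'
#' @param a,b label vectors of equal length.
#' @return ARI value.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    abort_omicsurv("label vectors must have equal length", "argument")
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)             # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Clustering stability across models
#'
#' Mean of the pairwise adjusted Rand indices between the label vectors of
#' different models — the consistency of class labeling during bagging.
#'
#' @param labelings list of >= 2 equal-length label vectors.
#' @return Mean pairwise ARI.
#' @export
clustering_stability <- function(labelings) {
  m <- length(labelings)
  if (m < 2) abort_omicsurv("need >= 2 labelings for stability", "argument")
  pairs <- utils::combn(m, 2)
  mean(apply(pairs, 2, function(ij)
    adjusted_rand_index(labelings[[ij[1]]], labelings[[ij[2]]])))
}

#' Choose the number of subtypes K
#'
#' Fits the full bagging ensemble for each candidate K and returns the K with
#' the best ensemble silhouette, ties broken by label stability (mean pairwise
#' ARI). The complete per-K metrics are returned for manual inspection — the
#' complementary visual criterion (few Kaplan-Meier crossovers) is left to the
#' analyst via the exported KM coordinates.
#'
#' @param dataset a `multi_omics_dataset`.
#' @param candidates integer candidates (default 2:5).
#' @param seed RNG seed (shared across candidates).
#' @param ... passed to [fit_ensemble()].
#' @return List with `K` (selected), `reports` (named list of
#'   `metrics_report` per candidate), `ensembles` (fitted per candidate).
#' @export
select_K <- function(dataset, candidates = 2:5, seed = 1, ...) {
  fits <- lapply(candidates, function(K) {
    tryCatch(fit_ensemble(dataset, K = K, seed = seed, ...),
             omicsurv_error = function(e) e)
  })
  names(fits) <- as.character(candidates)
  ok <- !vapply(fits, inherits, logical(1), "condition")
  if (!any(ok))
    abort_omicsurv("no candidate K yielded a valid ensemble", "no_valid_K")
  reports <- lapply(fits[ok], function(f) f$metrics)
  sil <- vapply(reports, function(r) r$silhouette %||% NA_real_, numeric(1))
  stab <- vapply(reports, function(r) r$stability_ari %||% NA_real_, numeric(1))
  best <- order(-sil, -stab)[1]
  list(K = as.integer(names(reports)[best]),
       reports = reports,
       ensembles = fits[ok])
}
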