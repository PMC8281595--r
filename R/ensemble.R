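# The bagging ensemble: many submodels on random 80% subsamples, each running
# normalization -> autoencoder -> survival-feature selection -> GMM subtyping
# -> classifier; models without survival-associated features or labels are
# eliminated; subtype probabilities of the survivors are averaged (classes
# matched by survival-ordered label index, 0 = worst survival).

default_config <- function() {
  list(top_k = 100, hidden = 100, epochs = 10, dropout = 0.5,
       backend = "autoencoder", alpha = 0.01, cluster_method = "gmm",
       n_init = 100, max_iter = 1000, per_omic = 50, min_common = 2)
}

# Fit one submodel on the given training sample ids; never throws for the
# expected failure modes — returns an object with validity flag + reason.
fit_submodel <- function(dataset, train_ids, K, seed, config) {
  holdout_ids <- setdiff(dataset$survival$sample_ids, train_ids)
  train_data <- subset_dataset(dataset, train_ids)
  seeds <- derive_seeds(seed, length(dataset$layers) + 2L)
  normalizers <- list(); encoders <- list(); latents <- list()
  train_feats <- list()
  for (i in seq_along(train_data$layers)) {
    tag <- names(train_data$layers)[i]
    nm <- fit_normalizer(train_data$layers[[i]], top_k = config$top_k)
    df <- transform_training(nm)
    enc <- if (config$backend == "pca") {
      fit_pca_embedding(df, k = min(config$hidden, nrow(df$values) - 1,
                                    ncol(df$values)), omic_tag = tag)
    } else {
      fit_autoencoder(df, h = config$hidden, epochs = config$epochs,
                      dropout = config$dropout, seed = seeds[i],
                      omic_tag = tag)
    }
    normalizers[[tag]] <- nm
    encoders[[tag]] <- enc
    latents[[tag]] <- encode(enc, df)
    train_feats[[tag]] <- df$values
  }
  sub <- list(train_ids = train_data$survival$sample_ids,
              holdout_ids = sort(holdout_ids),
              normalizers = normalizers, encoders = encoders,
              K = K, seed = seed, config = config,
              valid = FALSE, reason = NULL)

  sfm <- select_survival_features(latents, train_data$survival,
                                  alpha = config$alpha)
  sub$features <- sfm
  if (sfm$n_retained == 0) {
    sub$reason <- "no survival features"
    return(structure(sub, class = "omicsurv_submodel"))
  }
  raw <- tryCatch(
    cluster_subtypes(sfm, K = K, method = config$cluster_method,
                     seed = seeds[length(seeds) - 1L],
                     n_init = config$n_init, max_iter = config$max_iter,
                     survival = train_data$survival),
    omicsurv_error = function(e) e)
  if (inherits(raw, "condition")) {
    sub$reason <- paste("clustering failed:", conditionMessage(raw))
    return(structure(sub, class = "omicsurv_submodel"))
  }
  labeling <- order_labels_by_survival(raw, train_data$survival)
  sub$labeling <- labeling
  lr <- tryCatch(logrank_test(labeling$ordered_labels, train_data$survival),
                 omicsurv_error = function(e) e)
  if (inherits(lr, "condition")) {
    sub$reason <- "labels not survival-associated"
    sub$train_logrank_p <- 1
    return(structure(sub, class = "omicsurv_submodel"))
  }
  sub$train_logrank_p <- lr$p_value
  if (lr$p_value > 0.05) {
    sub$reason <- "labels not survival-associated"
    return(structure(sub, class = "omicsurv_submodel"))
  }
  cls <- tryCatch(
    fit_subtype_classifier(train_feats, labeling,
                           seed = seeds[length(seeds)],
                           per_omic = config$per_omic),
    error = function(e) e)               # incl. degenerate-class fit errors
  if (inherits(cls, "condition")) {
    sub$reason <- paste("classifier failed:", conditionMessage(cls))
    return(structure(sub, class = "omicsurv_submodel"))
  }
  sub$classifier <- cls
  sub$valid <- TRUE

  # hold-out evaluation: predict the 20% never seen during fitting
  if (length(holdout_ids) > 0) {
    ho <- subset_dataset(dataset, holdout_ids)
    pred <- tryCatch(predict_submodel(structure(sub, class = "omicsurv_submodel"),
                                      ho$layers),
                     omicsurv_error = function(e) NULL)
    if (!is.null(pred)) {
      sub$holdout_prediction <- pred
      risk <- pred$probabilities[, "0"]
      sub$holdout_c_index <- tryCatch(
        concordance_index(risk, ho$survival),
        omicsurv_error = function(e) NA_real_)
      sub$holdout_logrank_p <- tryCatch(
        logrank_test(pred$labels, ho$survival)$p_value,
        omicsurv_error = function(e) NA_real_,
        error = function(e) NA_real_)
    }
  }
  structure(sub, class = "omicsurv_submodel")
}

#' @export
print.omicsurv_submodel <- function(x, ...) {
  cat(sprintf("<omicsurv_submodel> K = %d, %d training samples, %s\n",
              x$K, length(x$train_ids),
              if (x$valid) sprintf("valid (%d survival features)",
                                   x$features$n_retained)
              else sprintf("invalid: %s", x$reason)))
  invisible(x)
}

# Predict subtype probabilities with one submodel for a named list of
# omics_matrix layers (any subset of the training omics).
predict_submodel <- function(sub, layers) {
  tags <- intersect(names(sub$normalizers), names(layers))
  if (length(tags) == 0)
    abort_omicsurv("no shared omic layer with the submodel", "no_shared_omics")
  feats <- list()
  for (tag in tags) {
    df <- tryCatch(transform_new(sub$normalizers[[tag]], layers[[tag]],
                                 min_common = sub$config$min_common),
                   omicsurv_error = function(e) NULL)
    if (!is.null(df) && nrow(df$values) > 0) feats[[tag]] <- df$values
  }
  if (length(feats) == 0)
    abort_omicsurv("no omic layer shares enough features with the submodel",
                   "no_shared_features")
  predict_subtype(sub$classifier, feats)
}

#' Filter submodels on survival association
#'
#' Keeps models that retained at least one survival-associated latent feature
#' and whose training cluster labels are survival-associated (log-rank
#' p <= 0.05). The elimination rule of the bagging procedure.
#'
#' @param models list of submodels from the ensemble fit.
#' @return The retained sublist (possibly empty; callers decide whether that
#'   is an error).
#' @export
filter_models <- function(models) {
  Filter(function(m) isTRUE(m$valid), models)
}

#' Fit a bagging ensemble of subtype models
#'
#' Draws `n_models` random subsamples (default 80% of the cohort), fits one
#' submodel per draw, eliminates those without survival-associated features or
#' labels, and aggregates the rest. Deterministic given
#' (dataset, configuration, seed).
#'
#' @param dataset a `multi_omics_dataset` from [align_dataset()].
#' @param K number of subtypes.
#' @param n_models number of submodels (default 10).
#' @param subsample training fraction per submodel (default 0.8).
#' @param seed RNG seed.
#' @param config pipeline configuration; see `default_config()` in the
#'   package sources. Any named element overrides the default (e.g.
#'   `list(epochs = 5)`).
#' @return An object of class `omicsurv_ensemble`: retained `models`,
#'   `all_model_reasons`, `metrics` (a `metrics_report`), `K`, `seed`,
#'   `config`.
#' @export
fit_ensemble <- function(dataset, K, n_models = 10, subsample = 0.8, seed = 1,
                         config = list()) {
  if (n_models < 1) abort_omicsurv("n_models must be >= 1", "argument")
  if (subsample <= 0 || subsample > 1)
    abort_omicsurv("subsample must be in (0, 1]", "argument")
  cfg <- utils::modifyList(default_config(), config)
  ids <- dataset$survival$sample_ids
  n <- length(ids)
  model_seeds <- derive_seeds(seed, n_models + 1L)
  draws <- with_seed(model_seeds[n_models + 1L], lapply(seq_len(n_models),
    function(i) sort(sample(ids, round(subsample * n)))))
  models <- lapply(seq_len(n_models), function(i)
    fit_submodel(dataset, draws[[i]], K = K, seed = model_seeds[i],
                 config = cfg))
  retained <- filter_models(models)
  reasons <- vapply(models, function(m)
    if (isTRUE(m$valid)) "retained" else m$reason, character(1))
  if (length(retained) == 0)
    abort_omicsurv(sprintf(
      "ensemble failed: no submodel retained (%s)",
      paste(sprintf("model %d: %s", seq_along(reasons), reasons),
            collapse = "; ")), "ensemble_failed",
      reasons = reasons)
  ens <- structure(list(models = retained, n_requested = n_models,
                        subsample = subsample, K = K, seed = seed,
                        config = cfg, all_model_reasons = reasons,
                        sample_ids = ids),
                   class = "omicsurv_ensemble")
  ens$metrics <- evaluate_holdout(ens, dataset$survival)
  ens
}

#' @export
print.omicsurv_ensemble <- function(x, ...) {
  cat(sprintf("<omicsurv_ensemble> K = %d, %d/%d models retained\n",
              x$K, length(x$models), x$n_requested))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Predict subtypes with the ensemble
#'
#' Per-class probability = unweighted mean over the retained models able to
#' score the sample (classes matched by survival-ordered label index; with
#' `weight_by_c_index = TRUE`, models are weighted by their hold-out
#' concordance instead). The risk score is the aggregated probability of the
#' worst-survival subtype (label 0); the final label is label 0 when the risk
#' score exceeds 0.5 for K = 2, otherwise the argmax of the averaged
#' probabilities.
#'
#' @param ensemble an `omicsurv_ensemble`.
#' @param layers named list of [omics_matrix()] layers (any subset of the
#'   training omics), or a `multi_omics_dataset`.
#' @param weight_by_c_index weight models by hold-out C-index (default FALSE:
#'   equal weights).
#' @return List with `probabilities` (samples x K, rows sum to 1), `risk`
#'   (worst-subtype probability), `labels` (final label per sample),
#'   `n_models_used`, `failed` (sample ids unpredictable by every model).
#' @export
predict_ensemble <- function(ensemble, layers, weight_by_c_index = FALSE) {
  if (inherits(layers, "multi_omics_dataset")) layers <- layers$layers
  class_names <- as.character(0:(ensemble$K - 1))
  per_model <- list(); wts <- c()
  for (m in ensemble$models) {
    pred <- tryCatch(predict_submodel(m, layers),
                     omicsurv_error = function(e) NULL)
    if (is.null(pred)) next
    P <- matrix(0, nrow(pred$probabilities), ensemble$K,
                dimnames = list(rownames(pred$probabilities), class_names))
    P[, colnames(pred$probabilities)] <- pred$probabilities
    per_model[[length(per_model) + 1L]] <- P
    wts <- c(wts, if (weight_by_c_index) m$holdout_c_index %||% NA_real_ else 1)
  }
  if (length(per_model) == 0)
    abort_omicsurv("no retained model can score these samples",
                   "no_applicable_model")
  wts[is.na(wts)] <- mean(wts, na.rm = TRUE)
  if (all(!is.finite(wts))) wts <- rep(1, length(per_model))
  wts <- wts / sum(wts)
  agg <- Reduce(`+`, Map(function(P, w) P * w, per_model, wts))
  risk <- agg[, "0"]
  labels <- if (ensemble$K == 2) {
    ifelse(risk > 0.5, "0", "1")
  } else {
    class_names[max.col(agg, ties.method = "first")]
  }
  all_ids <- unique(unlist(lapply(layers, function(l) l$sample_ids)))
  list(probabilities = agg, risk = risk,
       labels = stats::setNames(labels, rownames(agg)),
       n_models_used = length(per_model),
       failed = setdiff(all_ids, rownames(agg)))
}

#' Evaluate an ensemble on its hold-out samples
#'
#' Reports both readings of hold-out performance: the mean of per-model
#' hold-out metrics (each model scored on its own 20%), and pooled
#' out-of-bag metrics where every sample is scored by averaging the models
#' that held it out. Ensemble silhouette is the mean per-model silhouette on
#' the retained latent features; stability is the mean pairwise ARI between
#' the models' full-cohort labelings.
#'
#' @param ensemble an `omicsurv_ensemble`.
#' @param survival the cohort's [survival_table()] (stored predictions are
#'   matched by sample id).
#' @return A `metrics_report` list: `logrank_p`, `c_index` (pooled OOB),
#'   `logrank_p_models_mean`, `c_index_models_mean`, `silhouette`,
#'   `stability_ari`, `K`, `n_retained_models`, `oob_n`.
#' @export
evaluate_holdout <- function(ensemble, survival) {
  models <- ensemble$models
  per_c <- vapply(models, function(m) m$holdout_c_index %||% NA_real_,
                  numeric(1))
  per_p <- vapply(models, function(m) m$holdout_logrank_p %||% NA_real_,
                  numeric(1))
  # pooled out-of-bag aggregation
  class_names <- as.character(0:(ensemble$K - 1))
  acc <- list()
  for (m in models) {
    if (is.null(m$holdout_prediction)) next
    P <- matrix(0, nrow(m$holdout_prediction$probabilities), ensemble$K,
                dimnames = list(rownames(m$holdout_prediction$probabilities),
                                class_names))
    P[, colnames(m$holdout_prediction$probabilities)] <-
      m$holdout_prediction$probabilities
    for (sid in rownames(P)) {
      acc[[sid]] <- if (is.null(acc[[sid]])) list(sum = P[sid, ], n = 1L)
      else list(sum = acc[[sid]]$sum + P[sid, ], n = acc[[sid]]$n + 1L)
    }
  }
  pooled <- list(logrank_p = NA_real_, c_index = NA_real_, n = 0L)
  if (length(acc) > 0) {
    ids <- intersect(survival$sample_ids, names(acc))
    probs <- t(vapply(ids, function(sid) acc[[sid]]$sum / acc[[sid]]$n,
                      numeric(ensemble$K)))
    risk <- probs[, 1]
    labels <- if (ensemble$K == 2) ifelse(risk > 0.5, "0", "1")
    else class_names[max.col(probs, ties.method = "first")]
    sv <- subset_survival(survival, ids)
    pooled$c_index <- tryCatch(concordance_index(risk, sv),
                               omicsurv_error = function(e) NA_real_)
    pooled$logrank_p <- tryCatch(logrank_test(labels, sv)$p_value,
                                 omicsurv_error = function(e) NA_real_,
                                 error = function(e) NA_real_)
    pooled$n <- length(ids)
  }
  sil <- mean(vapply(models, function(m) {
    tryCatch(silhouette_score(m$features$Z, m$labeling$ordered_labels),
             omicsurv_error = function(e) NA_real_)
  }, numeric(1)), na.rm = TRUE)
  stab <- if (length(models) >= 2) {
    labs <- lapply(models, full_cohort_labels, ensemble = ensemble)
    ok <- !vapply(labs, is.null, logical(1))
    if (sum(ok) >= 2) clustering_stability(labs[ok]) else NA_real_
  } else NA_real_
  structure(list(logrank_p = pooled$logrank_p, c_index = pooled$c_index,
                 logrank_p_models_mean = mean(per_p, na.rm = TRUE),
                 c_index_models_mean = mean(per_c, na.rm = TRUE),
                 silhouette = sil, stability_ari = stab,
                 K = ensemble$K, n_retained_models = length(models),
                 oob_n = pooled$n),
            class = "metrics_report")
}

# Training labels from clustering + hold-out labels from the classifier, in
# the ensemble's cohort sample order (for stability ARI across models).
full_cohort_labels <- function(m, ensemble) {
  lab <- stats::setNames(as.character(m$labeling$ordered_labels),
                         m$labeling$sample_ids)
  if (!is.null(m$holdout_prediction))
    lab[rownames(m$holdout_prediction$probabilities)] <-
      m$holdout_prediction$labels
  if (!all(ensemble$sample_ids %in% names(lab))) return(NULL)
  unname(lab[ensemble$sample_ids])
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "  pooled OOB: C-index %.3f, log-rank p %.3g (n = %d)\n  per-model mean: C-index %.3f, log-rank p %.3g\n  silhouette %.3f, stability ARI %.3f, K = %d, models retained = %d\n",
    x$c_index, x$logrank_p, x$oob_n, x$c_index_models_mean,
    x$logrank_p_models_mean, x$silhouette, x$stability_ari, x$K,
    x$n_retained_models))
  invisible(x)
}

#' Apply an ensemble to an external cohort
#'
#' Transfer prediction: scores every sample of the external cohort with the
#' retained models (through the common-feature normalization path) and
#' evaluates the predicted labels and risk against the external cohort's own
#' survival.
#'
#' @param ensemble an `omicsurv_ensemble`.
#' @param other a `multi_omics_dataset` (the external cohort).
#' @return List with the `prediction` (as [predict_ensemble()]), `logrank_p`,
#'   `c_index`, and `n_scored`.
#' @export
cross_cohort_predict <- function(ensemble, other) {
  pred <- predict_ensemble(ensemble, other$layers)
  ids <- intersect(other$survival$sample_ids, rownames(pred$probabilities))
  sv <- subset_survival(other$survival, ids)
  risk <- pred$risk[ids]
  labels <- pred$labels[ids]
  list(prediction = pred,
       logrank_p = tryCatch(logrank_test(labels, sv)$p_value,
                            omicsurv_error = function(e) NA_real_,
                            error = function(e) NA_real_),
       c_index = tryCatch(concordance_index(risk, sv),
                          omicsurv_error = function(e) NA_real_),
       n_scored = length(ids))
}
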