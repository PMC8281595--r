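# Supervised subtype classifier over the normalized (distance-feature)
# representation: per-omic Kruskal-Wallis feature selection (top 50), a
# regularized linear margin classifier chosen by 5-fold cross-validated
# grid-search, logistic probabilities renormalized across classes, and
# on-demand reduced classifiers for samples carrying only a subset of the
# training omics.

#' Select the most subtype-discriminative features per omic
#'
#' Kruskal-Wallis test of every (distance) feature against the subtype labels,
#' per omic; the `per_omic` features with the smallest p-values are kept (all
#' features when fewer are available), ties broken by feature id. Fully
#' deterministic (no RNG).
#'
#' @param features named list (by omic tag) of samples x features matrices —
#'   typically `distance_features$values` per omic.
#' @param labels a `subtype_labeling` or vector of labels.
#' @param per_omic features kept per omic (default 50).
#' @return Named list per omic: data.frame with `feature`, `p_value`, ordered
#'   by selection rank.
#' @export
select_discriminative_features <- function(features, labels, per_omic = 50) {
  lab <- if (inherits(labels, "subtype_labeling")) labels$ordered_labels else labels
  if (length(unique(lab)) < 2)
    abort_omicsurv("need >= 2 subtype classes for feature selection",
                   "argument")
  if (min(table(lab)) < 2)
    abort_omicsurv("every subtype class needs >= 2 samples", "argument")
  lapply(features, function(M) {
    M <- as.matrix(M)
    kw <- kruskal_matrix(t(M), lab)
    ord <- order(kw$p_value, colnames(M))
    keep <- ord[seq_len(min(per_omic, ncol(M)))]
    data.frame(feature = colnames(M)[keep], p_value = kw$p_value[keep],
               stringsAsFactors = FALSE)
  })
}

# One-vs-rest ridge logistic classifier over a fixed lambda grid, 5-fold CV
# on misclassification error; ties prefer the larger lambda (stronger
# regularization). Returns the fitted per-class glmnet models at the chosen
# lambda plus the grid-search record.
fit_margin_classifier <- function(M, lab, seed,
                                  lambda_grid = c(1, 0.1, 0.01, 0.001, 1e-4),
                                  nfolds = 5) {
  classes <- sort(unique(lab))
  n <- nrow(M)
  min_class <- min(table(lab))
  if (min_class < nfolds) {
    nfolds <- max(2L, min_class)
    warning(sprintf("reducing CV folds to %d (smallest class has %d samples)",
                    nfolds, min_class))
  }
  foldid <- with_seed(seed, {
    f <- integer(n)
    for (cl in classes) {           # stratified folds
      idx <- which(lab == cl)
      f[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    f
  })
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)  # strong -> weak reg.
  fold_err <- vapply(seq_len(nfolds), function(fd) {
    tr <- foldid != fd; te <- !tr
    # folds that lose a class entirely (or to a single sample) are skipped
    if (length(unique(lab[tr])) < length(classes) ||
        min(table(lab[tr])) < 2)
      return(rep(NA_real_, length(lambda_grid)))
    # per class: one path fit over the whole lambda grid
    links <- lapply(classes, function(cl) {
      y <- as.numeric(lab[tr] == cl)
      # glmnet warns on very small fold classes; CV error handles quality
      fit <- suppressWarnings(
        glmnet::glmnet(M[tr, , drop = FALSE], y, family = "binomial",
                       alpha = 0, lambda = lambda_grid,
                       standardize = TRUE))
      stats::predict(fit, M[te, , drop = FALSE], type = "link",
                     s = lambda_grid)            # n_te x n_lambda
    })
    vapply(seq_along(lambda_grid), function(li) {
      sc <- vapply(links, function(L) L[, li], numeric(sum(te)))
      if (sum(te) == 1L) sc <- matrix(sc, nrow = 1)
      mean(classes[max.col(sc)] != lab[te])
    }, numeric(1))
  }, numeric(length(lambda_grid)))
  cv_err <- rowMeans(matrix(fold_err, nrow = length(lambda_grid)),
                     na.rm = TRUE)
  cv_err[is.nan(cv_err)] <- 1              # no usable fold: fall back to
  # the strongest regularization
  best <- which(cv_err == min(cv_err))[1]   # grid ordered strong -> weak reg.
  lambda <- lambda_grid[best]
  fits <- lapply(classes, function(cl) {
    y <- as.numeric(lab == cl)
    suppressWarnings(
      glmnet::glmnet(M, y, family = "binomial", alpha = 0,
                     lambda = lambda_grid, standardize = TRUE))
  })
  names(fits) <- as.character(classes)
  list(classes = classes, lambda = lambda, fits = fits,
       grid = data.frame(lambda = lambda_grid, cv_error = cv_err),
       nfolds = nfolds)
}

predict_margin <- function(mc, M) {
  probs <- vapply(mc$fits, function(fit)
    as.numeric(stats::predict(fit, M, type = "response", s = mc$lambda)),
    numeric(nrow(M)))
  if (nrow(M) == 1L) probs <- matrix(probs, nrow = 1)
  probs <- probs / rowSums(probs)           # renormalize one-vs-rest
  colnames(probs) <- as.character(mc$classes)
  probs
}

#' Fit the subtype classifier
#'
#' Builds the training matrix M by column-binding the selected features of
#' every omic and fits a one-vs-rest L2-regularized logistic margin classifier
#' whose regularization strength is chosen by stratified 5-fold
#' cross-validation over a fixed grid (objective: test-fold misclassification;
#' ties prefer stronger regularization). Probabilities are the per-class
#' logistic outputs renormalized to a simplex.
#'
#' @param features named list (by omic tag) of samples x features matrices.
#' @param labels a `subtype_labeling` (or label vector).
#' @param seed RNG seed (CV fold assignment).
#' @param per_omic features kept per omic (default 50).
#' @return An object of class `classifier_state`.
#' @export
fit_subtype_classifier <- function(features, labels, seed = 1, per_omic = 50) {
  lab <- if (inherits(labels, "subtype_labeling")) labels$ordered_labels else labels
  sel <- select_discriminative_features(features, lab, per_omic)
  M <- do.call(cbind, lapply(names(sel), function(tag) {
    m <- as.matrix(features[[tag]])[, sel[[tag]]$feature, drop = FALSE]
    colnames(m) <- paste(tag, colnames(m), sep = "::")
    m
  }))
  mc <- fit_margin_classifier(M, lab, seed)
  structure(list(selected = sel, omic_tags = names(sel),
                 classifier = mc, seed = seed, per_omic = per_omic,
                 train_features = lapply(features, function(m)
                   as.matrix(m)[, , drop = FALSE]),
                 train_labels = lab,
                 reduced_cache = list()),
            class = "classifier_state")
}

#' @export
print.classifier_state <- function(x, ...) {
  cat(sprintf("<classifier_state> classes {%s}, omics {%s}, lambda = %g\n",
              paste(x$classifier$classes, collapse = ","),
              paste(x$omic_tags, collapse = ","), x$classifier$lambda))
  invisible(x)
}

build_M <- function(state, features, tags) {
  do.call(cbind, lapply(tags, function(tag) {
    m <- as.matrix(features[[tag]])[, state$selected[[tag]]$feature,
                                    drop = FALSE]
    colnames(m) <- paste(tag, colnames(m), sep = "::")
    m
  }))
}

#' Predict subtypes for new samples
#'
#' When the new samples carry every training omic, the full classifier is
#' applied. When only a subset of omics is available, a reduced classifier is
#' re-fit on the training data restricted to that subset (cached per subset
#' signature) and applied — mirroring how partial-coverage samples are handled
#' at prediction time.
#'
#' @param state a `classifier_state`.
#' @param features named list (by omic tag) of samples x features matrices for
#'   the new samples; tags must be a subset of the training omics.
#' @return List with `probabilities` (samples x classes, rows sum to 1),
#'   `labels` (argmax class per sample), and the updated `state` (reduced-
#'   classifier cache).
#' @export
predict_subtype <- function(state, features) {
  tags <- intersect(state$omic_tags, names(features))
  if (length(tags) == 0)
    abort_omicsurv("new samples share no omic layer with the training set",
                   "no_shared_omics")
  if (length(tags) == length(state$omic_tags)) {
    mc <- state$classifier
  } else {
    key <- paste(sort(tags), collapse = "+")
    if (!is.null(state$reduced_cache[[key]])) {
      mc <- state$reduced_cache[[key]]
    } else {
      M_red <- build_M(state, state$train_features, tags)
      mc <- fit_margin_classifier(M_red, state$train_labels, state$seed)
      state$reduced_cache[[key]] <- mc
    }
  }
  M_new <- build_M(state, features, tags)
  probs <- predict_margin(mc, M_new)
  labels <- mc$classes[max.col(probs, ties.method = "first")]
  rownames(probs) <- rownames(M_new)
  list(probabilities = probs, labels = labels, state = state)
}
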