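# Per-omic rank / correlation-distance normalization.
#
# Stage 1: keep the top-variance features of the training layer and, within
# each sample, replace values by their within-sample rank divided by the number
# of kept features (highest value -> 1).  Stage 2: describe every sample by its
# rank-normalized correlation distance to each of the n training samples, so
# that samples measured on different platforms or feature subsets become
# comparable through the same n "distance features".

# Within-sample rank scores over the rows of `values` (features x samples):
# score = rank(value)/n_features, average ties, so the largest value in a
# sample scores 1.
rank_profiles <- function(values) {
  apply(values, 2, function(v) rank(v, ties.method = "average")) /
    nrow(values)
}

#' Fit the rank normalizer of one omic layer
#'
#' Selects the `top_k` highest-variance features of the training matrix
#' (ties broken by feature id) and stores, per training sample, the
#' within-sample rank profile over those features. The raw training values on
#' the selected features are kept so new samples measured on feature subsets
#' can be re-ranked on the common set at prediction time.
#'
#' @param matrix an [omics_matrix()] with at least 2 samples.
#' @param top_k number of highest-variance features to keep (default 100; all
#'   features if fewer are available).
#' @return An object of class `normalizer_state`.
#' @export
fit_normalizer <- function(matrix, top_k = 100) {
  if (length(matrix$sample_ids) < 2L)
    abort_omicsurv("need >= 2 training samples to fit a normalizer (variance undefined)",
                   "argument")
  v <- apply(matrix$values, 1, stats::var)
  ord <- order(-v, matrix$feature_ids)   # stable: variance desc, then id
  keep <- ord[seq_len(min(top_k, length(ord)))]
  sel_values <- matrix$values[keep, , drop = FALSE]
  structure(list(
    omic_tag = matrix$omic_tag,
    selected_features = matrix$feature_ids[keep],
    training_values = sel_values,
    training_rank_profiles = rank_profiles(sel_values),
    training_sample_ids = matrix$sample_ids,
    top_k = min(top_k, length(ord))
  ), class = "normalizer_state")
}

#' @export
print.normalizer_state <- function(x, ...) {
  cat(sprintf("<normalizer_state '%s'> %d features, %d training samples\n",
              x$omic_tag, length(x$selected_features),
              length(x$training_sample_ids)))
  invisible(x)
}

# Rank-normalize one row of distances: smallest distance -> 1, largest -> 0.
# Average-rank ties, then a linear rescale so the row always spans [0, 1]
# (constant rows are rejected upstream).
rank_normalize_distances <- function(d) {
  r <- rank(-d, ties.method = "average")
  rescale01(r)
}

# Correlation of columns of `a` (features x samples) against columns of `b`,
# with a named error when a profile is constant.
safe_cor <- function(a, b, ids_a, ids_b) {
  za <- apply(a, 2, stats::sd) == 0
  zb <- apply(b, 2, stats::sd) == 0
  if (any(za) || any(zb))
    abort_omicsurv(sprintf(
      "constant rank profile (correlation undefined) for sample(s): %s",
      paste(unique(c(ids_a[za], ids_b[zb])), collapse = ", ")),
      "degenerate")
  stats::cor(a, b)
}

#' Distance features of the training samples
#'
#' Pearson correlation between the rank profiles of every pair of training
#' samples, mapped to distances d = 1 - r, then rank-normalized per sample so
#' the closest training sample scores 1.0 and the farthest 0. A sample's
#' distance to itself (d = 0) is included and takes the top score unless
#' `include_self = FALSE`.
#'
#' @param state a fitted [fit_normalizer()] state.
#' @param include_self include each sample's own (zero) distance.
#' @return An object of class `distance_features`: samples x n matrix in
#'   \[0, 1\] with the n training sample ids as column names.
#' @export
transform_training <- function(state, include_self = TRUE) {
  p <- state$training_rank_profiles
  ids <- state$training_sample_ids
  r <- safe_cor(p, p, ids, ids)
  d <- 1 - r
  out <- t(vapply(seq_along(ids), function(i) {
    di <- d[i, ]
    if (!include_self) di[i] <- NA
    sc <- rank_normalize_distances(di[!is.na(di)])
    full <- rep(NA_real_, length(ids))
    full[!is.na(di)] <- sc
    if (!include_self) full[i] <- 1
    full
  }, numeric(length(ids))))
  dimnames(out) <- list(ids, ids)
  structure(list(sample_ids = ids, train_ids = ids, values = out),
            class = "distance_features")
}

#' Distance features of new samples
#'
#' Restricts each new sample and the stored training values to their common
#' selected features, re-ranks both on that common set, computes the
#' correlation distances to all n training samples, and rank-normalizes —
#' yielding rows directly comparable to [transform_training()] output.
#'
#' @param state a fitted [fit_normalizer()] state.
#' @param new_matrix an [omics_matrix()] of the same omic type.
#' @param min_common minimum number of shared features required per sample
#'   (default 2).
#' @return A `distance_features` object for the new samples. Samples with too
#'   few shared features are dropped and reported in the `failed` field
#'   (named character vector of reasons).
#' @export
transform_new <- function(state, new_matrix, min_common = 2) {
  common <- intersect(state$selected_features, new_matrix$feature_ids)
  failed <- character(0)
  if (length(common) < min_common) {
    failed <- stats::setNames(
      rep(sprintf("only %d feature(s) shared with the training set",
                  length(common)), length(new_matrix$sample_ids)),
      new_matrix$sample_ids)
    return(structure(list(sample_ids = character(0),
                          train_ids = state$training_sample_ids,
                          values = matrix(numeric(0), 0,
                                          length(state$training_sample_ids)),
                          failed = failed),
                     class = "distance_features"))
  }
  train_common <- state$training_values[
    match(common, state$selected_features), , drop = FALSE]
  new_common <- new_matrix$values[
    match(common, new_matrix$feature_ids), , drop = FALSE]
  train_prof <- rank_profiles(train_common)
  new_prof <- rank_profiles(new_common)
  r <- safe_cor(new_prof, train_prof, new_matrix$sample_ids,
                state$training_sample_ids)
  d <- 1 - r
  out <- t(apply(d, 1, rank_normalize_distances))
  if (length(new_matrix$sample_ids) == 1L) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(new_matrix$sample_ids, state$training_sample_ids)
  structure(list(sample_ids = new_matrix$sample_ids,
                 train_ids = state$training_sample_ids,
                 values = out, failed = failed),
            class = "distance_features")
}

#' @export
print.distance_features <- function(x, ...) {
  cat(sprintf("<distance_features> %d sample(s) x %d training distances\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
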