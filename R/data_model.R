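# Core data containers: omics matrices, survival tables, aligned multi-omic
# datasets, and ensemble (de)serialization.

#' Construct an omics matrix
#'
#' One omic layer: a real-valued feature-by-sample matrix with unique feature
#' and sample identifiers and a short omic tag (e.g. `"RNA"`, `"MIR"`,
#' `"METH"`). Values are platform-native (normalized counts, beta values, ...).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param omic_tag short string identifying the omic layer.
#' @param feature_ids,sample_ids character vectors; default to dimnames.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, omic_tag,
                         feature_ids = rownames(values),
                         sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids))
    abort_omicsurv("feature and sample identifiers are required", "argument")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(feature_ids) || ncol(values) != length(sample_ids))
    abort_omicsurv("matrix dimensions do not match identifier lengths",
                   "argument")
  if (anyDuplicated(sample_ids))
    abort_omicsurv(sprintf("duplicate sample ids in omic '%s': %s", omic_tag,
                           paste(unique(sample_ids[duplicated(sample_ids)]),
                                 collapse = ", ")), "load")
  if (anyDuplicated(feature_ids)) {
    dup <- unique(feature_ids[duplicated(feature_ids)])
    warning(sprintf(
      "omic '%s': %d duplicated feature id(s) (%s%s); keeping first occurrence",
      omic_tag, length(dup), paste(utils::head(dup, 5), collapse = ", "),
      if (length(dup) > 5) ", ..." else ""))
    keep <- !duplicated(feature_ids)
    values <- values[keep, , drop = FALSE]
    feature_ids <- feature_ids[keep]
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort_omicsurv(sprintf(
      "omic '%s': non-finite value at feature '%s', sample '%s'",
      omic_tag, feature_ids[bad[1]], sample_ids[bad[2]]), "parse")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(omic_tag = as.character(omic_tag)[1],
                 feature_ids = feature_ids,
                 sample_ids = sample_ids,
                 values = values),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s'> %d features x %d samples\n",
              x$omic_tag, length(x$feature_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read an omics matrix from a TSV file
#'
#' Expected layout: header row of sample ids, first column of feature ids,
#' numeric body (features x samples).
#'
#' @param path path to a tab-separated file.
#' @param omic_tag omic tag to attach.
#' @param impute_missing if `TRUE`, replace missing cells by the per-feature
#'   median; by default missing values are rejected.
#' @return An [omics_matrix()].
#' @export
load_omics_matrix <- function(path, omic_tag, impute_missing = FALSE) {
  if (!file.exists(path))
    abort_omicsurv(sprintf("file not found: %s", path), "io")
  df <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                          colClasses = "character")
  if (ncol(df) < 2L)
    abort_omicsurv(sprintf("%s: need a feature-id column plus >=1 sample", path),
                   "parse")
  feature_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- is.na(num) & !is.na(body)          # cells that failed to parse
  na_in <- is.na(num)
  if (any(na_in) && !impute_missing) {
    idx <- which(na_in, arr.ind = TRUE)[1, ]
    abort_omicsurv(sprintf(
      "%s: non-numeric or missing cell at feature '%s', sample '%s' (value '%s')",
      path, feature_ids[idx[1]], sample_ids[idx[2]], body[idx[1], idx[2]]),
      "parse")
  }
  if (any(bad)) {                            # genuinely unparseable text
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort_omicsurv(sprintf(
      "%s: non-numeric cell at feature '%s', sample '%s' (value '%s')",
      path, feature_ids[idx[1]], sample_ids[idx[2]], body[idx[1], idx[2]]),
      "parse")
  }
  if (any(na_in)) {
    for (i in which(rowSums(na_in) > 0)) {
      med <- stats::median(num[i, ], na.rm = TRUE)
      num[i, is.na(num[i, ])] <- med
    }
  }
  dimnames(num) <- list(feature_ids, sample_ids)
  omics_matrix(num, omic_tag)
}

#' Write an omics matrix as TSV
#'
#' Inverse of [load_omics_matrix()]; round-trips values exactly (full double
#' precision).
#' @param x an [omics_matrix()].
#' @param path output path.
#' @export
write_omics_matrix <- function(x, path) {
  df <- data.frame(feature = x$feature_ids,
                   format(x$values, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("feature", x$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a survival table
#'
#' Per-sample observation time (days) and event indicator (1 = observed death,
#' 0 = right-censored). The supervision signal for latent-feature selection,
#' subtype ordering, and evaluation.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param time positive observation times in days.
#' @param event 0/1 (or logical) event indicators.
#' @return An object of class `survival_table`.
#' @export
survival_table <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (anyDuplicated(sample_ids))
    abort_omicsurv("duplicate sample ids in survival table", "load")
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    abort_omicsurv("sample_ids, time, event must have equal length", "argument")
  if (any(!is.finite(time)) || any(time <= 0))
    abort_omicsurv(sprintf(
      "non-positive or missing survival times for sample(s): %s",
      paste(sample_ids[!is.finite(time) | time <= 0], collapse = ", ")),
      "validation")
  if (!all(event %in% c(0, 1)))
    abort_omicsurv("event indicator must be 0/1 (or logical)", "validation")
  structure(list(sample_ids = sample_ids, time = time, event = event),
            class = "survival_table")
}

#' @export
print.survival_table <- function(x, ...) {
  cat(sprintf("<survival_table> %d samples, %d events (%.0f%% censored)\n",
              length(x$sample_ids), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' Read a survival table from a TSV file
#'
#' @param path path to a tab-separated file with one row per sample.
#' @param sample_col,time_col,event_col column names (defaults `sample`,
#'   `days`, `event`).
#' @return A [survival_table()].
#' @export
load_survival <- function(path, sample_col = "sample", time_col = "days",
                          event_col = "event") {
  if (!file.exists(path))
    abort_omicsurv(sprintf("file not found: %s", path), "io")
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c(sample_col, time_col, event_col)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    abort_omicsurv(sprintf("%s: missing column(s): %s", path,
                           paste(miss, collapse = ", ")), "parse")
  ev <- df[[event_col]]
  if (is.logical(ev)) ev <- as.numeric(ev)
  if (is.character(ev)) ev <- as.numeric(ev %in% c("1", "TRUE", "true"))
  survival_table(df[[sample_col]], df[[time_col]], ev)
}

#' Write a survival table as TSV
#' @param x a [survival_table()].
#' @param path output path.
#' @export
write_survival <- function(x, path) {
  utils::write.table(
    data.frame(sample = x$sample_ids, days = x$time, event = x$event),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Subset a survival table by sample ids (in the given order).
subset_survival <- function(surv, ids) {
  idx <- match(ids, surv$sample_ids)
  if (anyNA(idx))
    abort_omicsurv("unknown sample id(s) in survival subset", "argument")
  survival_table(surv$sample_ids[idx], surv$time[idx], surv$event[idx])
}

subset_omics <- function(om, ids) {
  idx <- match(ids, om$sample_ids)
  if (anyNA(idx))
    abort_omicsurv("unknown sample id(s) in omics subset", "argument")
  omics_matrix(om$values[, idx, drop = FALSE], om$omic_tag)
}

#' Align omic layers and survival onto their common samples
#'
#' Restricts every layer and the survival table to the intersection of their
#' sample sets and puts all of them in one canonical order (sorted sample ids,
#' for run-to-run reproducibility). The number of samples dropped from each
#' layer is reported in the `dropped` field.
#'
#' @param layers list of [omics_matrix()] objects (optionally named; names
#'   default to each layer's omic tag).
#' @param survival a [survival_table()].
#' @return An object of class `multi_omics_dataset` with fields `layers`
#'   (named list), `survival`, and `dropped`.
#' @export
align_dataset <- function(layers, survival) {
  if (inherits(layers, "omics_matrix")) layers <- list(layers)
  if (length(layers) == 0L)
    abort_omicsurv("at least one omic layer is required", "argument")
  tags <- vapply(layers, function(l) l$omic_tag, character(1))
  if (anyDuplicated(tags))
    abort_omicsurv("duplicate omic tags across layers", "argument")
  names(layers) <- tags
  common <- Reduce(intersect, c(lapply(layers, function(l) l$sample_ids),
                                list(survival$sample_ids)))
  if (length(common) == 0L)
    abort_omicsurv("no samples shared by all omic layers and survival",
                   "alignment")
  common <- sort(common)
  dropped <- c(lapply(layers, function(l) setdiff(l$sample_ids, common)),
               list(survival = setdiff(survival$sample_ids, common)))
  structure(list(
    layers = lapply(layers, subset_omics, ids = common),
    survival = subset_survival(survival, common),
    dropped = dropped
  ), class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat(sprintf("<multi_omics_dataset> %d samples, %d layer(s): %s\n",
              length(x$survival$sample_ids), length(x$layers),
              paste(sprintf("%s[%d]", names(x$layers),
                            vapply(x$layers, function(l) length(l$feature_ids),
                                   integer(1))), collapse = ", ")))
  invisible(x)
}

# Restrict a dataset to a sample subset, preserving canonical (sorted) order.
subset_dataset <- function(dataset, ids) {
  ids <- sort(ids)
  structure(list(
    layers = lapply(dataset$layers, subset_omics, ids = ids),
    survival = subset_survival(dataset$survival, ids),
    dropped = NULL
  ), class = "multi_omics_dataset")
}

OMICSURV_SCHEMA_VERSION <- 1L

#' Save / load a fitted ensemble
#'
#' The archive is a single RDS file with an embedded schema version; loading a
#' file written by an incompatible version raises an explicit error.
#' Predictions of a loaded ensemble are bit-identical to the original.
#'
#' @param ensemble an object of class `omicsurv_ensemble` (see
#'   [fit_ensemble()]).
#' @param path archive path.
#' @return `save_ensemble` returns `path` invisibly; `load_ensemble` the
#'   restored ensemble.
#' @export
save_ensemble <- function(ensemble, path) {
  if (!inherits(ensemble, "omicsurv_ensemble"))
    abort_omicsurv("not an omicsurv_ensemble", "argument")
  saveRDS(list(schema_version = OMICSURV_SCHEMA_VERSION,
               package_version = as.character(utils::packageVersion("omicsurv")),
               ensemble = ensemble),
          path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  if (!file.exists(path))
    abort_omicsurv(sprintf("file not found: %s", path), "io")
  obj <- tryCatch(readRDS(path), error = function(e)
    abort_omicsurv(sprintf("cannot read ensemble archive %s: %s", path,
                           conditionMessage(e)), "archive"))
  if (!is.list(obj) || is.null(obj$schema_version))
    abort_omicsurv(sprintf("%s is not an omicsurv ensemble archive", path),
                   "archive")
  if (obj$schema_version != OMICSURV_SCHEMA_VERSION)
    abort_omicsurv(sprintf(
      "archive schema version %d incompatible with supported version %d",
      obj$schema_version, OMICSURV_SCHEMA_VERSION), "archive")
  obj$ensemble
}
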