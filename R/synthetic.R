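# Synthetic multi-omic cohorts with known subtype structure and survival
# signal, so every pipeline stage is testable without external downloads.
#
# Generative model: subtypes assigned uniformly; informative features are
# Normal(effect_size * subtype_index, 1) per omic (noise features
# Normal(0, 1)); survival times are exponential with hazard
# lambda * HR^subtype_index; censoring times are independent exponential with
# the rate calibrated so the expected censoring fraction hits the target.
# Methylation-like layers (tag "METH") are squashed through a logistic map to
# (0, 1) to exercise per-omic normalization with beta-value-like scales.

#' Specify a synthetic multi-omic cohort
#'
#' @param n_samples cohort size (default 200).
#' @param n_subtypes number of latent subtypes K (default 2).
#' @param omics named list per omic tag: `list(n_features, n_informative)`.
#'   Default: RNA 500/30, MIR 200/20, METH 500/30.
#' @param effect_size mean shift per subtype step, in SD units (default 1).
#' @param baseline_hazard events per day for subtype 0 (default 1/1000).
#' @param hazard_ratio hazard multiplier per subtype step (>= 1, default 3).
#' @param censoring_rate target fraction censored in \[0, 1) (default 0.2).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 200, n_subtypes = 2,
                        omics = list(RNA = list(n_features = 500, n_informative = 30),
                                     MIR = list(n_features = 200, n_informative = 20),
                                     METH = list(n_features = 500, n_informative = 30)),
                        effect_size = 1, baseline_hazard = 1 / 1000,
                        hazard_ratio = 3, censoring_rate = 0.2, seed = 1) {
  for (om in omics)
    if (om$n_informative > om$n_features)
      abort_omicsurv("n_informative cannot exceed n_features", "argument")
  if (hazard_ratio < 1)
    abort_omicsurv("hazard_ratio must be >= 1", "argument")
  if (censoring_rate < 0 || censoring_rate >= 1)
    abort_omicsurv("censoring_rate must be in [0, 1)", "argument")
  structure(list(n_samples = n_samples, n_subtypes = n_subtypes, omics = omics,
                 effect_size = effect_size, baseline_hazard = baseline_hazard,
                 hazard_ratio = hazard_ratio, censoring_rate = censoring_rate,
                 seed = seed),
            class = "cohort_spec")
}

# Censoring rate under C ~ Exp(rc), T ~ Exp(r_s), subtype s uniform:
# P(C < T) = mean_s rc / (rc + r_s); solve for rc by monotone root finding.
calibrate_censoring_rate <- function(rates, target) {
  if (target == 0) return(0)
  f <- function(rc) mean(rc / (rc + rates)) - target
  upper <- max(rates) * 1e6
  if (f(upper) < 0)
    abort_omicsurv("infeasible censoring target", "argument")
  stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param feature_prefix optional per-omic feature id prefix override (used by
#'   [generate_paired_cohorts()]).
#' @return A `synthetic_cohort`: fields `dataset` (a `multi_omics_dataset`),
#'   `subtype` (named 0-based ground-truth vector), `informative_features`
#'   (named list per omic), `spec`.
#' @export
generate_cohort <- function(spec, feature_prefix = NULL) {
  with_seed(spec$seed, {
    n <- spec$n_samples
    ids <- sprintf("S%04d", seq_len(n))
    subtype <- sample.int(spec$n_subtypes, n, replace = TRUE) - 1L
    layers <- vector("list", length(spec$omics))
    names(layers) <- names(spec$omics)
    informative <- vector("list", length(spec$omics))
    names(informative) <- names(spec$omics)
    for (tag in names(spec$omics)) {
      om <- spec$omics[[tag]]
      prefix <- if (!is.null(feature_prefix)) feature_prefix[[tag]] else tag
      fid <- sprintf("%s_f%05d", prefix, seq_len(om$n_features))
      vals <- matrix(stats::rnorm(om$n_features * n), om$n_features, n)
      if (om$n_informative > 0) {
        shift <- outer(rep(spec$effect_size, om$n_informative), subtype)
        vals[seq_len(om$n_informative), ] <-
          vals[seq_len(om$n_informative), , drop = FALSE] + shift
      }
      if (tag == "METH") vals <- 1 / (1 + exp(-vals))    # beta-value-like
      dimnames(vals) <- list(fid, ids)
      layers[[tag]] <- omics_matrix(vals, tag)
      informative[[tag]] <- fid[seq_len(om$n_informative)]
    }
    rate_s <- spec$baseline_hazard * spec$hazard_ratio^subtype
    t_event <- stats::rexp(n, rate_s)
    rc <- calibrate_censoring_rate(
      spec$baseline_hazard * spec$hazard_ratio^(seq_len(spec$n_subtypes) - 1),
      spec$censoring_rate)
    t_cens <- if (rc > 0) stats::rexp(n, rc) else rep(Inf, n)
    time <- pmax(pmin(t_event, t_cens), 1e-6)
    event <- as.numeric(t_event <= t_cens)
    surv <- survival_table(ids, time, event)
    dataset <- align_dataset(layers, surv)
    ord <- match(dataset$survival$sample_ids, ids)
    structure(list(dataset = dataset,
                   subtype = stats::setNames(subtype[ord],
                                             dataset$survival$sample_ids),
                   informative_features = informative,
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, K = %d, HR = %g, %.0f%% events\n",
              x$spec$n_samples, x$spec$n_subtypes, x$spec$hazard_ratio,
              100 * mean(x$dataset$survival$event)))
  invisible(x)
}

#' Generate two cohorts from the same generative process
#'
#' Both cohorts are independent draws from `spec`'s process; a stated fraction
#' of feature ids (taken from the start of each omic's feature list, so
#' informative features are shared first) is common to both, emulating
#' cross-cohort transfer with partial feature overlap.
#'
#' @param spec a [cohort_spec()].
#' @param shared_feature_fraction fraction of feature ids shared, in (0, 1\].
#' @return List of two `synthetic_cohort`s (`cohort_a`, `cohort_b`).
#' @export
generate_paired_cohorts <- function(spec, shared_feature_fraction = 1) {
  if (shared_feature_fraction <= 0 || shared_feature_fraction > 1)
    abort_omicsurv("shared_feature_fraction must be in (0, 1]", "argument")
  seeds <- derive_seeds(spec$seed, 2)
  spec_a <- spec; spec_a$seed <- seeds[1]
  spec_b <- spec; spec_b$seed <- seeds[2]
  a <- generate_cohort(spec_a)
  b <- generate_cohort(spec_b)
  # rename the non-shared tail of each omic's features in cohort b
  for (tag in names(spec$omics)) {
    nf <- spec$omics[[tag]]$n_features
    n_shared <- floor(shared_feature_fraction * nf)
    if (n_shared < nf) {
      om <- b$dataset$layers[[tag]]
      new_ids <- om$feature_ids
      ren <- (n_shared + 1):nf
      new_ids[ren] <- sprintf("%sB_f%05d", tag, ren)
      b$dataset$layers[[tag]] <- omics_matrix(
        `dimnames<-`(om$values, list(new_ids, om$sample_ids)), tag)
      b$informative_features[[tag]] <-
        intersect(b$informative_features[[tag]], new_ids)
    }
  }
  list(cohort_a = a, cohort_b = b)
}

#' Write a synthetic cohort to TSV files
#'
#' One matrix TSV per omic (`<prefix>_<TAG>.tsv`), a survival TSV
#' (`<prefix>_survival.tsv`), and a ground-truth TSV
#' (`<prefix>_truth.tsv`).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (tag in names(cohort$dataset$layers)) {
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, tag))
    write_omics_matrix(cohort$dataset$layers[[tag]], p)
    paths[tag] <- p
  }
  paths["survival"] <- file.path(dir, sprintf("%s_survival.tsv", prefix))
  write_survival(cohort$dataset$survival, paths[["survival"]])
  paths["truth"] <- file.path(dir, sprintf("%s_truth.tsv", prefix))
  utils::write.table(
    data.frame(sample = names(cohort$subtype), subtype = cohort$subtype),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
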