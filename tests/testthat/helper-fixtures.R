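# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# A small 3-omic cohort specification with survival signal.
signal_spec <- function(seed, n = 200, hr = 3, ...) {
  cohort_spec(n_samples = n, hazard_ratio = hr, seed = seed, ...)
}

# Matching null world: no informative features, flat hazard.
null_spec <- function(seed, n = 200) {
  cohort_spec(n_samples = n, hazard_ratio = 1, seed = seed,
              omics = list(RNA = list(n_features = 500, n_informative = 0),
                           MIR = list(n_features = 200, n_informative = 0),
                           METH = list(n_features = 500, n_informative = 0)))
}

# Reduced pipeline configuration for fast unit tests (acceptance tests use
# the defaults).
quick_cfg <- function(...) {
  utils::modifyList(list(hidden = 30, epochs = 3, n_init = 10, top_k = 50),
                    list(...))
}

# Small single-omic cohort for classifier/ensemble unit tests.
tiny_cohort <- function(seed, n = 120) {
  generate_cohort(cohort_spec(
    n_samples = n, seed = seed,
    omics = list(RNA = list(n_features = 120, n_informative = 25),
                 MIR = list(n_features = 80, n_informative = 15))))
}

# Random survival table (continuous times -> no ties).
random_survival <- function(n, censor = 0.3, seed = 1) {
  withr::with_seed(seed, {
    time <- rexp(n, 1 / 500)
    cens <- rbinom(n, 1, censor)
    survival_table(sprintf("s%03d", seq_len(n)), time, 1 - cens)
  })
}

# Internal functions referenced through the namespace.
cox_screen_ref <- function(...) omicsurv:::cox_screen(...)
subset_survival_ids <- function(sv, ids) omicsurv:::subset_survival(sv, ids)

# Brute-force Harrell C oracle: O(n^2) enumeration of comparable pairs.
c_index_oracle <- function(risk, surv) {
  t <- surv$time; e <- surv$event
  conc <- 0; n_comp <- 0
  n <- length(t)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (t[i] < t[j] && e[i] == 1) {       # i fails first, observed
      n_comp <- n_comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / n_comp
}

# Pair-counting ARI oracle (independent of the contingency-table formula).
ari_oracle <- function(a, b) {
  n <- length(a)
  s11 <- 0; s00 <- 0; s10 <- 0; s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# Naive silhouette oracle with explicit loops.
silhouette_oracle <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  mean(vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

read_tsv_layers <- function(omic_paths) {
  layers <- lapply(names(omic_paths), function(tag)
    load_omics_matrix(omic_paths[[tag]], tag))
  setNames(layers, names(omic_paths))
}

write_tsv_matrix <- function(values, path) {
  df <- data.frame(feature = rownames(values), values, check.names = FALSE)
  colnames(df) <- c("feature", colnames(values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
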