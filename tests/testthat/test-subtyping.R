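# Latent-feature selection, GMM clustering, survival ordering, and clustering
# quality metrics.

test_that("survival feature selection keeps signal and respects alpha", {
  n <- 200
  sv <- random_survival(n, censor = 0.2, seed = 31)
  withr::with_seed(31, {
    Z <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(sv$sample_ids, paste0("RNA.", 1:20)))
    Z[, 1] <- -log(sv$time) + rnorm(n, sd = 0.3)  # strong survival signal
  })
  lat <- structure(list(sample_ids = sv$sample_ids,
                        latent_ids = colnames(Z), values = Z,
                        omic_tag = "RNA"), class = "latent_matrix")
  sel <- select_survival_features(lat, sv, alpha = 0.01)
  expect_true("RNA.1" %in% sel$provenance$latent_id)
  expect_true(all(sel$provenance$p_value < 0.01))
  sel_all <- select_survival_features(lat, sv, alpha = 1)
  expect_equal(sel_all$n_retained, 20)
  # pure-noise retention stays near the binomial expectation at alpha = 0.01
  total <- 0
  for (s in 1:20) {
    svs <- random_survival(150, censor = 0.2, seed = 600 + s)
    Zs <- withr::with_seed(700 + s,
      matrix(rnorm(150 * 100), 150, 100,
             dimnames = list(svs$sample_ids, paste0("RNA.", 1:100))))
    lats <- structure(list(sample_ids = svs$sample_ids,
                           latent_ids = colnames(Zs), values = Zs,
                           omic_tag = "RNA"), class = "latent_matrix")
    total <- total + select_survival_features(lats, svs)$n_retained
  }
  # 2000 null tests at alpha 0.01: 99% binomial bounds around 20
  expect_gte(total, 8)
  expect_lte(total, 36)
})

test_that("GMM recovers separated blobs deterministically", {
  withr::with_seed(41, {
    X <- rbind(matrix(rnorm(60 * 3), 60, 3),
               matrix(rnorm(60 * 3, mean = 6), 60, 3))
  })
  truth <- rep(1:2, each = 60)
  lab <- cluster_subtypes(X, K = 2, seed = 1, n_init = 10)
  expect_equal(adjusted_rand_index(lab, truth), 1)
  lab2 <- cluster_subtypes(X, K = 2, seed = 1, n_init = 10)
  expect_identical(lab, lab2)
  # K = 2 on 3-blob data still assigns everyone to two clusters
  X3 <- rbind(X, matrix(rnorm(30 * 3, mean = 12), 30, 3))
  lab3 <- cluster_subtypes(X3, K = 2, seed = 2, n_init = 10)
  expect_setequal(unique(lab3), 1:2)
  expect_error(cluster_subtypes(matrix(1, 30, 3), K = 2),
               class = "omicsurv_degenerate_error")
  # k-means backend agrees on trivially separated blobs
  labk <- cluster_subtypes(X, K = 2, method = "kmeans", seed = 1)
  expect_equal(adjusted_rand_index(labk, truth), 1)
})

test_that("labels are ordered by KM median survival, worst first", {
  # two clusters with medians ~100 vs ~500 days
  sv <- withr::with_seed(61, survival_table(
    sprintf("s%d", 1:40),
    c(rexp(20, 1 / 100) + 1, rexp(20, 1 / 500) + 1),
    rep(1, 40)))
  raw <- rep(c(1, 2), each = 20)
  lb <- order_labels_by_survival(raw, sv)
  expect_equal(unique(lb$ordered_labels[1:20]), 0)
  expect_true(all(diff(lb$median_survival_per_label) >= 0))
  # K = 3 permutation: medians (300, 100, 200) -> mapping (1->0, 2->1, 0->2)
  sv3 <- survival_table(sprintf("s%d", 1:30),
                        rep(c(300, 100, 200), each = 10), rep(1, 30))
  lb3 <- order_labels_by_survival(rep(c(0, 1, 2), each = 10), sv3)
  expect_equal(unique(lb3$ordered_labels[1:10]), 2)
  expect_equal(unique(lb3$ordered_labels[11:20]), 0)
  expect_equal(unique(lb3$ordered_labels[21:30]), 1)
  # exact median tie: deterministic, smaller group becomes label 0
  svt <- survival_table(sprintf("s%d", 1:15), rep(100, 15), rep(1, 15))
  expect_warning(lbt <- order_labels_by_survival(rep(c(1, 2), c(5, 10)), svt),
                 "tie")
  expect_equal(unique(lbt$ordered_labels[1:5]), 0)
})

test_that("silhouette matches a direct O(n^2) oracle", {
  withr::with_seed(51, {
    for (rep in 1:5) {
      X <- matrix(rnorm(40 * 4), 40, 4)
      labels <- sample(1:3, 40, replace = TRUE)
      expect_equal(silhouette_score(X, labels), silhouette_oracle(X, labels),
                   tolerance = 1e-12)
    }
  })
  expect_error(silhouette_score(matrix(rnorm(20), 10, 2), rep(1, 10)),
               class = "omicsurv_degenerate_error")
})

test_that("ARI matches the pair-counting oracle and its invariances", {
  x <- c(0, 0, 1, 1, 2)
  expect_equal(adjusted_rand_index(x, x), 1)
  expect_equal(adjusted_rand_index(x, c(5, 5, 9, 9, 7)), 1)  # renaming
  withr::with_seed(52, {
    for (rep in 1:25) {
      n <- sample(8:30, 1)
      a <- sample(1:3, n, replace = TRUE)
      b <- sample(1:4, n, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b),
                   tolerance = 1e-12)
    }
  })
  # stability = mean of pairwise ARIs
  l <- list(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 2, 1, 2))
  expected <- mean(c(adjusted_rand_index(l[[1]], l[[2]]),
                     adjusted_rand_index(l[[1]], l[[3]]),
                     adjusted_rand_index(l[[2]], l[[3]])))
  expect_equal(clustering_stability(l), expected)
})

test_that("worst-survival label has the higher event rate on signal cohorts", {
  hits <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_spec(
      n_samples = 120, seed = 800 + s,
      omics = list(RNA = list(n_features = 150, n_informative = 30))))
    sv <- co$dataset$survival
    raw <- co$subtype + 1L
    lb <- order_labels_by_survival(raw, sv)
    worst <- lb$ordered_labels == 0
    mean(sv$event[worst]) > mean(sv$event[!worst])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
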