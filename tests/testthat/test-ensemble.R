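# Bagging ensemble: determinism, filtering, aggregation, hold-out evaluation,
# transfer. Unit scale (small cohorts, reduced config); full-scale behavior is
# covered by the acceptance tests.

test_that("ensemble fitting is deterministic and filters are recorded", {
  co <- tiny_cohort(81)
  e1 <- fit_ensemble(co$dataset, K = 2, n_models = 3, seed = 8,
                     config = quick_cfg())
  e2 <- fit_ensemble(co$dataset, K = 2, n_models = 3, seed = 8,
                     config = quick_cfg())
  p1 <- predict_ensemble(e1, co$dataset$layers)
  p2 <- predict_ensemble(e2, co$dataset$layers)
  expect_identical(p1$probabilities, p2$probabilities)
  expect_identical(p1$labels, p2$labels)
  expect_length(e1$all_model_reasons, 3)
  # training/hold-out splits partition the cohort
  for (m in e1$models) {
    expect_length(intersect(m$train_ids, m$holdout_ids), 0)
    expect_setequal(c(m$train_ids, m$holdout_ids),
                    co$dataset$survival$sample_ids)
  }
})

test_that("single-model full-sample ensemble is the identity aggregation", {
  co <- tiny_cohort(82)
  ens <- fit_ensemble(co$dataset, K = 2, n_models = 1, subsample = 1,
                      seed = 9, config = quick_cfg())
  expect_length(ens$models, 1)
  expect_length(ens$models[[1]]$holdout_ids, 0)
  pred <- predict_ensemble(ens, co$dataset$layers)
  sub_pred <- omicsurv:::predict_submodel(ens$models[[1]], co$dataset$layers)
  expect_equal(unname(pred$probabilities[, "0"]),
               unname(sub_pred$probabilities[, "0"]))
})

test_that("aggregated probabilities are convex combinations of model outputs", {
  co <- tiny_cohort(83)
  ens <- fit_ensemble(co$dataset, K = 2, n_models = 3, seed = 10,
                      config = quick_cfg())
  per <- lapply(ens$models, function(m)
    omicsurv:::predict_submodel(m, co$dataset$layers)$probabilities[, "0"])
  agg <- predict_ensemble(ens, co$dataset$layers)
  lo <- do.call(pmin, per); hi <- do.call(pmax, per)
  expect_true(all(agg$probabilities[, "0"] >= lo - 1e-12))
  expect_true(all(agg$probabilities[, "0"] <= hi + 1e-12))
  expect_true(all(abs(rowSums(agg$probabilities) - 1) < 1e-9))
  # risk score = worst-class probability; K = 2 label rule
  expect_identical(unname(agg$labels),
                   unname(ifelse(agg$risk > 0.5, "0", "1")))
})

test_that("filter_models applies the survival-association rule", {
  mk <- function(valid, reason = NULL)
    structure(list(valid = valid, reason = reason),
              class = "omicsurv_submodel")
  kept <- filter_models(list(mk(TRUE), mk(FALSE, "no survival features"),
                             mk(FALSE, "labels not survival-associated"),
                             mk(TRUE)))
  expect_length(kept, 2)
  expect_length(filter_models(list(mk(FALSE, "no survival features"))), 0)
})

test_that("hold-out metrics report is fully populated on signal cohorts", {
  co <- tiny_cohort(84)
  ens <- fit_ensemble(co$dataset, K = 2, n_models = 3, seed = 11,
                      config = quick_cfg())
  m <- ens$metrics
  expect_s3_class(m, "metrics_report")
  expect_true(is.finite(m$c_index))
  expect_true(is.finite(m$logrank_p))
  expect_true(is.finite(m$silhouette))
  expect_equal(m$K, 2)
  expect_equal(m$n_retained_models, length(ens$models))
  expect_gt(m$oob_n, 0)
})

test_that("cross-cohort transfer works and fails typed on foreign features", {
  pair <- generate_paired_cohorts(cohort_spec(
    n_samples = 120, seed = 85,
    omics = list(RNA = list(n_features = 150, n_informative = 30),
                 MIR = list(n_features = 100, n_informative = 20))),
    shared_feature_fraction = 0.7)
  ens <- fit_ensemble(pair$cohort_a$dataset, K = 2, n_models = 3, seed = 12,
                      config = quick_cfg())
  tr <- cross_cohort_predict(ens, pair$cohort_b$dataset)
  expect_equal(tr$n_scored, 120)
  expect_true(is.finite(tr$c_index))
  # a cohort sharing no features at all cannot be scored
  alien <- generate_cohort(cohort_spec(
    n_samples = 50, seed = 86,
    omics = list(RNA = list(n_features = 60, n_informative = 10))))
  lay <- alien$dataset$layers$RNA
  renamed <- omics_matrix(`rownames<-`(lay$values,
                                       paste0("zz_", lay$feature_ids)), "RNA")
  alien$dataset$layers$RNA <- renamed
  expect_error(cross_cohort_predict(ens, alien$dataset),
               class = "omicsurv_error")
})

test_that("weighting by hold-out concordance remains a valid aggregation", {
  co <- tiny_cohort(87)
  ens <- fit_ensemble(co$dataset, K = 2, n_models = 3, seed = 13,
                      config = quick_cfg())
  pw <- predict_ensemble(ens, co$dataset$layers, weight_by_c_index = TRUE)
  expect_true(all(abs(rowSums(pw$probabilities) - 1) < 1e-9))
})
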