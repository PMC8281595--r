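# Containers, TSV I/O, alignment, and archive round trips.

test_that("omics matrix TSV round trip preserves values and order", {
  m <- matrix(1:6, nrow = 3, dimnames = list(c("g1", "g2", "g3"),
                                             c("sampA", "sampB")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_matrix(m, path)
  om <- load_omics_matrix(path, "RNA")
  expect_s3_class(om, "omics_matrix")
  expect_identical(dim(om$values), c(3L, 2L))
  expect_identical(om$feature_ids, c("g1", "g2", "g3"))
  expect_identical(om$sample_ids, c("sampA", "sampB"))
  expect_equal(om$values, `storage.mode<-`(m, "double"))
  # write -> load round trip is exact, including non-integer doubles
  om$values[2, 1] <- pi
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(om, p2)
  om2 <- load_omics_matrix(p2, "RNA")
  expect_identical(om2$values, om$values)
})

test_that("duplicate feature ids keep first occurrence with a warning", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("g1", "g1", "g2"), c("a", "b")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_matrix(m, path)
  expect_warning(om <- load_omics_matrix(path, "RNA"), "duplicated feature")
  expect_identical(om$feature_ids, c("g1", "g2"))
  expect_equal(om$values["g1", ], c(a = 1, b = 4))   # first occurrence kept
})

test_that("non-numeric and missing cells are rejected naming the cell", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2", "g1\t1\t2", "g2\tNA\t4"), path)
  err <- expect_error(load_omics_matrix(path, "RNA"),
                      class = "omicsurv_parse_error")
  expect_match(conditionMessage(err), "g2")
  expect_match(conditionMessage(err), "s1")
  writeLines(c("feature\ts1\ts2", "g1\t1\tfoo"), path)
  expect_error(load_omics_matrix(path, "RNA"),
               class = "omicsurv_parse_error")
  # median imputation flag rescues NA cells
  writeLines(c("feature\ts1\ts2\ts3", "g1\tNA\t2\t4"), path)
  om <- load_omics_matrix(path, "RNA", impute_missing = TRUE)
  expect_equal(unname(om$values[1, 1]), 3)
})

test_that("survival table loads, coerces events, and validates times", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tdays\tevent", "a\t100\t1", "b\t200\t0", "c\t300\t1"),
             path)
  st <- load_survival(path)
  expect_equal(sum(st$event), 2)
  expect_equal(st$time, c(100, 200, 300))
  # all-censored is valid at load time
  st0 <- survival_table(c("a", "b"), c(10, 20), c(0, 0))
  expect_equal(sum(st0$event), 0)
  # non-positive time names the sample
  err <- expect_error(survival_table(c("a", "b"), c(0, 20), c(1, 0)),
                      class = "omicsurv_validation_error")
  expect_match(conditionMessage(err), "a")
  # custom column names
  writeLines(c("id\tt\td", "x\t5\tTRUE"), path)
  st2 <- load_survival(path, sample_col = "id", time_col = "t",
                       event_col = "d")
  expect_equal(st2$event, 1)
})

test_that("alignment intersects samples, sorts them, and is idempotent", {
  m1 <- omics_matrix(matrix(rnorm(9), 3, dimnames = list(paste0("g", 1:3),
                                                         c("A", "B", "C"))), "RNA")
  m2 <- omics_matrix(matrix(rnorm(9), 3, dimnames = list(paste0("m", 1:3),
                                                         c("B", "C", "D"))), "MIR")
  sv <- survival_table(c("A", "B", "C", "D"), c(1, 2, 3, 4), c(1, 1, 0, 1))
  ds <- align_dataset(list(m1, m2), sv)
  expect_identical(ds$survival$sample_ids, c("B", "C"))
  expect_identical(ds$layers$RNA$sample_ids, c("B", "C"))
  expect_identical(ds$dropped$RNA, "A")
  ds2 <- align_dataset(ds$layers, ds$survival)
  expect_identical(ds2$layers, ds$layers)
  expect_identical(ds2$survival, ds$survival)
  # identical sample sets: nothing dropped
  ds3 <- align_dataset(list(m2), survival_table(c("B", "C", "D"), 1:3, c(1, 0, 1)))
  expect_length(unlist(ds3$dropped), 0)
  # disjoint sets fail
  m3 <- omics_matrix(matrix(1:2, 1, dimnames = list("g", c("X", "Y"))), "RNA")
  expect_error(align_dataset(list(m3), sv), class = "omicsurv_alignment_error")
})

test_that("ensemble archive round trip preserves predictions bit-identically", {
  co <- tiny_cohort(5)
  ens <- fit_ensemble(co$dataset, K = 2, n_models = 2, seed = 5,
                      config = quick_cfg())
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(ens, path)
  ens2 <- load_ensemble(path)
  p1 <- predict_ensemble(ens, co$dataset$layers)
  p2 <- predict_ensemble(ens2, co$dataset$layers)
  expect_identical(p1$probabilities, p2$probabilities)
  expect_identical(p1$labels, p2$labels)
  # re-save and compare archives structurally
  path2 <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(ens2, path2)
  expect_equal(readRDS(path)$ensemble, readRDS(path2)$ensemble)
  # truncated archive errors cleanly
  trunc <- withr::local_tempfile(fileext = ".rds")
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[seq_len(floor(length(raw) / 3))], trunc)
  expect_error(load_ensemble(trunc), class = "omicsurv_archive_error")
  # schema version mismatch is explicit
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(schema_version = 999L, ensemble = NULL), bad)
  expect_error(load_ensemble(bad), class = "omicsurv_archive_error")
})
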