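# Differential features of the worst subtype, pan-dataset ranking, and
# consensus co-expression networks.

mk_labeling <- function(labels, ids) {
  structure(list(sample_ids = ids, raw_labels = labels,
                 ordered_labels = labels, K = length(unique(labels)),
                 median_survival_per_label = NULL),
            class = "subtype_labeling")
}

de_fixture <- function(seed = 91, n = 100, p = 40) {
  withr::with_seed(seed, {
    ids <- sprintf("s%03d", 1:n)
    lab <- rep(c(0L, 1L), each = n / 2)
    vals <- matrix(rnorm(p * n), p, n,
                   dimnames = list(sprintf("gene%02d", 1:p), ids))
    vals[1, ] <- lab * 3 + rnorm(n, sd = 0.1)       # over in worst group
    vals[2, ] <- -lab * 3 + rnorm(n, sd = 0.1)      # under in worst group
    vals[3, ] <- 7                                   # identical across groups
    # worst group (label 0) is the SECOND half so direction uses label 0
    lab <- rev(lab)
    sv <- survival_table(ids, rexp(n, 1 / 300) + 1, rbinom(n, 1, 0.8))
    list(layer = omics_matrix(vals, "RNA"), labeling = mk_labeling(lab, ids),
         survival = sv, lab = lab)
  })
}

test_that("differential features find planted effects with directions", {
  fx <- de_fixture()
  de <- differential_features(fx$layer, fx$labeling, fx$survival)
  expect_true(all(c("gene01", "gene02") %in% de$features$feature))
  expect_equal(de$features$direction[de$features$feature == "gene01"], "over")
  expect_equal(de$features$direction[de$features$feature == "gene02"], "under")
  expect_false("gene03" %in% de$features$feature)
  expect_true(all(de$features$wilcoxon_p < 0.001))
  # p-values agree with the stats oracle
  worst <- fx$labeling$ordered_labels == 0
  for (g in de$features$feature[1:2]) {
    v <- fx$layer$values[g, ]
    ref <- wilcox.test(v[worst], v[!worst], exact = FALSE,
                       correct = FALSE)$p.value
    expect_equal(de$features$wilcoxon_p[de$features$feature == g], ref,
                 tolerance = 1e-10)
  }
  expect_error(differential_features(fx$layer,
                                     mk_labeling(rep(c(0L, 1L), c(2, 98)),
                                                 fx$labeling$sample_ids),
                                     fx$survival),
               class = "omicsurv_argument_error")
})

test_that("pan-dataset ranking min-max normalizes and sums across datasets", {
  mk_de <- function(features, cox_p) {
    nr <- if (length(cox_p) == 1) 1 else {
      r <- -log10(cox_p)
      (r - min(r)) / (max(r) - min(r))
    }
    structure(list(features = data.frame(
      feature = features, direction = "over", wilcoxon_p = 1e-5,
      cox_p = cox_p, norm_rank = nr), omic_tag = "RNA", threshold = 0.001),
      class = "differential_feature_set")
  }
  one <- mk_de(c("a", "b"), c(1e-6, 1e-2))
  sc <- pan_dataset_rank(list(d1 = one))
  expect_equal(sc$score[sc$feature == "a"], 1)
  expect_equal(sc$score[sc$feature == "b"], 0)
  # a feature always ranked best across 3 datasets scores 3
  sc3 <- pan_dataset_rank(list(d1 = one, d2 = one, d3 = one))
  expect_equal(sc3$score[sc3$feature == "a"], 3)
  # random p-values match a brute-force recomputation
  withr::with_seed(92, {
    sets <- lapply(1:3, function(i) {
      f <- sample(letters[1:10], 6)
      mk_de(f, runif(6, 1e-8, 1e-3))
    })
  })
  sc_r <- pan_dataset_rank(setNames(sets, paste0("d", 1:3)))
  brute <- sapply(letters[1:10], function(f)
    sum(vapply(sets, function(s) {
      i <- match(f, s$features$feature)
      if (is.na(i)) 0 else s$features$norm_rank[i]
    }, numeric(1))))
  brute <- brute[brute > 0]
  expect_equal(setNames(sc_r$score, sc_r$feature)[names(sort(-brute))],
               sort(brute, decreasing = TRUE))
})

test_that("co-expression networks score correlated genes and prune properly", {
  fx <- de_fixture(seed = 93)
  # plant two perfectly correlated genes among the differential ones
  fx$layer$values[1, ] <- fx$lab * 3
  fx$layer$values[2, ] <- fx$lab * 6 + 1
  de <- differential_features(fx$layer, fx$labeling, fx$survival)
  net <- build_coexpression_network(fx$layer, de, top_n = 10)
  w12 <- net$edges$weight[(net$edges$from == "gene01" &
                             net$edges$to == "gene02") |
                            (net$edges$from == "gene02" &
                               net$edges$to == "gene01")]
  expect_equal(w12, 1)
  # node score = sum of incident normalized weights
  for (g in net$nodes$feature) {
    inc <- net$edges$weight[net$edges$from == g | net$edges$to == g]
    expect_equal(net$nodes$score[net$nodes$feature == g], sum(inc),
                 tolerance = 1e-12)
  }
  # constant gene is dropped with a warning
  de2 <- de
  de2$features <- rbind(de2$features[1:2, ],
                        within(de2$features[1, ], feature <- "gene04"))
  fx$layer$values[4, ] <- 5                # constant gene injected
  expect_warning(net2 <- build_coexpression_network(fx$layer, de2, top_n = 10),
                 "constant")
  expect_false("gene04" %in% net2$nodes$feature)
})

test_that("consensus network sums weights, prunes top-k, finds communities", {
  fx <- de_fixture(seed = 94)
  de <- differential_features(fx$layer, fx$labeling, fx$survival,
                              p_threshold = 0.05)
  net <- build_coexpression_network(fx$layer, de, top_n = 15)
  # identity transform when limits exceed the graph, plus communities
  cons1 <- consensus_network(list(net), top_nodes = 100,
                             max_edges_per_node = 1000)
  expect_setequal(cons1$nodes$feature, net$nodes$feature)
  expect_equal(nrow(cons1$edges), nrow(net$edges))
  expect_true(all(names(cons1$communities) %in% net$nodes$feature))
  # two identical graphs double every weight
  cons2 <- consensus_network(list(net, net), top_nodes = 100,
                             max_edges_per_node = 1000)
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  m <- match(key(net$edges), key(cons2$edges))
  expect_equal(cons2$edges$weight[m], 2 * net$edges$weight)
  # pruning respects the kept-by-either-endpoint rule on a star + clique mix
  cons3 <- consensus_network(list(net), top_nodes = 100,
                             max_edges_per_node = 3)
  for (v in cons3$nodes$feature) {
    inc_w <- cons3$edges$weight[cons3$edges$from == v | cons3$edges$to == v]
    all_w <- net$edges$weight[net$edges$from == v | net$edges$to == v]
    # every kept edge at v either ranks in v's own top 3 or in the top 3 of
    # its other endpoint; v's own top-3 edges must all survive
    top3 <- sort(all_w, decreasing = TRUE)[seq_len(min(3, length(all_w)))]
    expect_true(all(top3 %in% inc_w))
  }
})

test_that("walktrap recovers a planted two-block consensus graph", {
  withr::with_seed(95, {
    blocks <- rep(1:2, each = 8)
    nodes <- sprintf("n%02d", 1:16)
    edges <- do.call(rbind, lapply(1:15, function(i)
      do.call(rbind, lapply((i + 1):16, function(j) {
        w <- if (blocks[i] == blocks[j]) runif(1, 0.8, 1) else runif(1, 0, 0.05)
        data.frame(from = nodes[i], to = nodes[j], weight = w)
      }))))
    g <- structure(list(
      nodes = data.frame(feature = nodes, score = 1),
      edges = edges, communities = NULL), class = "coexpression_graph")
    cons <- consensus_network(list(g), top_nodes = 16,
                              max_edges_per_node = 10)
    memb <- cons$communities[nodes]
    expect_equal(adjusted_rand_index(memb, blocks), 1)
  })
})
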