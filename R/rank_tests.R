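# Vectorized rank tests used in per-feature loops: two-group Wilcoxon
# rank-sum and K-group Kruskal-Wallis, both as chi-square / normal
# approximations with tie correction and no continuity correction (matching
# stats::wilcox.test(exact = FALSE, correct = FALSE) and
# stats::kruskal.test, which serve as independent oracles in the test suite).

#' Two-group Wilcoxon rank-sum test, vectorized over features
#'
#' Normal approximation with tie correction, no continuity correction,
#' two-sided. Operates on a features x samples matrix and a logical group
#' indicator over samples.
#'
#' @param values numeric matrix (features x samples).
#' @param in_group logical vector over samples defining the first group.
#' @return List with per-feature vectors `p_value`, `statistic` (rank-sum W of
#'   the first group minus its null expectation, z-scaled), and `delta_median`
#'   (median(group) - median(rest)).
#' @export
wilcoxon_matrix <- function(values, in_group) {
  values <- as.matrix(values)
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  if (n1 < 1 || n2 < 1)
    abort_omicsurv("both groups must be non-empty", "argument")
  ranks <- t(apply(values, 1, rank, ties.method = "average"))
  if (nrow(values) == 1L) ranks <- matrix(ranks, nrow = 1)
  r1 <- rowSums(ranks[, in_group, drop = FALSE])
  # tie correction: sum over tie groups of (t^3 - t), per feature
  tie_term <- apply(values, 1, function(v) {
    t <- rle(sort(v))$lengths; sum(t^3 - t)
  })
  mu <- n1 * (n + 1) / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (r1 - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 == 0] <- 1                      # all values tied
  med1 <- apply(values[, in_group, drop = FALSE], 1, stats::median)
  med2 <- apply(values[, !in_group, drop = FALSE], 1, stats::median)
  list(p_value = unname(p), statistic = unname(z),
       delta_median = unname(med1 - med2))
}

#' Kruskal-Wallis test, vectorized over features
#'
#' Tie-corrected chi-square approximation with `nlevels - 1` degrees of
#' freedom, identical to [stats::kruskal.test()].
#'
#' @param values numeric matrix (features x samples).
#' @param groups factor (or coercible) over samples.
#' @return List with per-feature `p_value` and `statistic`.
#' @export
kruskal_matrix <- function(values, groups) {
  values <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    abort_omicsurv("Kruskal-Wallis needs >= 2 groups", "argument")
  n <- ncol(values)
  ranks <- t(apply(values, 1, rank, ties.method = "average"))
  if (nrow(values) == 1L) ranks <- matrix(ranks, nrow = 1)
  ng <- as.vector(table(groups))
  # per-feature per-group rank sums: features x groups
  gs <- t(rowsum(t(ranks), groups))
  H <- (12 / (n * (n + 1))) * rowSums(sweep(gs^2, 2, ng, "/")) - 3 * (n + 1)
  tie_term <- apply(values, 1, function(v) {
    t <- rle(sort(v))$lengths; sum(t^3 - t)
  })
  corr <- 1 - tie_term / (n^3 - n)
  H <- ifelse(corr > 0, H / corr, NA_real_)
  p <- stats::pchisq(H, df = nlevels(groups) - 1, lower.tail = FALSE)
  p[is.na(H)] <- 1                         # all values tied -> no information
  list(p_value = unname(p), statistic = unname(H))
}
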