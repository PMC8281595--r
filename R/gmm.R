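# Diagonal-covariance Gaussian mixture model fit by EM, best of many seeded
# initializations — the default subtype clustering primitive (1000 maximum
# iterations and 100 initializations by default).

log_gauss_diag <- function(X, mu, var, X2 = X^2) {
  # X: n x p, mu: K x p, var: K x p -> n x K log densities, via two GEMMs:
  # -(1/2) sum_j (x_j - mu_j)^2 / v_j expanded into quadratic/linear/const.
  p <- ncol(X)
  A <- X2 %*% t(1 / (2 * var))
  B <- X %*% t(mu / var)
  cst <- -0.5 * (rowSums(log(var)) + p * log(2 * pi) + rowSums(mu^2 / var))
  sweep(B - A, 2, cst, "+")
}

logsumexp_rows <- function(M) {
  mx <- M[, 1]
  for (k in seq_len(ncol(M))[-1]) mx <- pmax(mx, M[, k])
  mx + log(rowSums(exp(M - mx)))
}

gmm_em_once <- function(X, K, max_iter, tol, reg_covar, X2 = X^2) {
  n <- nrow(X); p <- ncol(X)
  mu <- X[sample.int(n, K), , drop = FALSE]
  gvar <- apply(X, 2, stats::var) + reg_covar
  var <- matrix(rep(gvar, each = K), K, p)
  wt <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- sweep(log_gauss_diag(X, mu, var, X2), 2, log(wt), "+")
    lse <- logsumexp_rows(lp)
    ll <- sum(lse)
    R <- exp(lp - lse)                     # responsibilities n x K
    nk <- colSums(R) + 1e-10
    wt <- nk / n
    mu <- sweep(t(R) %*% X, 1, nk, "/")
    var <- sweep(t(R) %*% X2, 1, nk, "/") - mu^2 + reg_covar
    # convergence on the change of the mean per-sample log-likelihood
    if (abs(ll - ll_old) / n < tol) break
    ll_old <- ll
  }
  lp <- sweep(log_gauss_diag(X, mu, var, X2), 2, log(wt), "+")
  ll <- sum(logsumexp_rows(lp))
  list(loglik = ll, means = mu, variances = var, weights = wt,
       labels = max.col(lp))
}

#' Fit a diagonal-covariance Gaussian mixture model
#'
#' EM with diagonal covariances; the best of `n_init` seeded random
#' initializations (means drawn from the data rows) by final log-likelihood is
#' returned. Deterministic given `seed`.
#'
#' @param X numeric matrix, samples x features.
#' @param K number of components (>= 2).
#' @param n_init number of initializations (default 100).
#' @param max_iter maximum EM iterations per initialization (default 1000).
#' @param seed RNG seed.
#' @param tol convergence tolerance on the change of the mean per-sample
#'   log-likelihood (default 1e-3, the usual EM default).
#' @param reg_covar variance floor added to every diagonal entry.
#' @return List with `labels` (1..K), `loglik`, `means`, `variances`,
#'   `weights`.
#' @export
fit_gmm_diag <- function(X, K, n_init = 100, max_iter = 1000, seed = 1,
                         tol = 1e-3, reg_covar = 1e-6) {
  X <- as.matrix(X)
  if (K < 2) abort_omicsurv("K must be >= 2", "argument")
  if (nrow(X) <= K)
    abort_omicsurv("need more samples than mixture components", "argument")
  if (all(apply(X, 2, stats::sd) == 0))
    abort_omicsurv("degenerate input: all rows identical, clustering undefined",
                   "degenerate")
  X2 <- X^2
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      fit <- gmm_em_once(X, K, max_iter, tol, reg_covar, X2)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best
  })
}
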