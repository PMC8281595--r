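# Reusable survival statistics: univariate Cox proportional hazards, K-group
# log-rank test, Harrell's concordance index, and a vectorized univariate Cox
# screen used to filter hundreds of latent features quickly.

surv_object <- function(survival) {
  survival::Surv(survival$time, survival$event)
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ covariate` by partial-likelihood maximization
#' (Efron tie handling) and reports the likelihood-ratio p-value. A constant
#' covariate carries no information: coefficient 0, p-value 1,
#' `converged = FALSE`.
#'
#' @param covariate numeric vector, one value per sample.
#' @param survival a [survival_table()].
#' @return List with `coefficient` (log hazard ratio), `standard_error`,
#'   `p_value` (likelihood-ratio test), `converged`.
#' @export
fit_univariate_coxph <- function(covariate, survival) {
  if (length(covariate) != length(survival$sample_ids))
    abort_omicsurv("covariate length must equal sample count", "argument")
  if (sum(survival$event) < 1)
    abort_omicsurv("Cox model needs at least one observed event", "degenerate")
  if (stats::sd(covariate) == 0)
    return(list(coefficient = 0, standard_error = NA_real_, p_value = 1,
                converged = FALSE))
  fit <- tryCatch(
    survival::coxph(surv_object(survival) ~ covariate, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(surv_object(survival) ~ covariate,
                                       ties = "efron"))
    })
  if (is.null(fit) || anyNA(stats::coef(fit)))
    return(list(coefficient = 0, standard_error = NA_real_, p_value = 1,
                converged = FALSE))
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  list(coefficient = unname(stats::coef(fit)),
       standard_error = unname(sqrt(diag(fit$var))),
       p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       converged = TRUE)
}

# Vectorized univariate Cox screen: likelihood-ratio p-value per column of Z.
# Exact Newton iterations on the untied partial likelihood (equals
# Breslow = Efron when event times are unique); falls back to
# fit_univariate_coxph per column when event times are tied. Used for
# latent-feature filtering where hundreds of columns are screened per model.
cox_screen <- function(Z, survival, iter_max = 25, tol = 1e-9) {
  Z <- as.matrix(Z)
  n <- nrow(Z); p <- ncol(Z)
  ev_times <- survival$time[survival$event == 1]
  if (anyDuplicated(ev_times) || sum(survival$event) < 1) {
    res <- apply(Z, 2, function(z) {
      f <- fit_univariate_coxph(z, survival)
      c(f$coefficient, f$p_value)
    })
    return(list(coefficient = res[1, ], p_value = res[2, ]))
  }
  ord <- order(survival$time)                     # increasing time
  X <- Z[ord, , drop = FALSE]
  ev <- survival$event[ord] == 1
  const <- apply(X, 2, stats::sd) == 0
  beta <- numeric(p)
  # centered covariates keep exp() well-conditioned
  X <- sweep(X, 2, colMeans(X), "-")
  loglik_at <- function(beta) {
    eta <- sweep(X, 2, beta, "*")                 # n x p: beta_j * x_ij
    w <- exp(eta)
    # risk set of sample i = samples with time >= t_i -> reverse cumsum
    S0 <- apply(w[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
    colSums(eta[ev, , drop = FALSE]) - colSums(log(S0[ev, , drop = FALSE]))
  }
  ll0 <- loglik_at(numeric(p))
  for (it in seq_len(iter_max)) {
    eta <- sweep(X, 2, beta, "*")
    w <- exp(pmin(eta, 500))
    rev_cumsum <- function(M) apply(M[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
    S0 <- rev_cumsum(w)
    S1 <- rev_cumsum(w * X)
    S2 <- rev_cumsum(w * X^2)
    xbar <- S1 / S0
    U <- colSums(X[ev, , drop = FALSE] - xbar[ev, , drop = FALSE])
    I <- colSums(S2[ev, , drop = FALSE] / S0[ev, , drop = FALSE] -
                   xbar[ev, , drop = FALSE]^2)
    step <- ifelse(I > 0, U / I, 0)
    step <- pmin(pmax(step, -2), 2)               # damped Newton
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  ll1 <- loglik_at(beta)
  lrt <- pmax(2 * (ll1 - ll0), 0)
  pv <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  pv[const] <- 1; beta[const] <- 0
  list(coefficient = beta, p_value = pv)
}

#' K-group log-rank test
#'
#' Standard log-rank chi-square statistic comparing the survival curves of the
#' groups defined by `labels`; degrees of freedom = (number of non-empty
#' groups) - 1. Empty levels are dropped with a warning.
#'
#' @param labels vector coercible to factor, one label per sample.
#' @param survival a [survival_table()].
#' @return List with `statistic`, `degrees_of_freedom`, `p_value`.
#' @export
logrank_test <- function(labels, survival) {
  if (!is.factor(labels)) labels <- factor(labels)
  if (any(table(labels) == 0)) {
    warning("dropping empty group level(s) from log-rank test")
    labels <- droplevels(labels)
  }
  k <- nlevels(labels)
  if (k < 2)
    abort_omicsurv("log-rank test needs >= 2 non-empty groups", "degenerate")
  if (sum(survival$event) < 1)
    abort_omicsurv("log-rank test needs at least one observed event",
                   "degenerate")
  sd <- survival::survdiff(surv_object(survival) ~ labels)
  list(statistic = unname(sd$chisq),
       degrees_of_freedom = k - 1L,
       p_value = stats::pchisq(sd$chisq, df = k - 1, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Probability that, of two comparable samples (the earlier observed time had
#' an event), the one failing earlier has the strictly higher predicted risk;
#' risk ties count 0.5. 0.5 = uninformative, 1 = perfect.
#'
#' @param risk numeric risk scores (higher = expected earlier failure).
#' @param survival a [survival_table()].
#' @return Concordance in \[0, 1\].
#' @export
concordance_index <- function(risk, survival) {
  if (length(risk) != length(survival$sample_ids))
    abort_omicsurv("risk length must equal sample count", "argument")
  if (sum(survival$event) < 1)
    abort_omicsurv("no comparable pairs: all samples censored", "degenerate")
  # timefix = FALSE: compare observation times exactly, per Harrell's
  # definition (the default near-tie adjustment merges close times; the
  # formula interface does not honor the flag, concordancefit does)
  cf <- survival::concordancefit(surv_object(survival), risk, reverse = TRUE,
                                 timefix = FALSE)
  n_pairs <- sum(cf$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0)
    abort_omicsurv("no comparable pairs in the data", "degenerate")
  unname(cf$concordance)
}
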