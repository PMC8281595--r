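# Per-omic nonlinear dimension reduction: a one-hidden-layer autoencoder
# trained with Adam, plus a PCA projector as a pluggable linear alternative.
#
# Architecture, for an input vector v of length m (the distance features, all
# in [0, 1]):
#     hidden  z = s(W v + b)            s = tanh by default, size h
#     output  f(v) = tanh(W' z + b')
# The tanh output is mapped through y = (f + 1) / 2 and trained against v with
# element-wise binary cross-entropy ("log-loss"); mean squared error is
# available behind a flag.  Defaults follow the pipeline's stated training
# recipe: h = 100, 10 epochs, 50% dropout.

act_fun <- function(name) {
  switch(name,
         tanh = list(f = tanh, grad = function(a) 1 - a^2),
         sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                        grad = function(a) a * (1 - a)),
         relu = list(f = function(x) pmax(x, 0),
                     grad = function(a) as.numeric(a > 0)),
         abort_omicsurv(sprintf("unknown activation '%s'", name), "argument"))
}

glorot_init <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

clip_by_norm <- function(g, max_norm) {
  nm <- sqrt(sum(g^2))
  if (is.finite(nm) && nm > max_norm) g * (max_norm / nm) else g
}

#' Fit a one-hidden-layer autoencoder on distance features
#'
#' Trains weights `W` (h x m), `W'` (m x h) and biases `b`, `b'` by Adam on
#' the reconstruction loss. Dropout (default rate 0.5) is applied to the input
#' units at each training step (`dropout_mode = "weight"` instead zeroes a
#' random half of the entries of both weight matrices per step, the
#' DropConnect reading). Gradients are clipped at norm 5 so degenerate inputs
#' never produce NaN weights. Fully deterministic given `seed`.
#'
#' @param X a `distance_features` object (or plain samples x m matrix in
#'   \[0,1\]).
#' @param h hidden-layer size (default 100).
#' @param epochs training epochs (default 10).
#' @param dropout dropout rate in \[0, 1) (default 0.5).
#' @param seed integer RNG seed.
#' @param activation hidden activation: `"tanh"` (default), `"sigmoid"`,
#'   `"relu"`.
#' @param loss `"bce"` (default) or `"mse"`.
#' @param dropout_mode `"unit"` (default) or `"weight"`.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size; by default full batch for n <= 512, else
#'   128.
#' @param omic_tag tag stored in the state (defaults from `X` if absent).
#' @return An object of class `encoder_state` with the fitted weights and the
#'   per-epoch training loss.
#' @export
fit_autoencoder <- function(X, h = 100, epochs = 10, dropout = 0.5, seed = 1,
                            activation = "tanh", loss = "bce",
                            dropout_mode = "unit", lr = 1e-3,
                            batch_size = NULL, omic_tag = "omic") {
  V <- if (inherits(X, "distance_features")) X$values else as.matrix(X)
  if (!all(is.finite(V)))
    abort_omicsurv("autoencoder input must be finite", "argument")
  n <- nrow(V); m <- ncol(V)
  if (h < 1) abort_omicsurv("hidden size must be >= 1", "argument")
  if (dropout < 0 || dropout >= 1)
    abort_omicsurv("dropout must be in [0, 1)", "argument")
  if (is.null(batch_size)) batch_size <- if (n <= 512) n else 128L
  act <- act_fun(activation)

  with_seed(seed, {
    W <- glorot_init(h, m); b <- numeric(h)
    Wp <- glorot_init(m, h); bp <- numeric(m)
    # Adam state per parameter
    mom <- lapply(list(W, b, Wp, bp), function(p) p * 0)
    vel <- lapply(list(W, b, Wp, bp), function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0
    loss_log <- numeric(epochs)

    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / batch_size))
      ep_loss <- 0; ep_n <- 0
      for (bi in batches) {
        Xb <- V[bi, , drop = FALSE]           # nb x m
        nb <- nrow(Xb)
        Xin <- Xb
        Wd <- W; Wpd <- Wp
        if (dropout > 0) {
          if (dropout_mode == "unit") {
            mask <- matrix(stats::rbinom(nb * m, 1, 1 - dropout), nb, m)
            Xin <- Xb * mask / (1 - dropout)  # inverted dropout
          } else {
            Wd <- W * matrix(stats::rbinom(h * m, 1, 1 - dropout), h, m)
            Wpd <- Wp * matrix(stats::rbinom(m * h, 1, 1 - dropout), m, h)
          }
        }
        Z <- act$f(sweep(Xin %*% t(Wd), 2, b, "+"))       # nb x h
        Out <- tanh(sweep(Z %*% t(Wpd), 2, bp, "+"))      # nb x m
        Y <- (Out + 1) / 2
        Yc <- pmin(pmax(Y, 1e-7), 1 - 1e-7)
        N <- nb * m
        if (loss == "bce") {
          l <- -sum(Xb * log(Yc) + (1 - Xb) * log(1 - Yc)) / N
          dOutZ2 <- 2 * (Y - Xb) / N     # d loss / d (pre-tanh output), exact
        } else {
          l <- sum((Y - Xb)^2) / N
          dOutZ2 <- (2 * (Y - Xb) / N) * (Y * (1 - Y) * 4) / 2
        }
        gWp <- t(dOutZ2) %*% Z                             # m x h
        gbp <- colSums(dOutZ2)
        dZ <- (dOutZ2 %*% Wpd) * act$grad(Z)               # nb x h
        gW <- t(dZ) %*% Xin                                # h x m
        gb <- colSums(dZ)
        grads <- list(clip_by_norm(gW, 5), clip_by_norm(gb, 5),
                      clip_by_norm(gWp, 5), clip_by_norm(gbp, 5))
        tstep <- tstep + 1
        params <- list(W, b, Wp, bp)
        for (k in 1:4) {
          mom[[k]] <- beta1 * mom[[k]] + (1 - beta1) * grads[[k]]
          vel[[k]] <- beta2 * vel[[k]] + (1 - beta2) * grads[[k]]^2
          mhat <- mom[[k]] / (1 - beta1^tstep)
          vhat <- vel[[k]] / (1 - beta2^tstep)
          params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
        }
        W <- params[[1]]; b <- params[[2]]; Wp <- params[[3]]; bp <- params[[4]]
        ep_loss <- ep_loss + l * nb; ep_n <- ep_n + nb
      }
      loss_log[ep] <- ep_loss / ep_n
    }

    structure(list(kind = "autoencoder", omic_tag = omic_tag,
                   W = W, b = b, W_prime = Wp, b_prime = bp,
                   hidden_size = h, input_dim = m,
                   activation = activation, output_activation = "tanh",
                   loss = loss, dropout = dropout, epochs = epochs,
                   loss_log = loss_log, seed = seed),
              class = "encoder_state")
  })
}

#' @export
print.encoder_state <- function(x, ...) {
  cat(sprintf("<encoder_state '%s' (%s)> %d -> %d, final loss %.4g\n",
              x$omic_tag, x$kind, x$input_dim, x$hidden_size,
              if (length(x$loss_log)) x$loss_log[length(x$loss_log)] else NA))
  invisible(x)
}

#' Encode samples into the latent space
#'
#' Deterministic forward pass `s(W x + b)` (no dropout at inference). For a
#' PCA projector, the centered projection onto the top components.
#'
#' @param state an `encoder_state` from [fit_autoencoder()] or
#'   [fit_pca_embedding()].
#' @param X `distance_features` or samples x m matrix matching
#'   `state$input_dim`.
#' @return A `latent_matrix`: samples x h matrix with latent column ids
#'   `"<omic_tag>.<index>"`.
#' @export
encode <- function(state, X) {
  V <- if (inherits(X, "distance_features")) X$values else as.matrix(X)
  if (ncol(V) != state$input_dim)
    abort_omicsurv(sprintf("input has %d columns, encoder expects %d",
                           ncol(V), state$input_dim), "argument")
  Z <- if (state$kind == "autoencoder") {
    act_fun(state$activation)$f(sweep(V %*% t(state$W), 2, state$b, "+"))
  } else {
    sweep(V, 2, state$center, "-") %*% state$rotation
  }
  latent_ids <- paste(state$omic_tag, seq_len(ncol(Z)), sep = ".")
  dimnames(Z) <- list(rownames(V), latent_ids)
  structure(list(sample_ids = rownames(V), latent_ids = latent_ids,
                 values = Z, omic_tag = state$omic_tag),
            class = "latent_matrix")
}

#' Fit a PCA projector as a linear embedding backend
#'
#' Drop-in replacement for the autoencoder: projects onto the top `k`
#' principal components of the (centered) distance features.
#'
#' @param X `distance_features` or samples x m matrix.
#' @param k number of components; must satisfy `k <= min(n - 1, m)`.
#' @param omic_tag tag stored in the state.
#' @return An `encoder_state` (kind `"pca"`) usable with [encode()]; carries
#'   `sdev` (component standard deviations), `rotation`, `center`.
#' @export
fit_pca_embedding <- function(X, k, omic_tag = "omic") {
  V <- if (inherits(X, "distance_features")) X$values else as.matrix(X)
  n <- nrow(V); m <- ncol(V)
  if (k > min(n - 1, m))
    abort_omicsurv(sprintf("k = %d exceeds min(n - 1, m) = %d", k,
                           min(n - 1, m)), "argument")
  pc <- stats::prcomp(V, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(kind = "pca", omic_tag = omic_tag,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, sdev = pc$sdev[seq_len(k)],
                 hidden_size = k, input_dim = m,
                 loss_log = numeric(0), seed = NA_integer_),
            class = "encoder_state")
}
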