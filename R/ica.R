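# Internal ICA engine.
#
# Model: the centred data matrix Xc (n observations x p variables) is
# decomposed as Xc ~ S %*% t(A), with S (n x k) columns maximally independent
# across observations and A (p x k) the mixing matrix. Data are PCA-whitened
# to k dimensions first. Two estimators are provided:
#   * fastica - symmetric fixed-point iteration with the tanh contrast;
#     deterministic given the seed, used for the group spectrocortical ICA.
#   * infomax - natural-gradient maximum-likelihood with a logistic score,
#     the classical choice for ocular-artifact removal in ERP work.
ica_decompose <- function(X, k, algorithm = c("fastica", "infomax"),
                          seed = 1, max_iter = 500, tol = 1e-6,
                          center = TRUE) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k > min(n, p)) stop("k = ", k, " exceeds min(dim) = ", min(n, p))
  mu <- if (center) colMeans(X) else rep(0, p)
  Xc <- sweep(X, 2, mu, "-")
  cv <- crossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(k)], 1e-12)
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  Kw <- E %*% diag(1 / sqrt(ev), k)       # whitening: Z = Xc Kw
  Z <- Xc %*% Kw
  set.seed(seed)
  W0 <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  converged <- FALSE
  if (algorithm == "fastica") {
    W <- W0
    for (it in seq_len(max_iter)) {
      U <- Z %*% W
      G <- tanh(U)
      W1 <- crossprod(Z, G) / n - W %*% diag(colMeans(1 - G^2), k)
      sw <- svd(W1)
      W1 <- sw$u %*% t(sw$v)              # symmetric decorrelation
      drift <- max(abs(abs(colSums(W1 * W)) - 1))
      W <- W1
      if (drift < tol) { converged <- TRUE; break }
    }
    S <- Z %*% W
    A <- E %*% diag(sqrt(ev), k) %*% W
    unmix <- Kw %*% W
  } else {
    # natural-gradient infomax with learning-rate annealing: the step is
    # shrunk whenever the gradient direction swings by more than 60 degrees
    W <- W0
    lr <- 0.1
    I_k <- diag(k)
    prev_dW <- NULL
    for (it in seq_len(max_iter)) {
      U <- Z %*% t(W)
      Y <- 1 / (1 + exp(-U))
      dW <- (I_k + crossprod(1 - 2 * Y, U) / n) %*% W
      if (!all(is.finite(dW))) { lr <- lr / 2; prev_dW <- NULL; next }
      if (!is.null(prev_dW)) {
        ang <- sum(dW * prev_dW) / sqrt(sum(dW^2) * sum(prev_dW^2))
        if (ang < 0.5) lr <- lr * 0.9
      }
      if (it > 200) lr <- lr * 0.99   # force the step schedule to settle
      W1 <- W + lr * dW
      wchange <- sum((W1 - W)^2) / sum(W^2)
      prev_dW <- dW
      W <- W1
      if (wchange < 1e-10) { converged <- TRUE; break }
    }
    S <- Z %*% t(W)
    # rescale sources to unit variance and push scale into the mixing matrix
    sdS <- apply(S, 2, stats::sd)
    sdS[sdS < 1e-12] <- 1
    S <- sweep(S, 2, sdS, "/")
    A <- E %*% diag(sqrt(ev), k) %*% solve(W) %*% diag(sdS, k)
    unmix <- Kw %*% t(W) %*% diag(1 / sdS, k)
  }
  list(S = S, A = A, mean = mu, unmixing = unmix, k = k,
       algorithm = algorithm, converged = converged)
}
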