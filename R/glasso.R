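# Sparse inverse-covariance estimation with an elementwise penalty matrix
# (graphical lasso, blockwise coordinate descent). Internal engine behind
# window_coaccessibility(); the penalty matrix carries the distance penalty.
# Hot path is compiled (src/glasso.cpp); glasso_fit_r is a pure-R reference
# used for testing.

glasso_fit <- function(S, Rho, maxit = 100, tol = 1e-5) {
  p <- ncol(S)
  if (any(diag(S) <= 0)) stop("zero-variance variable reached the solver")
  if (p == 1) return(matrix(1 / S[1, 1], 1, 1, dimnames = dimnames(S)))
  Theta <- glasso_fit_cpp(unname(as.matrix(S)), unname(as.matrix(Rho)),
                          as.integer(maxit), tol)
  dimnames(Theta) <- dimnames(S)
  Theta
}

# Coordinate-descent lasso for: min_b  1/2 b' W11 b - s12' b + sum(rho |b|)
lasso_cd_r <- function(W11, s12, rho, beta = NULL, maxit = 200, tol = 1e-7) {
  p <- length(s12)
  if (is.null(beta)) beta <- rep(0, p)
  d <- diag(W11)
  for (it in seq_len(maxit)) {
    delta_max <- 0
    for (k in seq_len(p)) {
      r <- s12[k] - sum(W11[, k] * beta) + d[k] * beta[k]
      bnew <- sign(r) * max(abs(r) - rho[k], 0) / d[k]
      delta_max <- max(delta_max, abs(bnew - beta[k]))
      beta[k] <- bnew
    }
    if (delta_max < tol) break
  }
  beta
}

glasso_fit_r <- function(S, Rho, maxit = 100, tol = 1e-5) {
  p <- ncol(S)
  if (p == 1) return(matrix(1 / S[1, 1], 1, 1))
  W <- S
  B <- matrix(0, p - 1, p)
  scale_ref <- mean(abs(S[upper.tri(S)])) + 1e-12
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      beta <- lasso_cd_r(W[idx, idx, drop = FALSE], S[idx, j], Rho[idx, j],
                         beta = B[, j])
      B[, j] <- beta
      w12 <- W[idx, idx, drop = FALSE] %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < tol * scale_ref) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- seq_len(p)[-j]
    denom <- W[j, j] - sum(W[idx, j] * B[, j])
    if (!is.finite(denom) || denom <= 0)
      stop("penalized covariance is numerically singular; ",
           "raise the penalty scale lambda0")
    Theta[j, j] <- 1 / denom
    Theta[idx, j] <- -B[, j] / denom
  }
  (Theta + t(Theta)) / 2
}

# Partial correlations from a precision matrix: -Theta_ab / sqrt(aa * bb),
# clamped to [-1, 1] against rounding.
partial_cor <- function(Theta) {
  d <- sqrt(diag(Theta))
  R <- -Theta / tcrossprod(d)
  diag(R) <- 1
  pmin(pmax(R, -1), 1)
}
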