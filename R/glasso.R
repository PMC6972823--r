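# Sparse inverse-covariance estimation: block coordinate-descent graphical
# LASSO (Friedman-style, diagonal unpenalized) with a KKT verifier.

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Graphical LASSO precision-matrix estimate
#'
#' Maximizes `log det(Theta) - trace(S Theta) - lambda * sum_offdiag |theta|`
#' over symmetric positive-definite matrices (the diagonal is not
#' penalized), by block coordinate descent on the working covariance: each
#' column is solved as an L1-regularized regression via coordinate-wise
#' soft-thresholding. Zeros in the estimate encode conditional
#' independence.
#'
#' @param S Symmetric correlation matrix (unit diagonal). A singular `S` is
#'   regularized internally by `+ 1e-8 I`; `lambda = 0` with singular `S`
#'   is refused.
#' @param lambda Non-negative L1 penalty on off-diagonal precision entries.
#' @param tol Convergence tolerance: mean absolute change of the working
#'   covariance's off-diagonals below `tol` times the mean absolute
#'   off-diagonal of `S`.
#' @param max_iter Maximum full sweeps; non-convergence returns the best
#'   iterate with a warning and attribute `converged = FALSE`.
#' @return The precision matrix `Theta`, with attributes `lambda`,
#'   `converged`, `iterations`, and `W` (the estimated covariance
#'   `Theta^-1` up to numerical error).
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-5, max_iter = 500) {
  p <- nrow(S)
  if (!is.matrix(S) || p != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stopf("S must be a symmetric matrix")
  if (lambda < 0) stopf("lambda must be >= 0")
  S <- (S + t(S)) / 2
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) {
    if (lambda == 0)
      stopf("lambda = 0 is not admissible for a singular correlation matrix")
    S <- S + diag(1e-8, p)
  }

  if (p == 1) {
    Theta <- matrix(1 / S[1, 1], 1, 1)
    attributes(Theta) <- c(attributes(Theta),
                           list(lambda = lambda, converged = TRUE,
                                iterations = 0L, W = S))
    return(Theta)
  }

  W <- S                                     # diagonal unpenalized: W_ii = S_ii
  B <- matrix(0, p, p)                       # per-column lasso coefficients
  off <- mean(abs(S[upper.tri(S)]))
  thresh <- tol * if (off > 0) off else 1
  inner_tol <- thresh / 10

  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    W_old <- W
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[idx, j]
      u <- as.vector(W11 %*% beta)
      inner_it <- 0L
      repeat {
        inner_it <- inner_it + 1L
        delta_max <- 0
        for (kk in seq_along(idx)) {
          bk <- beta[kk]
          r <- s12[kk] - (u[kk] - W11[kk, kk] * bk)
          bnew <- soft_threshold(r, lambda) / W11[kk, kk]
          if (bnew != bk) {
            beta[kk] <- bnew
            u <- u + W11[, kk] * (bnew - bk)
            delta_max <- max(delta_max, abs(bnew - bk))
          }
        }
        if (delta_max < inner_tol || inner_it >= 1000L) break
      }
      B[idx, j] <- beta
      w12 <- as.vector(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W[upper.tri(W)] - W_old[upper.tri(W_old)])) < thresh) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("graphical_lasso did not converge in %d sweeps", max_iter))

  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- seq_len(p)[-j]
    beta <- B[idx, j]
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -beta * theta_jj
  }
  Theta <- (Theta + t(Theta)) / 2
  dimnames(Theta) <- dimnames(S)
  attr(Theta, "lambda") <- lambda
  attr(Theta, "converged") <- converged
  attr(Theta, "iterations") <- it
  attr(Theta, "W") <- W
  Theta
}

# Verify the stationarity (KKT) conditions of the glasso optimum:
#   Sigma_hat - S = lambda * sign(theta_ij) on nonzero off-diagonals,
#   |Sigma_hat - S| <= lambda elsewhere, Sigma_hat = Theta^-1,
# each within a 10 * tol numerical margin. Returns TRUE/FALSE with a
# "residuals" attribute.
glasso_kkt_check <- function(S, Theta, lambda, tol = 1e-5, zero_tol = 1e-8) {
  Sigma <- solve(Theta)
  D <- Sigma - S
  diag(D) <- 0
  margin <- lambda + 10 * tol
  ok_bound <- all(abs(D) <= margin)
  nz <- abs(Theta) > zero_tol & row(Theta) != col(Theta)
  ok_sign <- !any(nz) ||
    all(abs(D[nz] - lambda * sign(Theta[nz])) <= 10 * tol + 1e-10)
  structure(ok_bound && ok_sign,
            residuals = c(max_bound = max(abs(D)) - lambda,
                          max_sign = if (any(nz))
                            max(abs(D[nz] - lambda * sign(Theta[nz])))
                          else 0))
}

# Penalized log-likelihood the glasso maximizes.
glasso_objective <- function(S, Theta, lambda) {
  determinant(Theta, logarithm = TRUE)$modulus[1] - sum(S * Theta) -
    lambda * sum(abs(Theta[row(Theta) != col(Theta)]))
}

#' Partial correlations from a precision matrix
#'
#' The Gaussian graphical model identity
#' `rho_ij = -theta_ij / sqrt(theta_ii * theta_jj)`, with a zero diagonal.
#'
#' @param Theta Symmetric positive-definite precision matrix.
#' @return Symmetric partial-correlation matrix.
#' @export
partial_correlations <- function(Theta) {
  if (max(abs(Theta - t(Theta))) > 1e-8) stopf("Theta must be symmetric")
  d <- diag(Theta)
  if (any(d <= 0)) stopf("Theta must have a positive diagonal")
  rho <- -Theta / sqrt(tcrossprod(d))
  diag(rho) <- 0
  (rho + t(rho)) / 2
}
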