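# Independent oracles, deliberately coded with plain loops and no shared
# data structures with the implementation they check.

# Exhaustive-search kNN imputer on log intensities (feature-space neighbors,
# pair-mean centering). Returns the completed intensity matrix.
oracle_knn_impute <- function(m, k) {
  L <- log(m)
  n_feat <- nrow(L)
  n_samp <- ncol(L)
  out <- L
  for (f in seq_len(n_feat)) {
    for (s in seq_len(n_samp)) {
      if (!is.na(L[f, s])) next
      cand <- c()
      dist <- c()
      for (g in seq_len(n_feat)) {
        if (g == f) next
        shared <- which(!is.na(L[f, ]) & !is.na(L[g, ]))
        if (length(shared) == 0) next
        d2 <- mean((L[f, shared] - L[g, shared])^2) * n_samp
        cand <- c(cand, g)
        dist <- c(dist, d2)
      }
      usable <- which(!is.na(L[cand, s]))
      if (length(usable) == 0) {
        out[f, s] <- mean(L[f, ], na.rm = TRUE)
        next
      }
      cand <- cand[usable]
      dist <- dist[usable]
      ord <- order(dist, cand)
      nb <- cand[ord][seq_len(min(k, length(cand)))]
      vals <- numeric(length(nb))
      for (ii in seq_along(nb)) {
        g <- nb[ii]
        shared <- which(!is.na(L[f, ]) & !is.na(L[g, ]))
        vals[ii] <- L[g, s] - mean(L[g, shared]) + mean(L[f, shared])
      }
      out[f, s] <- mean(vals)
    }
  }
  res <- m
  res[is.na(m)] <- exp(out[is.na(m)])
  res
}

# Independent maximizer of the graphical-LASSO objective
#   log det(Theta) - tr(S Theta) - lambda * sum_offdiag |theta_ij|
# via its smooth dual: maximize log det W over the box
# |W_ij - S_ij| <= lambda (i != j), W_ii = S_ii, then Theta = W^-1.
# Solved with L-BFGS-B; shares nothing with the coordinate-descent path.
oracle_glasso <- function(S, lambda) {
  p <- nrow(S)
  ut <- which(upper.tri(S))
  build <- function(w) {
    W <- S
    W[ut] <- w
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    W
  }
  neg_logdet <- function(w) {
    W <- build(w)
    ch <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    -2 * sum(log(diag(ch)))
  }
  grad <- function(w) {
    W <- build(w)
    ch <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(w)))
    Winv <- chol2inv(ch)
    -2 * Winv[ut]
  }
  fit <- stats::optim(S[ut], neg_logdet, grad, method = "L-BFGS-B",
                      lower = S[ut] - lambda, upper = S[ut] + lambda,
                      control = list(maxit = 2000, factr = 10))
  W <- build(fit$par)
  solve(W)
}

# Spearman correlation by explicit average-ranking then textbook Pearson.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Penalized log-likelihood evaluated independently of the package helper.
oracle_objective <- function(S, Theta, lambda) {
  ev <- determinant(Theta, logarithm = TRUE)
  as.numeric(ev$modulus) - sum(diag(S %*% Theta)) -
    lambda * (sum(abs(Theta)) - sum(abs(diag(Theta))))
}
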