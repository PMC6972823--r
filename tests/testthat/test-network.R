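# Graphical LASSO, RIC penalty, network construction, hub analysis.

test_that("autoscale standardizes columns and is idempotent", {
  set.seed(2)
  m <- matrix(rnorm(60, 5, 3), 10, 6)
  a <- autoscale(m)
  expect_lt(max(abs(colMeans(a))), 1e-12)
  expect_equal(unname(apply(a, 2, sd)), rep(1, 6), tolerance = 1e-12)
  expect_equal(autoscale(a), a, tolerance = 1e-12)
  # closed form for two rows: +-1/sqrt(2)
  two <- autoscale(matrix(c(1, 3, 10, 4), 2, 2))
  expect_equal(abs(unname(two)), matrix(1 / sqrt(2), 2, 2), tolerance = 1e-12)
  m[, 3] <- 7
  expect_error(autoscale(m), "constant column")
})

test_that("glasso closed-form limits hold", {
  # lambda at or above the largest off-diagonal: fully disconnected
  S <- random_corr(5, n = 30, seed = 4)
  lam <- max(abs(S[upper.tri(S)]))
  Theta <- graphical_lasso(S, lam + 1e-12)
  off <- Theta[upper.tri(Theta)]
  expect_true(all(abs(off) < 1e-10))
  expect_equal(diag(Theta), 1 / diag(S), tolerance = 1e-8)

  # p = 2, lambda = 0: partial correlation equals Pearson r
  r <- 0.62
  S2 <- matrix(c(1, r, r, 1), 2)
  Theta2 <- graphical_lasso(S2, 0)
  rho <- partial_correlations(Theta2)
  expect_equal(rho[1, 2], r, tolerance = 1e-8)

  # lambda = 0 on well-conditioned S inverts it
  Theta0 <- graphical_lasso(S, 0, tol = 1e-7)
  expect_lt(max(abs(Theta0 %*% S - diag(5))), 1e-6)
  expect_error(graphical_lasso(matrix(c(1, 1, 1, 1), 2), 0), "singular")
})

test_that("glasso attains the penalized maximum and satisfies the KKT conditions", {
  lambdas <- c(0.05, 0.1, 0.3)
  for (i in 1:10) {
    p <- if (i %% 2 == 0) 3 else 4
    S <- random_corr(p, n = 25, seed = 100 + i)
    for (lam in lambdas) {
      Theta <- graphical_lasso(S, lam, tol = 1e-7)
      expect_true(fecanet:::glasso_kkt_check(S, Theta, lam, tol = 1e-7))
      expect_gt(min(eigen(Theta, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
      ref <- oracle_glasso(S, lam)
      expect_lt(abs(oracle_objective(S, Theta, lam) -
                      oracle_objective(S, ref, lam)), 1e-6)
    }
  }
})

test_that("increasing the penalty never adds edges", {
  S <- random_corr(8, n = 15, seed = 42)
  edges <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8), function(lam) {
    Theta <- graphical_lasso(S, lam)
    sum(abs(Theta[upper.tri(Theta)]) > 1e-8)
  }, numeric(1))
  expect_true(all(diff(edges) <= 0))
})

test_that("partial correlations follow the precision-matrix identity", {
  expect_equal(partial_correlations(diag(c(2, 3, 4))), matrix(0, 3, 3))
  Theta <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(partial_correlations(Theta)[1, 2], 0.5)
  K <- simulate_precision(10, 0.4, seed = 5)
  rho <- partial_correlations(K)
  expect_equal(rho, t(rho))
  expect_true(all(abs(rho[upper.tri(rho)]) < 1))
  expect_error(partial_correlations(matrix(c(-1, 0, 0, 1), 2)),
               "positive diagonal")
})

test_that("ric_lambda is deterministic and tracks spurious correlation", {
  set.seed(8)
  X <- matrix(rnorm(1000 * 5), 1000, 5)
  l1 <- ric_lambda(X, n_rotations = 20, seed = 3)
  l2 <- ric_lambda(X, n_rotations = 20, seed = 3)
  expect_identical(as.numeric(l1), as.numeric(l2))
  # independent columns at n = 1000: spurious correlations are small
  expect_lt(as.numeric(l1), 0.15)
  # the selected penalty then yields a (near) empty graph on the same data
  Theta <- graphical_lasso(cor(X), as.numeric(l1))
  expect_lte(sum(abs(Theta[upper.tri(Theta)]) > 1e-8), 1)

  # a rotation replayed with the same per-(rotation, column) seeds equals
  # the max absolute off-diagonal correlation of the permuted matrix
  Xs <- matrix(rnorm(30), 10, 3)
  l <- ric_lambda(Xs, n_rotations = 1, seed = 11)
  rot <- Xs
  for (j in 1:3) {
    perm <- fecanet:::with_seed(fecanet:::derive_seed(11, 1, j),
                                sample.int(10))
    rot[, j] <- Xs[perm, j]
  }
  cc <- cor(rot)
  expect_equal(as.numeric(l), max(abs(cc[upper.tri(cc)])), tolerance = 1e-14)
  expect_error(ric_lambda(Xs[1:2, ], seed = 1), ">= 3 rows")
})

test_that("build_network finds edges, hub and shapes from a planted matrix", {
  # star: node A tied to B, C, D (degrees 3,1,1,1)
  ids <- c("A", "B", "C", "D")
  rho <- matrix(0, 4, 4, dimnames = list(ids, ids))
  rho["A", "B"] <- rho["B", "A"] <- 0.5
  rho["A", "C"] <- rho["C", "A"] <- -0.4
  rho["A", "D"] <- rho["D", "A"] <- 0.3
  meta <- data.frame(feature_id = ids, name = ids,
                     platform = c("polar", "lipid", "polar", "lipid"),
                     compound_class = "x", stringsAsFactors = FALSE)
  net <- build_network(rho, meta)
  expect_equal(net$hub, "A")
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$edges$sign, c("positive", "inverse"))
  expect_equal(net$nodes$shape[net$nodes$id == "B"], "circle")
  expect_equal(net$nodes$shape[net$nodes$id == "C"], "rectangle")
  expect_equal(sum(net$edges$sign == "inverse"), 1)

  # single edge between A and B: lexicographic tie-break picks A
  rho2 <- matrix(0, 2, 2, dimnames = list(c("B", "A"), c("B", "A")))
  rho2["A", "B"] <- rho2["B", "A"] <- 0.2
  net2 <- build_network(rho2, meta[1:2, ][c(2, 1), ])
  expect_equal(net2$hub, "A")
})

test_that("spearman_to_hub matches the rank-then-Pearson oracle", {
  hubv <- c(3, 1, 4, 1, 5)
  other <- c(2, 7, 1, 8, 2)
  X <- cbind(hub = hubv, mono = exp(hubv), rev = -hubv, other = other)
  rownames(X) <- paste0("I", 1:5)
  rho <- spearman_to_hub(X, "hub")
  expect_equal(unname(rho["mono"]), 1)
  expect_equal(unname(rho["rev"]), -1)
  expect_equal(unname(rho["other"]), oracle_spearman(other, hubv),
               tolerance = 1e-12)
  expect_equal(unname(rho["hub"]), 1)
  expect_error(spearman_to_hub(cbind(h = rep(1, 5), X), "h"), "constant")
})

test_that("infer_network is deterministic and exports its artifacts", {
  sim <- simulate_study(simulation_config(n_polar = 12, n_lipid = 8,
                                          n_unknowns = 0, network_size = 10,
                                          lod_quantile = 0, seed = 19))
  tab <- knn_impute(filter_by_missingness(filter_by_pool_rsd(
    filter_unknowns(normalize_to_is(sim$table)))))
  m1 <- infer_network(tab, seed = 5)
  m2 <- infer_network(tab, seed = 5)
  expect_identical(m1$edges, m2$edges)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$hub, m2$hub)
  expect_true(all(m1$edges$sign ==
                    ifelse(m1$edges$weight > 0, "positive", "inverse")))
  # precision stays positive definite and KKT-consistent
  expect_gt(min(eigen(m1$precision, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_true(fecanet:::glasso_kkt_check(m1$correlation, m1$precision,
                                         m1$lambda))

  dir <- withr::local_tempdir()
  paths <- write_network(m1, dir)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::gorder(g), nrow(m1$nodes))
  expect_equal(igraph::gsize(g), nrow(m1$edges))
})
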