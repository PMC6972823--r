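# Three-level CV decomposition and moderated F-tests.

cv_table <- function(m, participants, areas, n_pools) {
  toy_table(m, n_pools = n_pools, participants = participants, areas = areas)
}

test_that("the three CV levels match hand computations", {
  # 2 participants x 3 drills + 3 pools
  m <- rbind(c(1, 2, 3, 2, 4, 6, 90, 100, 110))
  tab <- cv_table(m, participants = rep(c("P1", "P2"), each = 3),
                  areas = rep(1:3, 2), n_pools = 3)
  expect_equal(technical_cv(tab, "F01"), 10)      # sd 10, mean 100
  expect_equal(area_cv(tab, "F01"), 50)           # mean(50%, 50%)
  # participant means (2, 4): sd = sqrt(2), mean = 3
  expect_equal(participant_cv(tab, "F01"), 100 * sqrt(2) / 3)

  # degenerate inputs
  m0 <- rbind(c(5, 5, 5, 5, 5, 5, 10, 10, 10))
  tab0 <- cv_table(m0, participants = rep(c("P1", "P2"), each = 3),
                   areas = rep(1:3, 2), n_pools = 3)
  expect_equal(technical_cv(tab0, "F01"), 0)
  expect_equal(area_cv(tab0, "F01"), 0)
  expect_equal(participant_cv(tab0, "F01"), 0)
})

test_that("all CV levels are invariant to a positive constant multiple", {
  sim <- simulate_study(simulation_config(n_polar = 6, n_lipid = 4,
                                          n_unknowns = 0, lod_quantile = 0,
                                          network_size = 4, seed = 21))
  tab <- sim$table
  f <- "POL_0002"
  scaled <- tab
  i <- match(f, tab$features$feature_id)
  scaled$intensities[i, ] <- scaled$intensities[i, ] * 13.7
  for (fun in list(technical_cv, area_cv, participant_cv)) {
    expect_equal(fun(scaled, f), fun(tab, f), tolerance = 1e-12)
  }
})

test_that("unmoderated F equals classical one-way ANOVA", {
  sim <- simulate_study(simulation_config(n_polar = 10, n_lipid = 5,
                                          n_unknowns = 0, lod_quantile = 0,
                                          network_size = 6, seed = 9))
  tab <- sim$table
  ft <- feature_f_test(tab, moderation = "none")
  study <- tab$samples$sample_type == "study"
  grp <- factor(tab$samples$participant_id[study])
  for (f in c("POL_0003", "LIP_0002")) {
    y <- log(tab$intensities[match(f, tab$features$feature_id), study])
    ref <- stats::anova(stats::lm(y ~ grp))
    expect_equal(ft$f_statistic[ft$feature_id == f], ref$`F value`[1],
                 tolerance = 1e-10)
    expect_equal(ft$p_value[ft$feature_id == f], ref$`Pr(>F)`[1],
                 tolerance = 1e-10)
  }
})

test_that("two balanced groups give F equal to the squared pooled t", {
  m <- matrix(exp(c(1.2, 1.9, 1.4, 2.8, 2.1, 2.4)), nrow = 1)
  tab <- toy_table(m, participants = rep(c("P1", "P2"), each = 3),
                   areas = rep(1:3, 2))
  ft <- feature_f_test(tab, moderation = "none")
  y <- log(m[1, ])
  tt <- stats::t.test(y[1:3], y[4:6], var.equal = TRUE)
  expect_equal(ft$f_statistic, unname(tt$statistic^2), tolerance = 1e-12)
})

test_that("equal group means give F = 0; constant features give p = 1", {
  m <- rbind(exp(c(1, 2, 3, 1, 2, 3)),     # identical group profiles
             rep(7, 6))                    # constant everywhere
  tab <- toy_table(m, participants = rep(c("P1", "P2"), each = 3),
                   areas = rep(1:3, 2))
  ft <- feature_f_test(tab, moderation = "none")
  expect_equal(ft$f_statistic[1], 0, tolerance = 1e-12)
  expect_equal(ft$f_statistic[2], 0)
  expect_equal(ft$p_value[2], 1)
})

test_that("moderated F collapses to ordinary F when the prior is flat", {
  sim <- simulate_study(simulation_config(n_polar = 40, n_lipid = 20,
                                          n_unknowns = 0, lod_quantile = 0,
                                          seed = 14))
  tab <- sim$table
  plain <- feature_f_test(tab, moderation = "none")
  mod <- feature_f_test(tab, moderation = "empirical_bayes")
  # moderation shrinks residual variances toward a common value: the
  # moderated statistic stays between the ordinary F and the F computed
  # with the fully pooled variance
  s2 <- NULL
  study <- tab$samples$sample_type == "study"
  grp <- factor(tab$samples$participant_id[study])
  expect_true(all(is.finite(mod$f_statistic)))
  expect_gt(stats::cor(mod$f_statistic, plain$f_statistic), 0.95)
  # agreement with limma's own moderation of the same variances
  L <- log(tab$intensities[, study])
  fit <- limma::lmFit(L, stats::model.matrix(~grp))
  eb <- limma::eBayes(fit[, -1])   # moderated F over the group contrasts
  expect_equal(unname(mod$f_statistic), unname(eb$F), tolerance = 1e-8)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  p <- runif(50)^2
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  # permutation equivariance
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("variance_profile assembles one complete row per feature", {
  sim <- simulate_study(simulation_config(n_polar = 15, n_lipid = 10,
                                          n_unknowns = 10, network_size = 8,
                                          seed = 25))
  tab <- knn_impute(filter_by_missingness(filter_by_pool_rsd(
    filter_unknowns(normalize_to_is(sim$table)))))
  prof <- variance_profile(tab)
  expect_equal(nrow(prof), nrow(tab$intensities))
  expect_false(any(duplicated(prof$feature_id)))
  expect_true(all(prof$q_value >= prof$p_value))
  # q monotone in p
  ord <- order(prof$p_value)
  expect_true(all(diff(prof$q_value[ord]) >= -1e-15))
  dir <- withr::local_tempdir()
  paths <- write_variance_profile(prof, dir)
  expect_true(all(file.exists(paths)))
  polar <- read.delim(file.path(dir, "variance_polar.tsv"))
  expect_equal(nrow(polar), sum(prof$platform == "polar"))
})
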