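# Three-level CV decomposition (technical / drill-area / participant) and
# the feature-wise (optionally empirical-Bayes moderated) one-way F-test
# with participant as the factor.

feature_row <- function(table, feature_id) {
  i <- match(feature_id, table$features$feature_id)
  if (is.na(i)) stopf("unknown feature '%s'", feature_id)
  table$intensities[i, ]
}

#' Technical CV of a feature
#'
#' RSD of the feature across the pooled QC injections — repeated
#' measurements of the same material, so their spread is purely technical.
#'
#' @param table A [feature_table()].
#' @param feature_id Feature to evaluate.
#' @return Percent CV.
#' @export
technical_cv <- function(table, feature_id) {
  v <- feature_row(table, feature_id)[table$samples$sample_type == "pool"]
  if (sum(!is.na(v)) < 2)
    stopf("feature '%s': < 2 observed pool values", feature_id)
  rsd(v)
}

#' Drill-area CV of a feature (specimen heterogeneity)
#'
#' For each participant with at least two observed drill replicates, the RSD
#' across that participant's drill areas; the feature's area CV is the mean
#' of these within-participant RSDs. Averaging within participants keeps
#' between-participant variation out of the heterogeneity estimate.
#'
#' @inheritParams technical_cv
#' @return Percent CV.
#' @export
area_cv <- function(table, feature_id) {
  v <- feature_row(table, feature_id)
  study <- table$samples$sample_type == "study"
  per <- split(v[study], table$samples$participant_id[study])
  cvs <- vapply(per, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || mean(x) == 0) NA_real_ else rsd(x)
  }, numeric(1))
  if (all(is.na(cvs)))
    stopf("feature '%s': no participant with >= 2 observed drill values",
          feature_id)
  mean(cvs, na.rm = TRUE)
}

#' Between-participant CV of a feature
#'
#' Each participant is summarized by the mean of their drill replicates; the
#' feature's participant CV is the RSD across these participant means.
#'
#' @inheritParams technical_cv
#' @return Percent CV.
#' @export
participant_cv <- function(table, feature_id) {
  v <- feature_row(table, feature_id)
  study <- table$samples$sample_type == "study"
  means <- vapply(split(v[study], table$samples$participant_id[study]),
                  function(x) mean(x, na.rm = TRUE), numeric(1))
  means <- means[is.finite(means)]
  if (length(means) < 2)
    stopf("feature '%s': < 2 participants with observed values", feature_id)
  rsd(means)
}

#' Feature-wise F-test with participant as factor
#'
#' One-way ANOVA per feature on log intensities over the study samples,
#' with the participant as the grouping factor. With
#' `moderation = "empirical_bayes"` (the default) each feature's
#' within-group variance is shrunk toward a common prior estimated across
#' features by [limma::squeezeVar()], and the moderated F is referred to an
#' F distribution with `(g - 1, d0 + dg)` degrees of freedom; with
#' `moderation = "none"` the ordinary ANOVA F is returned. A feature
#' constant across all samples gets `F = 0`, `p = 1`.
#'
#' @param table A [feature_table()] with at least two participants and
#'   replicate samples.
#' @param moderation `"empirical_bayes"` or `"none"`.
#' @return `data.frame` with columns `feature_id`, `f_statistic`, `p_value`,
#'   `df1`, `df2` (residual df; for the moderated test including the prior
#'   df).
#' @export
feature_f_test <- function(table, moderation = c("empirical_bayes", "none")) {
  moderation <- match.arg(moderation)
  validate_feature_table(table)
  study <- table$samples$sample_type == "study"
  grp <- factor(table$samples$participant_id[study])
  if (nlevels(grp) < 2) stopf("F-test needs >= 2 participants")
  if (max(table(grp)) < 2) stopf("F-test needs replicates within participants")

  L <- safe_log(table$intensities[, study, drop = FALSE])
  obs <- (!is.na(L)) * 1
  Lz <- L
  Lz[obs == 0] <- 0
  G <- stats::model.matrix(~ 0 + grp)          # samples x groups

  n_g <- obs %*% G                              # per-feature group counts
  sum_g <- Lz %*% G
  mean_g <- sum_g / n_g
  mean_g[n_g == 0] <- 0
  n_tot <- rowSums(n_g)
  grand <- rowSums(sum_g) / n_tot

  ssb <- rowSums(n_g * (mean_g - grand)^2)
  sstot <- rowSums(Lz^2 %*% G - 2 * sum_g * mean_g + n_g * mean_g^2)
  ssw <- pmax(sstot, 0)
  g_eff <- rowSums(n_g > 0)
  df1 <- g_eff - 1
  df2 <- n_tot - g_eff
  if (any(df1 < 1) || any(df2 < 1))
    stopf("some features lack groups or replicates for the F-test")

  msb <- ssb / df1
  s2 <- ssw / df2

  if (moderation == "empirical_bayes") {
    sq <- limma::squeezeVar(s2, df2)
    f_stat <- msb / sq$var.post
    df2_out <- df2 + sq$df.prior
  } else {
    f_stat <- msb / s2
    df2_out <- df2
  }
  constant <- ssb == 0 & ssw == 0
  f_stat[constant] <- 0
  f_stat[!constant & s2 == 0 & ssb > 0] <- Inf
  p <- stats::pf(f_stat, df1, df2_out, lower.tail = FALSE)
  p[constant] <- 1
  p[is.infinite(f_stat)] <- 0

  data.frame(feature_id = table$features$feature_id,
             f_statistic = f_stat, p_value = p,
             df1 = df1, df2 = df2_out,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction (via [stats::p.adjust()] with
#' `method = "BH"`), after validating that every input lies in `[0, 1]`.
#'
#' @param p_values Numeric vector of p-values.
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1] and be non-missing")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-feature variance profile (bubble-plot data)
#'
#' Assembles, for every feature, the three CV levels, the moderated F
#' statistic, its p-value and the BH q-value (adjusted jointly across all
#' features in the table) — the tidy data behind per-platform bubble plots
#' of participant CV versus drill-area CV.
#'
#' @param table A QC'd, imputed [feature_table()].
#' @param moderation Passed to [feature_f_test()].
#' @return `data.frame` with columns `feature_id`, `name`, `platform`,
#'   `compound_class`, `cv_technical`, `cv_area`, `cv_participant`,
#'   `f_statistic`, `p_value`, `q_value`.
#' @export
variance_profile <- function(table, moderation = "empirical_bayes") {
  validate_feature_table(table)
  ft <- feature_f_test(table, moderation = moderation)
  cvs <- vapply(table$features$feature_id, function(f) {
    c(technical_cv(table, f), area_cv(table, f), participant_cv(table, f))
  }, numeric(3))
  data.frame(
    feature_id = table$features$feature_id,
    name = table$features$name,
    platform = table$features$platform,
    compound_class = table$features$compound_class,
    cv_technical = cvs[1, ],
    cv_area = cvs[2, ],
    cv_participant = cvs[3, ],
    f_statistic = ft$f_statistic,
    p_value = ft$p_value,
    q_value = bh_adjust(ft$p_value),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write per-platform variance profiles
#'
#' @param profile Output of [variance_profile()].
#' @param out_dir Directory for `variance_<platform>.tsv` files.
#' @return Invisibly, the written paths.
#' @export
write_variance_profile <- function(profile, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (pf in unique(profile$platform)) {
    path <- file.path(out_dir, sprintf("variance_%s.tsv", pf))
    sub <- profile[profile$platform == pf, , drop = FALSE]
    num <- vapply(sub, is.numeric, logical(1))
    sub[num] <- lapply(sub[num], format_full)
    utils::write.table(sub, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Bubble plot of a variance profile
#'
#' Scatter of participant CV against drill-area CV, one point per feature,
#' colored by compound class, with 30% guide lines — requires ggplot2.
#'
#' @param profile Output of [variance_profile()], typically one platform.
#' @return A ggplot object.
#' @export
plot_variance_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_variance_profile requires the ggplot2 package")
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$cv_area, y = .data$cv_participant,
                               color = .data$compound_class,
                               size = .data$cv_technical)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 30, linetype = 2) +
    ggplot2::geom_vline(xintercept = 30, linetype = 2) +
    ggplot2::labs(x = "CV between drill areas (%)",
                  y = "CV between participants (%)",
                  size = "technical CV (%)", color = "class")
}
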