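# QC gate: drop unknowns, drop features failing the pooled-sample RSD
# threshold, drop features with too many missing values, impute the rest.

#' Relative standard deviation (percent CV)
#'
#' `100 * sd(x) / mean(x)` on the raw (linear) scale, with the `n - 1`
#' denominator — the analytical-chemistry %RSD convention.
#'
#' @param values Numeric vector; missing values are dropped. At least two
#'   non-missing values are required and the mean must be nonzero.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stopf("rsd needs >= 2 non-missing values, got %d",
                           length(v))
  m <- mean(v)
  if (m == 0) stopf("rsd undefined: mean is zero")
  100 * stats::sd(v) / m
}

# vectorized row-wise RSD; rows with < 2 observed values get NA
row_rsd <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sq <- rowSums((m - mu)^2, na.rm = TRUE)
  out <- 100 * sqrt(sq / (n - 1)) / mu
  out[n < 2 | mu == 0] <- NA_real_
  out
}

#' Discard level-4 (unknown) features
#'
#' @param table A [feature_table()].
#' @return The table restricted to features with annotation level 1-3.
#' @export
filter_unknowns <- function(table) {
  validate_feature_table(table)
  subset_features(table, table$features$annotation_level != 4L,
                  stage = "unknowns_filter")
}

#' Filter features by pooled-sample RSD
#'
#' Keeps features whose relative standard deviation across the pooled QC
#' injections is at most `threshold` percent ("higher than 30%" excluded,
#' so a feature exactly at the threshold is kept). Features with fewer than
#' two observed pool values cannot be QC'd and are excluded.
#'
#' @param table A [feature_table()] containing at least two pool samples.
#' @param threshold Maximum tolerated pool RSD, percent.
#' @return The filtered table.
#' @export
filter_by_pool_rsd <- function(table, threshold = 30) {
  validate_feature_table(table)
  pool <- table$samples$sample_type == "pool"
  if (sum(pool) < 2)
    stopf("pool-RSD filter needs >= 2 pool samples, found %d", sum(pool))
  pr <- row_rsd(table$intensities[, pool, drop = FALSE])
  keep <- !is.na(pr) & pr <= threshold
  subset_features(table, keep, stage = "pool_rsd_filter")
}

#' Filter features by missingness
#'
#' Removes features missing in strictly more than `max_fraction` of all
#' samples (study and pool alike).
#'
#' @param table A [feature_table()].
#' @param max_fraction Maximum tolerated missing fraction.
#' @return The filtered table.
#' @export
filter_by_missingness <- function(table, max_fraction = 0.20) {
  validate_feature_table(table)
  frac <- rowMeans(is.na(table$intensities))
  subset_features(table, frac <= max_fraction, stage = "missingness_filter")
}

#' Impute remaining missing values by k-nearest neighbors
#'
#' Feature-space kNN on log intensities, in the spirit of the classic
#' microarray imputer: for a missing value of feature *f* in sample *s*, the
#' k features closest to *f* in Euclidean distance — mean squared log
#' difference over commonly observed samples, scaled by the total sample
#' count — among those observed in *s* donate their log values, each
#' centered by its own mean and re-centered to *f*'s mean over the samples
#' the pair shares. The imputed intensity is the exponential of the average
#' donated log value. With fewer than `k` eligible neighbors all available
#' ones are used; with none, the feature's own observed mean log value.
#'
#' @param table A [feature_table()] that already passed the missingness
#'   filter; every feature needs at least one observed value.
#' @param k Number of neighbors (default 10).
#' @return The table with every missing cell imputed (strictly positive).
#' @export
knn_impute <- function(table, k = 10) {
  validate_feature_table(table)
  if (k < 1) stopf("k must be >= 1")
  m <- table$intensities
  if (!any(is.na(m))) return(table)
  L <- safe_log(m)
  obs <- !is.na(L)
  if (any(rowSums(obs) == 0))
    stopf("feature(s) with zero observed values: %s",
          paste(table$features$feature_id[rowSums(obs) == 0], collapse = ", "))

  n_feat <- nrow(L)
  n_samp <- ncol(L)
  Lz <- L
  Lz[!obs] <- 0
  # pairwise mean squared difference over common samples, scaled by n_samp:
  # d2[f,g] = n_samp * sum((Lf - Lg)^2 over common) / n_common
  common <- tcrossprod(obs * 1)                  # common sample counts
  cross <- tcrossprod(Lz)                        # sum Lf*Lg over common
  sq <- tcrossprod(Lz^2, obs * 1)                # sum Lf^2 over common
  ssd <- sq + t(sq) - 2 * cross
  d2 <- n_samp * ssd / common
  d2[common == 0] <- Inf
  diag(d2) <- Inf
  # pair-specific means over common samples
  rowsum_common <- tcrossprod(Lz, obs * 1)       # sum Lf over common(f, g)

  out <- L
  for (f in which(rowSums(!obs) > 0)) {
    cand_all <- which(is.finite(d2[f, ]))
    for (s in which(!obs[f, ])) {
      cand <- cand_all[obs[cand_all, s]]
      if (!length(cand)) {
        out[f, s] <- mean(L[f, obs[f, ]])
        next
      }
      ord <- order(d2[f, cand], cand)
      nb <- cand[ord[seq_len(min(k, length(cand)))]]
      mf <- rowsum_common[f, nb] / common[f, nb]
      mg <- rowsum_common[nb, f] / common[f, nb]
      out[f, s] <- mean(L[nb, s] - mg + mf)
    }
  }
  table$intensities[is.na(m)] <- exp(out[is.na(m)])
  table <- record_stage(table, "knn_imputation", n_feat, n_feat)
  table
}
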