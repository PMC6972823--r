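# Internal-standard normalization: each feature is divided, sample-wise, by
# the same-platform internal standard it correlates with best.

# Correlation of every non-IS feature with every same-platform IS, on log
# intensities over pairwise-complete samples; candidates with < 3 complete
# pairs are disqualified. Returns the mapping data.frame.
is_correlation_map <- function(table) {
  feats <- table$features
  is_idx <- which(feats$is_internal_standard)
  out <- data.frame(feature_id = character(), selected_is = character(),
                    r = numeric(), n_pairs = integer(),
                    stringsAsFactors = FALSE)
  for (pf in unique(feats$platform[!feats$is_internal_standard])) {
    f_idx <- which(feats$platform == pf & !feats$is_internal_standard)
    if (!length(f_idx)) next
    s_idx <- is_idx[feats$platform[is_idx] == pf]
    if (!length(s_idx))
      stopf("no internal standard available on platform '%s'", pf)
    # order candidates by id so that which.max's first-hit rule implements
    # the lexicographic tie-break
    s_idx <- s_idx[order(feats$feature_id[s_idx])]

    lf <- safe_log(t(table$intensities[f_idx, , drop = FALSE]))
    ls <- safe_log(t(table$intensities[s_idx, , drop = FALSE]))
    r <- suppressWarnings(stats::cor(lf, ls, use = "pairwise.complete.obs"))
    n_pairs <- crossprod(!is.na(lf), !is.na(ls))
    # eligibility needs >= 3 complete pairs; an eligible candidate whose
    # correlation is undefined (constant series) stays selectable last
    score <- r
    score[n_pairs >= 3 & is.na(r)] <- -Inf
    score[n_pairs < 3] <- NA_real_

    pick <- integer(length(f_idx))
    for (i in seq_along(f_idx)) {
      si <- score[i, ]
      if (all(is.na(si)))
        stopf("feature '%s': no internal standard with >= 3 complete pairs",
              feats$feature_id[f_idx[i]])
      pick[i] <- which.max(si)
    }
    out <- rbind(out, data.frame(
      feature_id = feats$feature_id[f_idx],
      selected_is = feats$feature_id[s_idx][pick],
      r = r[cbind(seq_along(f_idx), pick)],
      n_pairs = as.integer(n_pairs[cbind(seq_along(f_idx), pick)]),
      stringsAsFactors = FALSE))
  }
  out
}

#' Select the most-correlated internal standard for one feature
#'
#' Among the internal standards of the feature's own platform, returns the
#' one maximizing the Pearson correlation with the feature on log-transformed
#' intensities, computed over samples where both are observed. Candidates
#' with fewer than 3 complete pairs are skipped; ties break lexicographically
#' by internal-standard id.
#'
#' @param table A [feature_table()].
#' @param feature_id Feature to map.
#' @return The selected internal standard's feature id, with attributes `r`
#'   (the correlation) and `n_pairs`.
#' @export
select_internal_standard <- function(table, feature_id) {
  validate_feature_table(table)
  if (!feature_id %in% table$features$feature_id)
    stopf("unknown feature '%s'", feature_id)
  keep <- table$features$is_internal_standard |
    table$features$feature_id == feature_id
  map <- is_correlation_map(subset_features(table, keep))
  row <- map[map$feature_id == feature_id, ]
  structure(row$selected_is, r = row$r, n_pairs = row$n_pairs)
}

#' Normalize every feature to its most-correlated internal standard
#'
#' Divides each non-IS feature, sample by sample, by the intensity of its
#' selected internal standard; samples where the standard is missing become
#' missing. Internal-standard features are dropped from the output. The
#' feature-to-IS mapping (with correlations and pair counts) is attached as
#' attribute `"is_mapping"`.
#'
#' @param table A [feature_table()]; every platform present must carry at
#'   least one internal standard.
#' @return The normalized `feature_table` (intensities are now unitless
#'   ratios).
#' @export
normalize_to_is <- function(table) {
  validate_feature_table(table)
  map <- is_correlation_map(table)
  n_in <- nrow(table$intensities)

  out <- subset_features(table, !table$features$is_internal_standard)
  ord <- match(out$features$feature_id, map$feature_id)
  is_mat <- table$intensities[map$selected_is[ord], , drop = FALSE]
  is_mat[!is.na(is_mat) & is_mat <= 0] <- NA_real_
  out$intensities <- out$intensities / is_mat
  rownames(out$intensities) <- out$features$feature_id

  out <- record_stage(out, "is_normalization", n_in, nrow(out$intensities))
  attr(out, "is_mapping") <- map[ord, , drop = FALSE]
  validate_feature_table(out)
  out
}
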