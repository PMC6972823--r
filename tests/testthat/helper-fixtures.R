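# Small in-code fixtures shared across tests.

# A hand-built table: `n_feat` features x (participants x areas + pools),
# with optional internal standards per platform.
toy_table <- function(intensities, platform = NULL, annotation_level = NULL,
                      is_internal_standard = NULL, n_pools = 0,
                      participants = NULL, areas = NULL) {
  n_feat <- nrow(intensities)
  n_samp <- ncol(intensities)
  n_study <- n_samp - n_pools
  if (is.null(participants)) participants <- rep("P01", n_study)
  if (is.null(areas)) areas <- seq_len(n_study)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samp)),
    participant_id = c(participants, rep(NA_character_, n_pools)),
    drill_area = c(areas, rep(NA_integer_, n_pools)),
    sample_type = c(rep("study", n_study), rep("pool", n_pools)),
    stringsAsFactors = FALSE)
  if (is.null(platform)) platform <- rep("polar", n_feat)
  if (is.null(annotation_level)) annotation_level <- rep(2L, n_feat)
  if (is.null(is_internal_standard)) is_internal_standard <- rep(FALSE, n_feat)
  annotation_level[is_internal_standard] <- 1L
  features <- data.frame(
    feature_id = sprintf("F%02d", seq_len(n_feat)),
    name = sprintf("feature %02d", seq_len(n_feat)),
    platform = platform,
    compound_class = rep_len(c("amino acid", "Cer"), n_feat),
    annotation_level = annotation_level,
    is_internal_standard = is_internal_standard,
    stringsAsFactors = FALSE)
  feature_table(intensities, samples, features)
}

# subset a feature_table by feature for fixtures (keeps metadata aligned)
subset_features_for_test <- function(tab, keep) {
  feature_table(tab$intensities[keep, , drop = FALSE], tab$samples,
                tab$features[keep, , drop = FALSE])
}

# random correlation matrix from n draws of p variables (always PD for n > p)
random_corr <- function(p, n = 40, seed = 1) {
  set.seed(seed)
  stats::cor(matrix(stats::rnorm(n * p), n, p))
}

# edge sets of a precision/partial-correlation matrix as "i j" keys (i < j)
edge_keys <- function(m, ids = rownames(m), zero_tol = 1e-8) {
  ut <- which(upper.tri(m) & abs(m) > zero_tol, arr.ind = TRUE)
  paste(ids[ut[, 1]], ids[ut[, 2]])
}

# undirected match: predicted "a b" keys against true keys in either order
support_metrics <- function(pred, truth_keys_both) {
  tp <- sum(pred %in% truth_keys_both)
  c(precision = tp / max(length(pred), 1),
    recall = 2 * tp / max(length(truth_keys_both), 1))
}
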