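# Cross-platform integration: auto-scaled log intensities averaged per
# individual and per compound category, combined and row-scaled for heatmap
# display.

#' Average study samples to one row per individual
#'
#' Auto-scales the log intensities of the study samples feature-wise, then
#' averages each participant's drill replicates, yielding an individuals x
#' features matrix. (Pass `autoscaled = FALSE` to average raw log values.)
#'
#' @param table A [feature_table()] with study samples.
#' @param autoscaled Auto-scale features before averaging (default TRUE).
#' @return Numeric matrix, individuals x features.
#' @export
average_over_replicates <- function(table, autoscaled = TRUE) {
  validate_feature_table(table)
  study <- table$samples$sample_type == "study"
  if (!any(study)) stopf("no study samples to average")
  L <- t(safe_log(table$intensities[, study, drop = FALSE]))
  if (autoscaled) L <- autoscale(L)
  grp <- table$samples$participant_id[study]
  counts <- rowsum((!is.na(L)) * 1, grp)
  sums <- rowsum(ifelse(is.na(L), 0, L), grp)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  out
}

#' Average features into compound categories
#'
#' Per individual, the mean over all features of each compound class;
#' category columns are ordered by platform then class name and labeled
#' `"<platform>: <class>"`.
#'
#' @param m Individuals x features matrix (columns named by feature id).
#' @param features Feature metadata covering every column.
#' @return Individuals x categories matrix.
#' @export
average_over_categories <- function(m, features) {
  meta <- features[match(colnames(m), features$feature_id), , drop = FALSE]
  if (any(is.na(meta$feature_id)))
    stopf("feature metadata missing for: %s",
          paste(colnames(m)[is.na(meta$feature_id)], collapse = ", "))
  cat_key <- paste(meta$platform, meta$compound_class, sep = ": ")
  cats <- sort(unique(cat_key))
  out <- vapply(cats, function(cc)
    rowMeans(m[, cat_key == cc, drop = FALSE], na.rm = TRUE),
    numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(m), cats))
  out
}

#' Combine platform category summaries and row-scale
#'
#' Column-binds the per-platform individuals x categories matrices (over
#' identical individuals) and standardizes each individual's row to mean 0,
#' sd 1 (`n - 1`) — the matrix behind the cross-platform heatmap.
#'
#' @param polar_summary,lipid_summary Individuals x categories matrices
#'   with matching row names.
#' @return The combined, row-scaled matrix.
#' @export
combine_and_rowscale <- function(polar_summary, lipid_summary) {
  only_p <- setdiff(rownames(polar_summary), rownames(lipid_summary))
  only_l <- setdiff(rownames(lipid_summary), rownames(polar_summary))
  if (length(only_p) || length(only_l))
    stopf("individual sets differ: only in first [%s]; only in second [%s]",
          paste(only_p, collapse = ", "), paste(only_l, collapse = ", "))
  comb <- cbind(polar_summary,
                lipid_summary[rownames(polar_summary), , drop = FALSE])
  if (ncol(comb) < 2)
    stopf("row-scaling needs >= 2 categories, got %d", ncol(comb))
  sds <- apply(comb, 1, stats::sd)
  if (any(!is.finite(sds) | sds == 0))
    stopf("cannot row-scale constant row(s): %s",
          paste(rownames(comb)[!is.finite(sds) | sds == 0], collapse = ", "))
  rowscale(comb)
}

rowscale <- function(m) {
  out <- t(scale(t(m)))
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Cross-platform integration matrix
#'
#' Chains [average_over_replicates()], [average_over_categories()] per
#' platform, and [combine_and_rowscale()] on a QC'd, imputed table holding
#' both platforms.
#'
#' @param table A [feature_table()].
#' @return Row-scaled individuals x categories matrix.
#' @export
integration_matrix <- function(table) {
  validate_feature_table(table)
  split_tab <- function(pf)
    subset_features(table, table$features$platform == pf)
  summaries <- lapply(c("polar", "lipid"), function(pf) {
    sub <- split_tab(pf)
    if (nrow(sub$intensities) == 0) return(NULL)
    average_over_categories(average_over_replicates(sub), sub$features)
  })
  if (is.null(summaries[[1]])) return(summaries[[2]])
  if (is.null(summaries[[2]])) {
    if (ncol(summaries[[1]]) < 2) stopf("row-scaling needs >= 2 categories")
    return(rowscale(summaries[[1]]))
  }
  combine_and_rowscale(summaries[[1]], summaries[[2]])
}

#' Write the integration matrix as tidy TSV
#'
#' @param m Output of [integration_matrix()].
#' @param path Output TSV path (`individual`, `category`, `value`).
#' @return Invisibly, `path`.
#' @export
write_integration_matrix <- function(m, path) {
  df <- data.frame(
    individual = rep(rownames(m), times = ncol(m)),
    category = rep(colnames(m), each = nrow(m)),
    value = format_full(as.vector(m)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
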