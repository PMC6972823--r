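# Partial-correlation network machinery: auto-scaling, rotation-based
# penalty selection, network construction, hub analysis, exports.

#' Auto-scale a data matrix
#'
#' Column-wise standardization to mean 0 and standard deviation 1
#' (`n - 1` denominator) — the usual metabolomics "auto-scaling".
#'
#' @param m Numeric matrix, observations x features; every column needs at
#'   least two distinct values.
#' @return The standardized matrix.
#' @export
autoscale <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2, stats::sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad)) {
    nm <- colnames(m)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stopf("cannot auto-scale constant column(s): %s", paste(nm, collapse = ", "))
  }
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Rotation-based penalty for the graphical LASSO
#'
#' Calibrates the L1 penalty to the largest spurious correlation expected
#' under independence: each rotation independently permutes the rows of
#' every column (destroying all cross-feature dependence while preserving
#' marginals) and records the maximum absolute off-diagonal Pearson
#' correlation; the penalty is the mean of these maxima. Permutations are
#' seeded per (rotation, column), so the result is reproducible from
#' `seed` alone.
#'
#' @param data Numeric matrix, individuals x features (>= 3 rows, >= 2
#'   columns), typically auto-scaled.
#' @param n_rotations Number of rotations to average (default 50).
#' @param seed Integer seed.
#' @return The penalty `lambda`, with attribute `rotation_maxima`.
#' @export
ric_lambda <- function(data, n_rotations = 50, seed = 1) {
  data <- as.matrix(data)
  n <- nrow(data)
  p <- ncol(data)
  if (n < 3) stopf("ric_lambda needs >= 3 rows, got %d", n)
  if (p < 2) stopf("ric_lambda needs >= 2 columns")
  if (n_rotations < 1) stopf("n_rotations must be >= 1")

  maxima <- numeric(n_rotations)
  for (r in seq_len(n_rotations)) {
    rot <- data
    for (j in seq_len(p)) {
      perm <- with_seed(derive_seed(seed, r, j), sample.int(n))
      rot[, j] <- data[perm, j]
    }
    cc <- suppressWarnings(stats::cor(rot))
    maxima[r] <- max(abs(cc[upper.tri(cc)]), na.rm = TRUE)
  }
  structure(mean(maxima), rotation_maxima = maxima)
}

#' Build a signed network from a partial-correlation matrix
#'
#' Edges are all pairs whose absolute partial correlation exceeds
#' `edge_threshold` (which separates numerical zeros from shrunk-but-real
#' couplings); the hub is the node of maximal degree, ties broken first by
#' larger total absolute edge weight, then lexicographically.
#'
#' @param pcorr Symmetric partial-correlation matrix with zero diagonal;
#'   row/column names are the node ids.
#' @param node_meta `data.frame` of feature metadata (`feature_id`, `name`,
#'   `platform`, `compound_class`) covering every node.
#' @param edge_threshold Minimum absolute partial correlation for an edge.
#' @return A list of class `network_model` with elements `edges`
#'   (`node_i`, `node_j`, `weight`, `sign`), `nodes` (id, name, platform,
#'   shape — circles for lipids, rectangles for polar metabolites — class,
#'   degree), `hub`, and `pcorr`.
#' @export
build_network <- function(pcorr, node_meta, edge_threshold = 1e-8) {
  if (nrow(pcorr) == 0) stopf("empty node set")
  ids <- rownames(pcorr)
  if (is.null(ids)) ids <- node_meta$feature_id[seq_len(nrow(pcorr))]
  if (max(abs(pcorr - t(pcorr))) > 1e-8) stopf("pcorr must be symmetric")
  meta <- node_meta[match(ids, node_meta$feature_id), , drop = FALSE]
  if (any(is.na(meta$feature_id)))
    stopf("node metadata missing for: %s",
          paste(ids[is.na(meta$feature_id)], collapse = ", "))

  ut <- which(upper.tri(pcorr) & abs(pcorr) > edge_threshold, arr.ind = TRUE)
  edges <- data.frame(
    node_i = ids[ut[, 1]], node_j = ids[ut[, 2]],
    weight = pcorr[ut],
    sign = ifelse(pcorr[ut] > 0, "positive", "inverse"),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_i, edges$node_j), , drop = FALSE]
  rownames(edges) <- NULL

  degree <- stats::setNames(integer(length(ids)), ids)
  strength <- stats::setNames(numeric(length(ids)), ids)
  for (k in seq_len(nrow(edges))) {
    for (nd in c(edges$node_i[k], edges$node_j[k])) {
      degree[nd] <- degree[nd] + 1L
      strength[nd] <- strength[nd] + abs(edges$weight[k])
    }
  }
  ord <- order(-degree, -strength, ids)
  hub <- ids[ord[1]]

  nodes <- data.frame(
    id = ids, name = meta$name, platform = meta$platform,
    shape = ifelse(meta$platform == "lipid", "circle", "rectangle"),
    compound_class = meta$compound_class,
    degree = as.integer(degree),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(edges = edges, nodes = nodes, hub = hub, pcorr = pcorr),
            class = "network_model")
}

#' Spearman correlation of every feature with the hub
#'
#' Rank correlation (average ranks on ties) between each column and the hub
#' column across individuals; used to color network nodes. The hub itself
#' maps to 1.
#'
#' @param data Numeric matrix, individuals x features, with column names;
#'   >= 3 rows.
#' @param hub Hub column name.
#' @return Named vector of Spearman correlations in `[-1, 1]`.
#' @export
spearman_to_hub <- function(data, hub) {
  data <- as.matrix(data)
  if (nrow(data) < 3) stopf("spearman_to_hub needs >= 3 individuals")
  if (!hub %in% colnames(data)) stopf("hub column '%s' not present", hub)
  h <- data[, hub]
  if (stats::sd(h) == 0) stopf("hub column '%s' is constant", hub)
  rho <- suppressWarnings(
    as.vector(stats::cor(data, h, method = "spearman")))
  names(rho) <- colnames(data)
  rho[hub] <- 1
  rho
}

#' Infer a partial-correlation network from a feature table
#'
#' The full network stage: log-transform, aggregate study samples (by
#' default to one mean value per participant, since the network describes
#' between-person covariation), auto-scale, estimate the correlation
#' matrix, select the penalty by [ric_lambda()], fit [graphical_lasso()],
#' convert to partial correlations, build the signed network, and compute
#' every node's Spearman correlation to the hub. All intermediates are kept
#' in the returned model for audit.
#'
#' @param table A QC'd, imputed [feature_table()].
#' @param level `"participant_mean"` (default) or `"all_study_samples"`.
#' @param seed Integer seed driving the rotation permutations.
#' @param n_rotations Rotations for [ric_lambda()].
#' @param edge_threshold Passed to [build_network()].
#' @return A `network_model` list: `lambda`, `precision`, `pcorr`, `edges`,
#'   `nodes`, `hub`, `hub_spearman`, `data` (the auto-scaled matrix),
#'   `correlation`, `converged`, `level`, `seed`.
#' @export
infer_network <- function(table,
                          level = c("participant_mean", "all_study_samples"),
                          seed = 1, n_rotations = 50, edge_threshold = 1e-8) {
  level <- match.arg(level)
  validate_feature_table(table)
  if (any(is.na(table$intensities)))
    stopf("infer_network requires an imputed table (no missing values)")

  study <- table$samples$sample_type == "study"
  L <- t(safe_log(table$intensities[, study, drop = FALSE]))
  if (level == "participant_mean") {
    grp <- table$samples$participant_id[study]
    L <- rowsum(L, grp) / as.vector(table(grp)[sort(unique(grp))])
  }
  X <- autoscale(L)
  S <- stats::cor(X)
  lambda <- ric_lambda(X, n_rotations = n_rotations, seed = seed)
  Theta <- graphical_lasso(S, as.numeric(lambda))
  rho <- partial_correlations(Theta)
  dimnames(rho) <- dimnames(S)
  model <- build_network(rho, table$features, edge_threshold = edge_threshold)
  model$hub_spearman <- spearman_to_hub(X, model$hub)
  model$lambda <- as.numeric(lambda)
  model$rotation_maxima <- attr(lambda, "rotation_maxima")
  model$precision <- Theta
  model$correlation <- S
  model$data <- X
  model$converged <- attr(Theta, "converged")
  model$level <- level
  model$seed <- as.integer(seed)
  model
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d nodes, %d edges (%d positive, %d inverse)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "inverse")))
  if (!is.null(x$lambda))
    cat(sprintf("  lambda = %.4f (%s)\n", x$lambda,
                if (isTRUE(x$converged)) "converged" else "not converged"))
  cat(sprintf("  hub: %s (degree %d)\n", x$hub,
              x$nodes$degree[x$nodes$id == x$hub]))
  invisible(x)
}

#' Write network artifacts
#'
#' Emits `edges.tsv`, `nodes.tsv` (with hub-Spearman node colors and
#' platform shapes), a GraphML file carrying the same attributes, and
#' `network_model.json` (penalty, convergence flag, hub).
#'
#' @param model A `network_model` from [infer_network()].
#' @param out_dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_network <- function(model, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- model$nodes
  if (!is.null(model$hub_spearman))
    nodes$spearman_to_hub <- as.numeric(model$hub_spearman[nodes$id])

  p_edges <- file.path(out_dir, "edges.tsv")
  p_nodes <- file.path(out_dir, "nodes.tsv")
  p_graph <- file.path(out_dir, "network.graphml")
  p_json <- file.path(out_dir, "network_model.json")

  ed <- model$edges
  ed$weight <- format_full(ed$weight)
  utils::write.table(ed, p_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  nd <- nodes
  if (!is.null(nd$spearman_to_hub))
    nd$spearman_to_hub <- format_full(nd$spearman_to_hub)
  utils::write.table(nd, p_nodes, sep = "\t", quote = FALSE, row.names = FALSE)

  g <- igraph::graph_from_data_frame(model$edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, p_graph, format = "graphml")

  jsonlite::write_json(
    list(lambda = model$lambda, converged = isTRUE(model$converged),
         hub = model$hub, n_nodes = nrow(model$nodes),
         n_edges = nrow(model$edges), level = model$level,
         seed = model$seed),
    p_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(edges = p_edges, nodes = p_nodes, graphml = p_graph,
              json = p_json))
}
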