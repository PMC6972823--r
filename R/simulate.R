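# Synthetic-study generator: hierarchical log-normal intensities over a
# participants x drill-areas design with pooled QC injections, platform-wise
# extraction/drift factors, internal standards, below-LOD censoring, and a
# planted sparse Gaussian graphical model on a feature subset.

polar_classes <- c("amino acid", "benzene derivative", "carboxylic acid",
                   "fatty acid derivative", "indole derivative", "amine",
                   "purine derivative", "pyrimidine derivative")
lipid_classes <- c("Cer", "DG", "TG", "PC", "LPC", "SM", "PG", "PI")

#' Convert a log-scale standard deviation to a coefficient of variation
#'
#' For a log-normal variable with log-scale standard deviation `sigma`, the
#' coefficient of variation is `100 * sqrt(exp(sigma^2) - 1)` percent,
#' independent of the mean.
#'
#' @param sigma Non-negative log-scale standard deviation.
#' @return CV in percent.
#' @seealso [cv_to_sigma()] for the inverse.
#' @export
expected_cv <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stopf("sigma must be non-negative and finite")
  100 * sqrt(exp(sigma^2) - 1)
}

#' @rdname expected_cv
#' @param cv CV in percent.
#' @export
cv_to_sigma <- function(cv) {
  if (any(!is.finite(cv)) || any(cv < 0)) stopf("cv must be non-negative")
  sqrt(log(1 + (cv / 100)^2))
}

#' Simulation configuration
#'
#' Defaults reproduce the study design the analysis is built for: 10
#' participants each cryogenically drilled in 4 areas, 8 pooled QC
#' injections, 182 annotated polar + 116 annotated lipid features plus 2028
#' level-4 unknowns (2326 features in total), 3 internal standards per
#' platform, and log-normal variance components of 10% (technical), 25%
#' (drill area) and 60% (participant) CV.
#'
#' @param n_participants,n_areas,n_pools Design sizes.
#' @param n_polar,n_lipid,n_unknowns Feature counts (annotated polar,
#'   annotated lipid, level-4 unknowns).
#' @param n_is_per_platform Internal standards spiked per platform.
#' @param cv_technical,cv_area,cv_participant Variance components, percent CV.
#' @param sigma_extraction Log-scale SD of the per-sample, per-platform
#'   extraction/injection drift factor shared by all features of a platform
#'   (internal standards included) in one sample.
#' @param network_size Number of annotated features whose participant-level
#'   effects follow a planted Gaussian graphical model.
#' @param network_density Fraction of possible edges in the planted model.
#' @param network_hub_degree If positive, the first network feature is
#'   forced to have at least this many true neighbors (a planted hub).
#' @param lod_quantile Per-platform quantile below which intensities are
#'   censored to missing (limit of detection).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 10, n_areas = 4, n_pools = 8,
                              n_polar = 182, n_lipid = 116, n_unknowns = 2028,
                              n_is_per_platform = 3,
                              cv_technical = 10, cv_area = 25,
                              cv_participant = 60,
                              sigma_extraction = 0.3,
                              network_size = 30, network_density = 0.1,
                              network_hub_degree = 0,
                              lod_quantile = 0.05, seed = 1) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_areas = as.integer(n_areas), n_pools = as.integer(n_pools),
              n_polar = as.integer(n_polar), n_lipid = as.integer(n_lipid),
              n_unknowns = as.integer(n_unknowns),
              n_is_per_platform = as.integer(n_is_per_platform),
              cv_technical = cv_technical, cv_area = cv_area,
              cv_participant = cv_participant,
              sigma_extraction = sigma_extraction,
              network_size = as.integer(network_size),
              network_density = network_density,
              network_hub_degree = as.integer(network_hub_degree),
              lod_quantile = lod_quantile, seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_participants, n_areas, n_pools, n_polar, n_lipid,
              n_is_per_platform) < 1) || n_unknowns < 0)
      stopf("all design counts must be positive (n_unknowns >= 0)")
    if (any(c(cv_technical, cv_area, cv_participant) <= 0))
      stopf("cv values must be > 0")
    if (sigma_extraction < 0) stopf("sigma_extraction must be >= 0")
    if (network_density < 0 || network_density > 1)
      stopf("network_density must be in [0, 1]")
    if (lod_quantile < 0 || lod_quantile >= 1)
      stopf("lod_quantile must be in [0, 1)")
    if (network_size > n_polar + n_lipid)
      stopf("network_size (%d) exceeds annotated feature count (%d)",
            network_size, n_polar + n_lipid)
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate a sparse symmetric positive-definite precision matrix
#'
#' Off-diagonal support is drawn uniformly at random at the requested edge
#' density; nonzero partial couplings are uniform on +/-\[0.2, 0.5\]; the
#' diagonal is set to each row's absolute off-diagonal sum plus 0.5, which
#' makes the matrix strictly diagonally dominant and hence positive
#' definite.
#'
#' @param p Dimension (>= 2).
#' @param density Fraction of the `p(p-1)/2` possible edges to make nonzero.
#' @param seed Integer seed.
#' @param hub_degree If positive, node 1 is additionally connected to nodes
#'   `2..hub_degree+1` (a planted hub).
#' @return A `p x p` symmetric positive-definite matrix.
#' @export
simulate_precision <- function(p, density, seed, hub_degree = 0) {
  if (p < 2) stopf("p must be >= 2")
  if (density < 0 || density > 1) stopf("density must be in [0, 1]")
  if (hub_degree > p - 1) stopf("hub_degree must be < p")
  with_seed(seed, {
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    n_edges <- round(density * nrow(pairs))
    sel <- if (n_edges > 0) sample.int(nrow(pairs), n_edges) else integer(0)
    K <- matrix(0, p, p)
    if (length(sel)) {
      vals <- stats::runif(length(sel), 0.2, 0.5) *
        sample(c(-1, 1), length(sel), replace = TRUE)
      K[pairs[sel, , drop = FALSE]] <- vals
    }
    if (hub_degree > 0) {
      nb <- 2:(hub_degree + 1)
      new <- nb[K[1, nb] == 0]
      if (length(new))
        K[1, new] <- stats::runif(length(new), 0.2, 0.5) *
          sample(c(-1, 1), length(new), replace = TRUE)
    }
    K <- K + t(K)
    diag(K) <- rowSums(abs(K)) + 0.5
    K
  })
}

#' Simulate a complete study with ground truth
#'
#' Generates a [feature_table()] under the hierarchical log-normal model:
#' for feature *f*, participant *i*, drill area *a*, in sample *j*,
#' `log x = mu_f + s_j + b_fi + d_fia + e`, with `mu_f` uniform on
#' `[log 1e4, log 1e6]`; `s_j` a per-sample, per-platform extraction/drift
#' factor `N(0, sigma_extraction^2)` shared by every feature of that
#' platform in sample *j*; participant effects `b ~ N(0, sigma_P^2)` (for
#' the `network_size` selected features, jointly multivariate normal with
#' covariance the inverse of the planted precision matrix, rescaled so each
#' marginal variance is `sigma_P^2`); area effects `d ~ N(0, sigma_A^2)`;
#' and technical noise `e ~ N(0, sigma_T^2)`. The sigmas derive from the
#' configured CVs through [cv_to_sigma()].
#'
#' Internal standards represent a constant spiked amount: they carry only
#' `mu_f + s_j`, so dividing a feature by its internal standard removes the
#' drift factor without adding noise. Level-4 unknowns carry no biological
#' signal (`b = d = 0`) and doubled technical noise. Pooled QC samples are
#' the grand mean of the study material (mean of `b + d` over all study
#' aliquots) plus a fresh drift factor and fresh technical noise, so their
#' spread estimates technical variation by construction. Finally, any
#' non-IS intensity below its platform's `lod_quantile` quantile is
#' censored to missing.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `table` (the `feature_table`) and `truth`
#'   (sigmas, planted precision matrix and its feature ids, the nominal
#'   feature-to-IS assignment, LOD thresholds, censored positions, seed).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  sigma_T <- cv_to_sigma(cfg$cv_technical)
  sigma_A <- cv_to_sigma(cfg$cv_area)
  sigma_P <- cv_to_sigma(cfg$cv_participant)

  nP <- cfg$n_participants; nA <- cfg$n_areas; nQ <- cfg$n_pools
  n_study <- nP * nA
  n_samp <- n_study + nQ

  # ---- metadata -------------------------------------------------------------
  participants <- sprintf("P%02d", seq_len(nP))
  study_ids <- as.vector(t(outer(participants, seq_len(nA),
                                 function(p, a) sprintf("%s_A%d", p, a))))
  pool_ids <- sprintf("POOL_%02d", seq_len(nQ))
  samples <- data.frame(
    sample_id = c(study_ids, pool_ids),
    participant_id = c(rep(participants, each = nA), rep(NA_character_, nQ)),
    drill_area = c(rep(seq_len(nA), nP), rep(NA_integer_, nQ)),
    sample_type = c(rep("study", n_study), rep("pool", nQ)),
    stringsAsFactors = FALSE)

  make_features <- function(platform, n_annot, n_is, classes) {
    is_ids <- sprintf("IS_%s_%d", platform, seq_len(n_is))
    an_ids <- sprintf("%s_%04d", toupper(substr(platform, 1, 3)),
                      seq_len(n_annot))
    data.frame(
      feature_id = c(is_ids, an_ids),
      name = c(sprintf("internal standard %s %d", platform, seq_len(n_is)),
               sprintf("%s metabolite %04d", platform, seq_len(n_annot))),
      platform = platform,
      compound_class = c(rep("internal standard", n_is),
                         rep_len(classes, n_annot)),
      annotation_level = c(rep(1L, n_is),
                           rep_len(1:3, n_annot)),
      is_internal_standard = c(rep(TRUE, n_is), rep(FALSE, n_annot)),
      stringsAsFactors = FALSE)
  }
  feats <- rbind(
    make_features("polar", cfg$n_polar, cfg$n_is_per_platform, polar_classes),
    make_features("lipid", cfg$n_lipid, cfg$n_is_per_platform, lipid_classes))
  if (cfg$n_unknowns > 0) {
    feats <- rbind(feats, data.frame(
      feature_id = sprintf("UNK_%04d", seq_len(cfg$n_unknowns)),
      name = sprintf("unknown %04d", seq_len(cfg$n_unknowns)),
      platform = rep_len(c("polar", "lipid"), cfg$n_unknowns),
      compound_class = "unknown",
      annotation_level = 4L,
      is_internal_standard = FALSE,
      stringsAsFactors = FALSE))
  }
  n_feat <- nrow(feats)
  is_is <- feats$is_internal_standard
  is_unknown <- feats$annotation_level == 4L

  # network features: annotated, split across platforms in proportion
  annot_polar <- feats$feature_id[feats$platform == "polar" & !is_is & !is_unknown]
  annot_lipid <- feats$feature_id[feats$platform == "lipid" & !is_is & !is_unknown]
  n_net_polar <- min(length(annot_polar),
                     round(cfg$network_size * cfg$n_polar /
                             (cfg$n_polar + cfg$n_lipid)))
  net_ids <- c(annot_polar[seq_len(n_net_polar)],
               annot_lipid[seq_len(cfg$network_size - n_net_polar)])
  net_idx <- match(net_ids, feats$feature_id)

  truth <- list(sigma_T = sigma_T, sigma_A = sigma_A, sigma_P = sigma_P,
                sigma_extraction = cfg$sigma_extraction, seed = cfg$seed)

  logm <- with_seed(cfg$seed, {
    K <- simulate_precision(cfg$network_size, cfg$network_density,
                            seed = derive_seed(cfg$seed, 1),
                            hub_degree = cfg$network_hub_degree)
    # scale the implied covariance to unit marginals first (numerically
    # stable even for tiny sigma_P), then multiply effects by sigma_P
    Sig_corr <- stats::cov2cor(solve(K))
    Sig <- Sig_corr * sigma_P^2          # marginal variances = sigma_P^2

    mu <- stats::runif(n_feat, log(1e4), log(1e6))

    # per-platform, per-sample drift factors
    s_fac <- matrix(stats::rnorm(2 * n_samp, 0, cfg$sigma_extraction),
                    nrow = 2, dimnames = list(c("polar", "lipid"), NULL))

    # participant effects
    b <- matrix(stats::rnorm(n_feat * nP, 0, sigma_P), n_feat, nP)
    z <- matrix(stats::rnorm(cfg$network_size * nP), cfg$network_size, nP)
    b[net_idx, ] <- sigma_P * crossprod(chol(Sig_corr), z)
    b[is_is | is_unknown, ] <- 0

    # area effects
    d <- matrix(stats::rnorm(n_feat * n_study, 0, sigma_A), n_feat, n_study)
    d[is_is | is_unknown, ] <- 0

    # technical noise (IS: none; unknowns: doubled)
    eps_sd <- rep(sigma_T, n_feat)
    eps_sd[is_unknown] <- 2 * sigma_T
    eps_sd[is_is] <- 0
    eps <- matrix(stats::rnorm(n_feat * n_samp), n_feat, n_samp) * eps_sd

    part_of <- rep(seq_len(nP), each = nA)
    lm <- matrix(0, n_feat, n_samp)
    s_row <- s_fac[ifelse(feats$platform == "polar", 1L, 2L), , drop = FALSE]
    s_per_feat <- s_row[cbind(rep(seq_len(n_feat), n_samp),
                              rep(seq_len(n_samp), each = n_feat))]
    dim(s_per_feat) <- c(n_feat, n_samp)

    lm[, seq_len(n_study)] <- mu + b[, part_of] + d
    pool_mean <- rowMeans(b[, part_of, drop = FALSE] + d)
    lm[, n_study + seq_len(nQ)] <- mu + pool_mean
    lm <- lm + s_per_feat + eps

    truth$true_precision <- K
    truth$true_covariance <- Sig
    truth$network_features <- net_ids
    truth$mu <- stats::setNames(mu, feats$feature_id)
    lm
  })

  ints <- exp(logm)
  rownames(ints) <- feats$feature_id
  colnames(ints) <- samples$sample_id

  # below-LOD censoring per platform over non-IS intensities
  lod <- c(polar = NA_real_, lipid = NA_real_)
  censored <- data.frame(feature_id = character(), sample_id = character(),
                         stringsAsFactors = FALSE)
  if (cfg$lod_quantile > 0) {
    for (pf in c("polar", "lipid")) {
      rows <- feats$platform == pf & !is_is
      if (!any(rows)) next
      thr <- stats::quantile(ints[rows, , drop = FALSE], cfg$lod_quantile,
                             names = FALSE)
      lod[pf] <- thr
      hit <- which(ints < thr & rows, arr.ind = TRUE)
      if (nrow(hit)) {
        censored <- rbind(censored, data.frame(
          feature_id = feats$feature_id[hit[, 1]],
          sample_id = samples$sample_id[hit[, 2]],
          stringsAsFactors = FALSE))
        ints[hit] <- NA_real_
      }
    }
  }
  truth$lod_threshold <- lod
  truth$censored_positions <- censored
  # nominal assignment: every non-IS feature maps to its platform's first IS
  # (all IS of a platform carry the same drift factor, so any is valid)
  truth$is_assignment <- stats::setNames(
    sprintf("IS_%s_1", feats$platform[!is_is]), feats$feature_id[!is_is])
  truth$config <- unclass(cfg)

  tab <- feature_table(ints, samples, feats)
  tab <- record_stage(tab, "simulated", n_feat, n_feat)
  list(table = tab, truth = truth)
}
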