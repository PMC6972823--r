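#' Construct a feature table
#'
#' The central container of the package: an intensity matrix (features in
#' rows, samples in columns, arbitrary units, `NA` for missing) together
#' with sample metadata and feature metadata. All pipeline stages consume
#' and return `feature_table` objects.
#'
#' @param intensities Numeric matrix, features x samples. Entries must be
#'   `NA` or finite and non-negative. Row and column names are set from the
#'   metadata identifiers.
#' @param samples `data.frame` with columns `sample_id`, `participant_id`,
#'   `drill_area` (integer, area within a specimen), `sample_type`
#'   (`"study"` or `"pool"`). Study samples must carry participant and area;
#'   pooled quality-control samples must carry neither.
#' @param features `data.frame` with columns `feature_id`, `name`,
#'   `platform` (`"polar"` or `"lipid"`), `compound_class`,
#'   `annotation_level` (1 = authentic standard ... 4 = unknown), and
#'   `is_internal_standard` (logical; internal standards must be level 1).
#'
#' @return An object of class `feature_table`.
#' @seealso [read_feature_table()], [write_feature_table()],
#'   [merge_platforms()]
#' @export
feature_table <- function(intensities, samples, features) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"

  req_s <- c("sample_id", "participant_id", "drill_area", "sample_type")
  req_f <- c("feature_id", "name", "platform", "compound_class",
             "annotation_level", "is_internal_standard")
  miss <- setdiff(req_s, names(samples))
  if (length(miss)) stopf("sample metadata lacks column(s): %s",
                          paste(miss, collapse = ", "))
  miss <- setdiff(req_f, names(features))
  if (length(miss)) stopf("feature metadata lacks column(s): %s",
                          paste(miss, collapse = ", "))

  samples$sample_id <- as.character(samples$sample_id)
  samples$participant_id <- as.character(samples$participant_id)
  samples$drill_area <- suppressWarnings(as.integer(samples$drill_area))
  samples$sample_type <- as.character(samples$sample_type)
  features$feature_id <- as.character(features$feature_id)
  features$name <- as.character(features$name)
  features$platform <- as.character(features$platform)
  features$compound_class <- as.character(features$compound_class)
  features$annotation_level <- as.integer(features$annotation_level)
  features$is_internal_standard <- as.logical(features$is_internal_standard)

  obj <- structure(
    list(intensities = intensities, samples = samples, features = features),
    class = "feature_table"
  )
  validate_feature_table(obj)
  rownames(obj$intensities) <- features$feature_id
  colnames(obj$intensities) <- samples$sample_id
  obj
}

validate_feature_table <- function(x) {
  ints <- x$intensities
  if (nrow(ints) != nrow(x$features))
    stopf("intensity matrix has %d rows but feature metadata has %d records",
          nrow(ints), nrow(x$features))
  if (ncol(ints) != nrow(x$samples))
    stopf("intensity matrix has %d columns but sample metadata has %d records",
          ncol(ints), nrow(x$samples))

  dup <- x$samples$sample_id[duplicated(x$samples$sample_id)]
  if (length(dup)) stopf("duplicate sample id(s): %s",
                         paste(unique(dup), collapse = ", "))
  dup <- x$features$feature_id[duplicated(x$features$feature_id)]
  if (length(dup)) stopf("duplicate feature id(s): %s",
                         paste(unique(dup), collapse = ", "))

  bad <- which(!is.na(ints) & (!is.finite(ints) | ints < 0), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("invalid intensity (negative or non-finite) at feature '%s', sample '%s'",
          x$features$feature_id[bad[1, 1]], x$samples$sample_id[bad[1, 2]])
  }

  if (!all(x$samples$sample_type %in% c("study", "pool")))
    stopf("sample_type must be 'study' or 'pool'")
  is_study <- x$samples$sample_type == "study"
  bad <- is_study & (is.na(x$samples$participant_id) |
                       x$samples$participant_id == "" |
                       is.na(x$samples$drill_area))
  if (any(bad))
    stopf("study sample(s) without participant_id/drill_area: %s",
          paste(x$samples$sample_id[bad], collapse = ", "))
  bad <- !is_study & (!is.na(x$samples$participant_id) &
                        x$samples$participant_id != "" |
                        !is.na(x$samples$drill_area))
  if (any(bad))
    stopf("pool sample(s) carrying participant_id/drill_area: %s",
          paste(x$samples$sample_id[bad], collapse = ", "))
  if (!all(is.na(x$samples$drill_area) |
             (x$samples$drill_area >= 1)))
    stopf("drill_area must be a positive integer")

  if (!all(x$features$annotation_level %in% 1:4))
    stopf("annotation_level must be in 1..4")
  if (!all(x$features$platform %in% c("polar", "lipid")))
    stopf("platform must be 'polar' or 'lipid'")
  bad <- x$features$is_internal_standard & x$features$annotation_level != 1L
  if (any(bad))
    stopf("internal standard(s) not at annotation level 1: %s",
          paste(x$features$feature_id[bad], collapse = ", "))
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  n_pool <- sum(x$samples$sample_type == "pool")
  cat(sprintf(
    "feature_table: %d features x %d samples (%d study, %d pool)\n",
    nrow(x$intensities), ncol(x$intensities),
    ncol(x$intensities) - n_pool, n_pool))
  cat(sprintf("  platforms: %s\n",
              paste(sprintf("%s=%d", names(table(x$features$platform)),
                            table(x$features$platform)), collapse = ", ")))
  cat(sprintf("  internal standards: %d; missing cells: %d (%.1f%%)\n",
              sum(x$features$is_internal_standard),
              sum(is.na(x$intensities)),
              100 * mean(is.na(x$intensities))))
  sc <- stage_counts(x)
  if (!is.null(sc) && nrow(sc))
    cat(sprintf("  stages: %s\n",
                paste(sprintf("%s(%d->%d)", sc$stage, sc$n_in, sc$n_out),
                      collapse = " ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# ---- stage-count bookkeeping (run report) ----------------------------------

#' Stage counts of a feature table
#'
#' Filtering stages record how many features entered and survived each step;
#' the resulting table is part of the run report and reconciles as
#' `n_out[k] == n_in[k + 1]`.
#'
#' @param x A `feature_table`.
#' @return A `data.frame` with columns `stage`, `n_in`, `n_out` (or an empty
#'   one if no stage has run).
#' @export
stage_counts <- function(x) {
  sc <- attr(x, "stage_counts")
  if (is.null(sc))
    sc <- data.frame(stage = character(), n_in = integer(),
                     n_out = integer(), stringsAsFactors = FALSE)
  sc
}

record_stage <- function(x, stage, n_in, n_out) {
  sc <- stage_counts(x)
  sc <- rbind(sc, data.frame(stage = stage, n_in = as.integer(n_in),
                             n_out = as.integer(n_out),
                             stringsAsFactors = FALSE))
  attr(x, "stage_counts") <- sc
  x
}

# Subset features by logical/index vector, preserving stage history.
subset_features <- function(x, keep, stage = NULL) {
  n_in <- nrow(x$intensities)
  out <- x
  out$intensities <- x$intensities[keep, , drop = FALSE]
  out$features <- x$features[keep, , drop = FALSE]
  rownames(out$features) <- NULL
  if (!is.null(stage))
    out <- record_stage(out, stage, n_in, nrow(out$intensities))
  out
}

# ---- TSV input/output ------------------------------------------------------

read_tsv_raw <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    na.strings = c("", "NA", "NaN"),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read a peak table with its metadata
#'
#' Ingests the three-file exchange format: a wide peak table
#' (`feature_id` column then one column per sample), a sample metadata TSV
#' and a feature metadata TSV. Missing intensities may be encoded as empty
#' cells, `NA`, or `NaN`.
#'
#' @param peak_path Path to the peak-table TSV.
#' @param sample_meta_path Path to the sample-metadata TSV.
#' @param feature_meta_path Path to the feature-metadata TSV.
#' @return A validated [feature_table()]; intensity columns are ordered as
#'   in the sample metadata.
#' @export
read_feature_table <- function(peak_path, sample_meta_path, feature_meta_path) {
  for (p in c(peak_path, sample_meta_path, feature_meta_path))
    if (!file.exists(p)) stopf("input file not found: %s", p)

  peak <- read_tsv_raw(peak_path)
  samples <- utils::read.delim(sample_meta_path, sep = "\t", header = TRUE,
                               na.strings = c("", "NA", "NaN"),
                               stringsAsFactors = FALSE)
  features <- utils::read.delim(feature_meta_path, sep = "\t", header = TRUE,
                                na.strings = c("", "NA", "NaN"),
                                stringsAsFactors = FALSE)

  samples$sample_id <- as.character(samples$sample_id)
  features$feature_id <- as.character(features$feature_id)
  if (names(peak)[1] != "feature_id")
    stopf("peak table must start with a 'feature_id' column, found '%s'",
          names(peak)[1])
  fid <- peak$feature_id
  peak_samples <- names(peak)[-1]

  only_peak <- setdiff(peak_samples, samples$sample_id)
  only_meta <- setdiff(samples$sample_id, peak_samples)
  if (length(only_peak) || length(only_meta))
    stopf(paste0("peak table and sample metadata disagree: ",
                 "in peak table only [%s]; in metadata only [%s]"),
          paste(only_peak, collapse = ", "),
          paste(only_meta, collapse = ", "))
  only_peak <- setdiff(fid, features$feature_id)
  only_meta <- setdiff(features$feature_id, fid)
  if (length(only_peak) || length(only_meta))
    stopf(paste0("peak table and feature metadata disagree: ",
                 "in peak table only [%s]; in metadata only [%s]"),
          paste(only_peak, collapse = ", "),
          paste(only_meta, collapse = ", "))

  # align metadata order to its own files; matrix columns follow sample meta
  m <- matrix(NA_real_, nrow = length(fid), ncol = nrow(samples))
  for (j in seq_len(nrow(samples))) {
    m[, j] <- suppressWarnings(as.numeric(peak[[samples$sample_id[j]]]))
  }
  m <- m[match(features$feature_id, fid), , drop = FALSE]
  feature_table(m, samples, features)
}

#' Write a feature table to a directory
#'
#' Serializes the three-file exchange format with full numeric precision so
#' that [read_feature_table()] reproduces the object exactly, including the
#' position of every missing value (written as `NA`).
#'
#' @param table A `feature_table`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector with the three file paths
#'   (`peak`, `samples`, `features`).
#' @export
write_feature_table <- function(table, out_dir) {
  validate_feature_table(table)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)

  paths <- c(peak = file.path(out_dir, "peak_table.tsv"),
             samples = file.path(out_dir, "sample_metadata.tsv"),
             features = file.path(out_dir, "feature_metadata.tsv"))

  con <- file(paths[["peak"]], open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("feature_id", table$samples$sample_id), collapse = "\t"),
             con, sep = "\n")
  if (nrow(table$intensities)) {
    body <- apply(table$intensities, 1, function(r)
      paste(format_full(r), collapse = "\t"))
    writeLines(paste(table$features$feature_id, body, sep = "\t"), con,
               sep = "\n")
  }
  close(con)
  on.exit(NULL)

  write_meta <- function(df, path) {
    df_chr <- df
    for (nm in names(df_chr)) {
      v <- df_chr[[nm]]
      v <- if (is.numeric(v)) format_full(v) else as.character(v)
      v[is.na(df_chr[[nm]])] <- "NA"
      df_chr[[nm]] <- v
    }
    lines <- c(paste(names(df_chr), collapse = "\t"),
               do.call(paste, c(unname(df_chr), sep = "\t")))
    if (nrow(df_chr) == 0) lines <- lines[1]
    con2 <- file(path, open = "wb")
    writeLines(lines, con2, sep = "\n")
    close(con2)
  }
  write_meta(table$samples, paths[["samples"]])
  write_meta(table$features, paths[["features"]])
  invisible(paths)
}

#' Merge the polar and lipid platforms into one table
#'
#' Row-binds two feature tables measured on the same samples. Sample order
#' is taken from the first (polar) table; colliding feature identifiers are
#' disambiguated by prefixing each with its platform.
#'
#' @param polar,lipid `feature_table` objects over identical sample sets.
#' @return A `feature_table` with the concatenated features.
#' @export
merge_platforms <- function(polar, lipid) {
  validate_feature_table(polar)
  validate_feature_table(lipid)
  only_p <- setdiff(polar$samples$sample_id, lipid$samples$sample_id)
  only_l <- setdiff(lipid$samples$sample_id, polar$samples$sample_id)
  if (length(only_p) || length(only_l))
    stopf("sample sets differ: only in first table [%s]; only in second [%s]",
          paste(only_p, collapse = ", "), paste(only_l, collapse = ", "))

  ord <- match(polar$samples$sample_id, lipid$samples$sample_id)
  lipid_m <- lipid$intensities[, ord, drop = FALSE]

  # collisions disambiguated by each argument's platform role, which keeps
  # even a self-merge disjoint
  collide <- intersect(polar$features$feature_id, lipid$features$feature_id)
  f1 <- polar$features
  f2 <- lipid$features
  if (length(collide)) {
    hit <- f1$feature_id %in% collide
    f1$feature_id[hit] <- paste("polar", f1$feature_id[hit], sep = "_")
    hit <- f2$feature_id %in% collide
    f2$feature_id[hit] <- paste("lipid", f2$feature_id[hit], sep = "_")
  }
  feature_table(rbind(polar$intensities, lipid_m),
                polar$samples, rbind(f1, f2))
}
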