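test_that("a hand-written table round-trips through TSV exactly", {
  m <- matrix(c(1.5, NA, 3.25, 0, 1 / 3, 7e-12), nrow = 3,
              dimnames = NULL)
  tab <- toy_table(m, n_pools = 0, participants = rep("P01", 2),
                   areas = 1:2)
  dir <- withr::local_tempdir()
  paths <- write_feature_table(tab, dir)
  back <- read_feature_table(paths[["peak"]], paths[["samples"]],
                             paths[["features"]])
  expect_identical(back$intensities, tab$intensities)
  expect_identical(back$samples, tab$samples)
  expect_identical(back$features, tab$features)

  # NA cell is written as the literal string, not zero
  peak_lines <- readLines(paths[["peak"]])
  expect_match(peak_lines[3], "\tNA\t")
})

test_that("round-trip identity holds on simulated data with missing values", {
  sim <- simulate_study(simulation_config(n_polar = 8, n_lipid = 5,
                                          n_unknowns = 4, network_size = 6,
                                          seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_feature_table(sim$table, dir)
  back <- read_feature_table(paths[["peak"]], paths[["samples"]],
                             paths[["features"]])
  expect_identical(back$intensities, sim$table$intensities)
  expect_identical(which(is.na(back$intensities)),
                   which(is.na(sim$table$intensities)))
})

test_that("construction and reading reject malformed inputs by name", {
  m <- matrix(1:4, 2)
  expect_error(toy_table(matrix(c(1, -2, 3, 4), 2), areas = 1:2,
                         participants = rep("P01", 2)),
               "negative|invalid intensity")
  samples <- data.frame(sample_id = c("S1", "S1"),
                        participant_id = c("P1", "P1"),
                        drill_area = c(1L, 2L), sample_type = "study")
  features <- data.frame(feature_id = c("F1", "F2"), name = c("a", "b"),
                         platform = "polar", compound_class = "x",
                         annotation_level = 2L, is_internal_standard = FALSE)
  expect_error(feature_table(m, samples, features), "duplicate sample.*S1")

  # sample present in the peak table but absent from metadata
  dir <- withr::local_tempdir()
  tab <- toy_table(matrix(1:6, 2), participants = rep("P01", 3), areas = 1:3)
  paths <- write_feature_table(tab, dir)
  peak <- readLines(paths[["peak"]])
  peak[1] <- sub("S03", "S09", peak[1])
  writeLines(peak, paths[["peak"]])
  expect_error(read_feature_table(paths[["peak"]], paths[["samples"]],
                                  paths[["features"]]), "S09")
})

test_that("pool/study metadata invariants are enforced", {
  m <- matrix(1:4, 2)
  expect_error(
    feature_table(m,
                  data.frame(sample_id = c("S1", "S2"),
                             participant_id = c("P1", NA),
                             drill_area = c(1L, NA),
                             sample_type = c("study", "study")),
                  data.frame(feature_id = c("F1", "F2"), name = "n",
                             platform = "polar", compound_class = "x",
                             annotation_level = 2L,
                             is_internal_standard = FALSE)),
    "without participant_id")
  expect_error(
    feature_table(m,
                  data.frame(sample_id = c("S1", "S2"),
                             participant_id = c("P1", "P1"),
                             drill_area = c(1L, 2L),
                             sample_type = c("study", "pool")),
                  data.frame(feature_id = c("F1", "F2"), name = "n",
                             platform = "polar", compound_class = "x",
                             annotation_level = 2L,
                             is_internal_standard = FALSE)),
    "pool sample")
})

test_that("merge_platforms concatenates features and preserves samples", {
  sim <- simulate_study(simulation_config(n_polar = 6, n_lipid = 4,
                                          n_unknowns = 0, lod_quantile = 0,
                                          network_size = 5, seed = 5))
  tab <- sim$table
  polar <- subset_features_for_test(tab, tab$features$platform == "polar")
  lipid <- subset_features_for_test(tab, tab$features$platform == "lipid")
  merged <- merge_platforms(polar, lipid)
  expect_equal(nrow(merged$intensities),
               nrow(polar$intensities) + nrow(lipid$intensities))
  expect_identical(merged$samples$sample_id, polar$samples$sample_id)
  expect_identical(merged$intensities[polar$features$feature_id, ],
                   polar$intensities)
  expect_identical(merged$intensities[lipid$features$feature_id, ],
                   lipid$intensities)

  # self-merge: ids disambiguated by prefixing, feature count doubles
  doubled <- merge_platforms(polar, polar)
  expect_equal(nrow(doubled$intensities), 2 * nrow(polar$intensities))
  expect_true(anyDuplicated(doubled$features$feature_id) == 0)

  # missing sample detected by name
  short <- lipid
  keep <- short$samples$sample_id != "P03_A2"
  short$samples <- short$samples[keep, ]
  short$intensities <- short$intensities[, keep]
  expect_error(merge_platforms(polar, short), "P03_A2")
})
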