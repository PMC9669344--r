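small_cfg <- function(...) {
  phantom_config(grid_shape = c(44, 44, 36), voxel_spacing = c(3, 3, 3), ...)
}

test_that("the atlas hosts exactly 16 labelled regions partitioning the brain", {
  atl <- make_atlas(phantom_config())
  labs <- setdiff(sort(unique(as.vector(atl))), 0L)
  expect_equal(labs, 1:16)
  counts <- tabulate(atl[atl > 0], 16)
  expect_true(all(counts > 0))
})

test_that("a grid too small for 16 regions errors naming the empty region", {
  cfg <- phantom_config()
  cfg$grid_shape <- c(2L, 2L, 2L)
  expect_error(make_atlas(cfg), "region")
})

test_that("region split honours the supra/infra configuration", {
  expect_error(phantom_config(n_regions_supra = 10, n_regions_infra = 4),
               "16")
  atl <- make_atlas(phantom_config())
  # infratentorial labels live strictly below supratentorial ones
  z_supra <- which(array(atl %in% 1:12, dim(atl)), arr.ind = TRUE)[, 3]
  z_infra <- which(array(atl %in% 13:16, dim(atl)), arr.ind = TRUE)[, 3]
  expect_lt(max(z_infra), min(z_supra) + diff(range(z_supra)))
  expect_lt(mean(z_infra), mean(z_supra))
})

test_that("same (config, class, seed) regenerates a subject bit for bit", {
  cfg <- small_cfg()
  s1 <- simulate_subject(cfg, "AE", seed = 11, subject_id = "A")
  s2 <- simulate_subject(cfg, "AE", seed = 11, subject_id = "A")
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  s3 <- simulate_subject(cfg, "AE", seed = 12)
  expect_false(identical(s1$mask, s3$mask))
})

test_that("a degenerate single-count class yields exactly one lesion", {
  cfg <- small_cfg()
  cfg$classes$AS$count_lambda <- 0
  for (sd in 1:5) {
    s <- simulate_subject(cfg, "AS", seed = sd)
    lab <- label_components(s$mask, s$spacing)
    expect_equal(nrow(lab$sizes), 1)
  }
})

test_that("empirical mean lesion count matches the configured distribution", {
  cfg <- small_cfg()
  n <- 120
  counts <- vapply(seq_len(n), function(sd) {
    s <- simulate_subject(cfg, "AE", seed = 1000 + sd)
    nrow(label_components(s$mask, s$spacing)$sizes)
  }, numeric(1))
  lambda <- cfg$classes$AE$count_lambda
  # merged/filtered lesions can only lower the observed count
  expect_lte(mean(counts), 1 + lambda + 3 * sd(counts) / sqrt(n))
  expect_gte(mean(counts), 1 + 0.5 * lambda - 3 * sd(counts) / sqrt(n))
})

test_that("every subject carries a lesion component of at least 8 mm^3", {
  cfg <- small_cfg()
  for (sd in 1:8) {
    for (cl in c("AE", "AS")) {
      s <- simulate_subject(cfg, cl, seed = 300 + sd)
      lab <- label_components(s$mask, s$spacing, min_volume = 8)
      expect_gte(nrow(lab$sizes), 1)
      expect_true(all(s$atlas[s$mask] > 0))
      expect_true(all(is.finite(s$image)))
    }
  }
})

test_that("cohorts have the requested size, seeded scanners and determinism", {
  cfg <- small_cfg()
  co <- simulate_cohort(cfg, n_AE = 3, n_AS = 2, seed = 9)
  expect_equal(nrow(co$truth), 5)
  expect_equal(sum(co$truth$class == "AE"), 3)
  co2 <- simulate_cohort(cfg, n_AE = 3, n_AS = 2, seed = 9)
  expect_identical(co$truth, co2$truth)
  expect_identical(co$subjects[[4]]$image, co2$subjects[[4]]$image)
  co0 <- simulate_cohort(cfg, 0, 0, seed = 1)
  expect_equal(nrow(co0$truth), 0)
  expect_length(co0$subjects, 0)
})

test_that("phantom cohorts round-trip through NIfTI on disk", {
  cfg <- small_cfg()
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cfg, 1, 1, seed = 4, dir = dir)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "S001_image.nii.gz")))
  back <- read_phantom_cohort(dir)
  expect_equal(back$truth$class, co$truth$class)
  expect_equal(back$subjects[[1]]$mask, co$subjects[[1]]$mask)
  expect_equal(back$subjects[[1]]$image, co$subjects[[1]]$image,
               tolerance = 1e-6)
  expect_equal(back$subjects[[1]]$spacing, co$subjects[[1]]$spacing)
})

test_that("class separation is controllable: identical params give chance-level AUC, defaults separate", {
  # null generator: both classes share the AE-like parameter set
  null_cfg <- small_cfg()
  null_cfg$classes$AS <- null_cfg$classes$AE
  null_auc <- vapply(1:20, function(i) {
    co <- simulate_cohort(null_cfg, 8, 8, seed = 5000 + i,
                          scanner_mix = c(A = 1))
    score <- vapply(co$subjects, function(s) {
      sum(label_components(s$mask, s$spacing)$sizes$volume)
    }, numeric(1))
    auc(score, co$truth$class)
  }, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.1)
  expect_true(all(abs(null_auc - 0.5) < 0.45))  # never saturates

  # default (strongly separated) generator: the spatial channel separates
  sep_auc <- vapply(1:5, function(i) {
    co <- simulate_cohort(small_cfg(), 12, 12, seed = 6000 + i,
                          scanner_mix = c(A = 1))
    spa <- suppressMessages(extract_spatial(co$subjects))
    sdi <- suppressWarnings(fit_spatial_model(spa, co$truth$class, k = 4,
                                              seed = i))
    auc(score_ril(spa, sdi), co$truth$class)
  }, numeric(1))
  expect_gt(mean(sep_auc), 0.9)
})
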