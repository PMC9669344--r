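test_that("the catalog enforces the 29/20/30/272 family split of 351", {
  cat <- feature_catalog()
  counts <- table(cat$family)
  expect_equal(unname(counts[["morphology"]]), 29)
  expect_equal(unname(counts[["statistics"]]), 20)
  expect_equal(unname(counts[["histogram"]]), 30)
  expect_equal(unname(counts[["texture"]]), 272)
  expect_equal(nrow(cat), 351)
  expect_equal(anyDuplicated(cat$feature), 0)
  # texture grid: subfamily x aggregation block sizes
  tex <- cat[cat$family == "texture", ]
  expect_equal(as.vector(table(tex$subfamily)[c("glcm", "glrlm", "glszm",
                                                "gldzm", "ngtdm", "ngldm")]),
               c(100, 64, 32, 32, 10, 34))
})

test_that("extraction returns the full catalog, in order, finite", {
  les <- random_lesion(seed = 42)
  fv <- extract_features(les)
  expect_length(fv, 351)
  expect_identical(names(fv), feature_catalog()$feature)
  expect_true(all(is.finite(fv)))
})

test_that("bit-identical lesions give identical vectors", {
  l1 <- random_lesion(seed = 7)
  l2 <- lesion_image(l1$image + 0, l1$mask & TRUE, l1$spacing)
  expect_identical(extract_features(l1), extract_features(l2))
})

test_that("features are invariant to translating the lesion inside the grid", {
  set.seed(8)
  dims <- c(26, 25, 24)
  base_img <- array(rnorm(prod(dims), 40, 5), dims)
  msk <- array(FALSE, dims)
  msk[9:14, 9:14, 9:13] <- random_lesion(dims = c(6, 6, 5), seed = 8)$mask
  l1 <- lesion_image(base_img, msk, c(1, 1, 1))
  # shift image content and mask together by (2, 1, 1); the lesion plus its
  # 1 cm peak neighbourhood stays interior in both positions
  sh <- function(a, fill) radspat:::shift3(a, c(-2, -1, -1), fill = fill)
  l2 <- lesion_image(sh(base_img, 0), sh(msk, FALSE) & TRUE, c(1, 1, 1))
  f1 <- extract_features(l1)
  f2 <- extract_features(l2)
  # hull-family features see a position-dependent jitter; all else exact
  jittered <- grepl("mvee|chull|ombb|diam3d", names(f1))
  expect_equal(f1[jittered], f2[jittered], tolerance = 1e-2)
  expect_equal(f1[!jittered], f2[!jittered], tolerance = 1e-8)
})

test_that("axis-mirroring leaves reflection-invariant features unchanged", {
  l1 <- random_lesion(dims = c(6, 5, 4), seed = 9)
  l2 <- lesion_image(l1$image[6:1, , ], l1$mask[6:1, , ], l1$spacing)
  f1 <- extract_features(l1)
  f2 <- extract_features(l2)
  # the surface mesh triangulation and the hull jitter are orientation-
  # dependent at the percent level; everything else must match exactly:
  # voxel volume, the whole histogram and statistics sets, and all textures
  approx_only <- grepl(
    "mvee|chull|ombb|diam3d|vol_mesh|sphericity|compact|sph_dispr|aspher|av_ratio|vdens|adens|area_surf|moran|geary",
    names(f1))
  expect_equal(f1[approx_only], f2[approx_only], tolerance = 0.05)
  expect_equal(f1[!approx_only], f2[!approx_only], tolerance = 1e-8)
})

test_that("cohort extraction yields one row per lesion with ids", {
  cfg <- phantom_config(grid_shape = c(40, 40, 32), voxel_spacing = c(3, 3, 3))
  s <- simulate_subject(cfg, "AE", seed = 5, subject_id = "X1")
  tbl <- extract_radiomics(list(s), families = c("statistics", "histogram"))
  expect_true(all(c("subject_id", "lesion_id", "stat_mean", "ih_entropy")
                  %in% names(tbl)))
  expect_equal(ncol(tbl), 2 + 50)
  expect_true(all(tbl$subject_id == "X1"))
})
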