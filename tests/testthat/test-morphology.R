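test_that("voxel-counting volume and integrated intensity are exact on a cube", {
  img <- array(4, c(5, 5, 5))
  msk <- array(FALSE, c(5, 5, 5))
  msk[2:4, 2:4, 2:4] <- TRUE
  mf <- morphology_features(lesion_image(img, msk, c(1, 1, 1)))
  expect_equal(unname(mf["morph_vol_voxel"]), 27)
  expect_equal(unname(mf["morph_integrated_intensity"]), 4 * 27)
})

test_that("sphericity of a radius-20 digital ball approaches 1", {
  n <- 45
  g <- expand.grid(1:n, 1:n, 1:n)
  msk <- array(sqrt((g[, 1] - 23)^2 + (g[, 2] - 23)^2 + (g[, 3] - 23)^2) <= 20,
               c(n, n, n))
  mf <- morphology_features(lesion_image(array(1, dim(msk)), msk, c(1, 1, 1)))
  expect_gt(unname(mf["morph_sphericity"]), 0.95)
  expect_lte(unname(mf["morph_sphericity"]), 1.0)
  # mesh volume close to the analytic ball volume
  expect_equal(unname(mf["morph_vol_mesh"]), 4 / 3 * pi * 20^3, tolerance = 0.02)
  # max 3D diameter about one voxel above 2r (corner-based point cloud)
  expect_equal(unname(mf["morph_diam3d"]), 41, tolerance = 0.05)
})

test_that("doubling the voxel spacing scales voxel-counting volume by 8", {
  set.seed(21)
  les1 <- random_lesion(spacing = c(1, 1, 1), seed = 5)
  les2 <- lesion_image(les1$image, les1$mask, c(2, 2, 2))
  m1 <- morphology_features(les1)
  m2 <- morphology_features(les2)
  expect_equal(unname(m2["morph_vol_voxel"]) / unname(m1["morph_vol_voxel"]), 8)
})

test_that("density features are at most 1 and axes are ordered", {
  for (rep in 1:5) {
    mf <- morphology_features(random_lesion(seed = rep + 30))
    for (nm in c("morph_vdens_aabb", "morph_vdens_ombb", "morph_vdens_chull"))
      expect_lte(unname(mf[nm]), 1 + 1e-6)
    expect_true(mf["morph_axis_major"] >= mf["morph_axis_minor"])
    expect_true(mf["morph_axis_minor"] >= mf["morph_axis_least"])
    expect_true(mf["morph_elongation"] >= mf["morph_flatness"])
    expect_true(all(is.finite(mf)))
  }
})

test_that("single-voxel masks stay finite under documented conventions", {
  les <- lesion_image(array(2, c(3, 3, 3)),
                      array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)), c(3, 3, 3)),
                      c(1, 1, 1))
  mf <- morphology_features(les)
  expect_true(all(is.finite(mf)))
  expect_equal(unname(mf["morph_vol_voxel"]), 1)
  expect_equal(unname(mf["morph_elongation"]), 1)
})

test_that("centre-of-mass shift responds to an intensity gradient", {
  msk <- array(TRUE, c(9, 3, 3))
  img0 <- array(5, c(9, 3, 3))
  img1 <- array(rep(1:9, 9), c(9, 3, 3))   # ramp along x
  m0 <- morphology_features(lesion_image(img0, msk))
  m1 <- morphology_features(lesion_image(img1, msk))
  expect_equal(unname(m0["morph_com_shift"]), 0, tolerance = 1e-12)
  expect_gt(unname(m1["morph_com_shift"]), 0.5)
})

test_that("Moran's I is high for smooth fields and near zero for noise", {
  set.seed(77)
  msk <- array(TRUE, c(6, 6, 6))
  ramp <- array(rep(1:6, each = 1, times = 36), c(6, 6, 6))
  noise <- array(rnorm(216), c(6, 6, 6))
  mi_ramp <- morphology_features(lesion_image(ramp, msk))["morph_moran_i"]
  mi_noise <- morphology_features(lesion_image(noise, msk))["morph_moran_i"]
  expect_gt(unname(mi_ramp), 0.2)
  expect_lt(abs(unname(mi_noise)), 0.15)
})
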