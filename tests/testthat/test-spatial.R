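test_that("probabilistic masks binarize at the 0.5 boundary inclusively", {
  expect_true(all(binarize_mask(array(0.6, c(2, 2, 2)))))
  expect_false(any(binarize_mask(array(0.4, c(2, 2, 2)))))
  expect_true(all(binarize_mask(array(0.5, c(2, 2, 2)))))
  expect_error(binarize_mask(array(1.2, c(2, 2, 2))), "\\[0, 1\\]")
})

test_that("component labelling sizes, the 8 mm^3 floor, and 26-connectivity", {
  m <- array(FALSE, c(10, 10, 5))
  m[2:4, 2:4, 2:4] <- TRUE
  m[7:9, 7:9, 2:4] <- TRUE
  lc <- label_components(m, c(1, 1, 1))
  expect_equal(nrow(lc$sizes), 2)
  expect_equal(lc$sizes$volume, c(27, 27))

  single <- array(FALSE, c(5, 5, 5))
  single[3, 3, 3] <- TRUE
  expect_message(lc1 <- label_components(single, c(1, 1, 1)), "discarding")
  expect_equal(nrow(lc1$sizes), 0)

  diag2 <- array(FALSE, c(4, 4, 4))
  diag2[2, 2, 2] <- TRUE
  diag2[3, 3, 3] <- TRUE
  lcd <- label_components(diag2, c(3, 3, 3))   # diagonal voxels touch (26-conn)
  expect_equal(nrow(lcd$sizes), 1)
  expect_equal(lcd$sizes$n_voxels, 2)
})

test_that("worked spatial vectors: single cube, empty mask, three sizes", {
  atlas <- array(3L, c(10, 10, 10))
  m <- array(FALSE, c(10, 10, 10))
  m[4:6, 4:6, 4:6] <- TRUE
  v <- spatial_vector(m, atlas, c(1, 1, 1))
  expect_length(v, 27)
  expect_equal(unname(v["spat_region_03"]), 27)
  expect_equal(sum(v[sprintf("spat_region_%02d", c(1:2, 4:16))]), 0)
  expect_equal(unname(v["spat_n_lesions"]), 1)
  expect_equal(unname(v[c("spat_size_mean", "spat_size_max", "spat_size_sum")]),
               c(27, 27, 27))
  expect_equal(unname(v["spat_bin_8_80"]), 1)
  expect_equal(sum(v[grepl("spat_bin", names(v))]), 1)

  v0 <- spatial_vector(array(FALSE, c(4, 4, 4)), array(1L, c(4, 4, 4)))
  expect_true(all(v0 == 0))

  # components of 50, 100 and 3000 mm^3 (1 mm voxels, separated blocks)
  big <- array(FALSE, c(40, 40, 10))
  atlas2 <- array(1L, c(40, 40, 10))
  big[1:5, 1:5, 1:2] <- TRUE                    # 50
  big[10:14, 10:14, 1:4] <- TRUE                # 100
  big[20:35, 20:34, 1:8] <- TRUE                # wait: adjust below
  big[20:35, 20:34, 1:8] <- FALSE
  big[20:34, 20:39, 1:10] <- TRUE               # 15*20*10 = 3000
  v3 <- spatial_vector(big, atlas2, c(1, 1, 1))
  expect_equal(unname(v3["spat_n_lesions"]), 3)
  expect_equal(unname(v3["spat_size_max"]), 3000)
  expect_equal(unname(v3["spat_size_sum"]), 3150)
  expect_equal(unname(v3["spat_size_mean"]), 1050)
  expect_equal(unname(v3["spat_bin_8_80"]), 1)
  expect_equal(unname(v3["spat_bin_80_160"]), 1)
  expect_equal(unname(v3["spat_bin_ge_2560"]), 1)
})

test_that("lesion voxels on atlas background warn and skip region counts", {
  atlas <- array(0L, c(6, 6, 6))
  atlas[, , 4:6] <- 2L
  m <- array(FALSE, c(6, 6, 6))
  m[2:4, 2:4, 2:5] <- TRUE   # straddles background and region 2
  expect_warning(v <- spatial_vector(m, atlas, c(1, 1, 1)), "background")
  expect_equal(unname(v["spat_region_02"]), 3 * 3 * 2)
  expect_equal(unname(v["spat_size_sum"]), 3 * 3 * 4)  # totals keep all voxels
})

test_that("bin counts always total the lesion count on random masks", {
  set.seed(41)
  atlas <- array(1L, c(20, 20, 12))
  for (rep in 1:15) {
    m <- array(runif(20 * 20 * 12) < 0.18, c(20, 20, 12))
    v <- suppressMessages(spatial_vector(m, atlas, c(2, 2, 2)))
    expect_equal(sum(v[grepl("spat_bin", names(v))]),
                 unname(v["spat_n_lesions"]))
    expect_lte(sum(v[grepl("spat_region", names(v))]),
               unname(v["spat_size_sum"]) / 8)
  }
})

test_that("spatial vectors are invariant to component relabelling order", {
  atlas <- array(1L, c(12, 12, 6))
  m <- array(FALSE, c(12, 12, 6))
  m[1:3, 1:3, 1:3] <- TRUE
  m[8:11, 8:11, 2:5] <- TRUE
  v1 <- spatial_vector(m, atlas, c(1, 1, 1))
  # mirrored mask: same components, discovered in the other order
  v2 <- spatial_vector(m[12:1, , ], atlas, c(1, 1, 1))
  expect_equal(v1, v2)
})
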