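# Optimized matrix builders against brute-force enumeration oracles.

test_that("GLCM matrices and all 25 features match brute-force enumeration", {
  set.seed(101)
  d3 <- radspat:::directions_3d()
  for (rep in 1:40) {
    ng <- sample(2:4, 1)
    dims <- sample(2:5, 3, replace = TRUE)
    lv <- random_level_grid(dims, ng)
    d <- d3[sample(nrow(d3), 1), ]
    m_pkg <- pkg_glcm_matrix(lv, ng, d)
    m_ora <- oracle_glcm_matrix(lv, ng, d)
    expect_equal(m_pkg, m_ora, tolerance = 1e-12)
    if (sum(m_ora) > 0) {
      expect_equal(pkg_glcm_features(m_pkg), oracle_glcm_features(m_ora),
                   tolerance = 1e-10)
    }
  }
})

test_that("GLRLM run counts match a walk-the-line oracle", {
  set.seed(102)
  d3 <- radspat:::directions_3d()
  for (rep in 1:30) {
    ng <- sample(2:4, 1)
    dims <- sample(2:5, 3, replace = TRUE)
    lv <- random_level_grid(dims, ng)
    maxlen <- max(dims)
    d <- d3[sample(nrow(d3), 1), ]
    expect_equal(pkg_rlm_counts(lv, ng, d, maxlen),
                 oracle_rlm_matrix(lv, ng, d, maxlen),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("GLSZM zone counts match a flood-fill oracle in 3D and 2D", {
  set.seed(103)
  for (rep in 1:30) {
    ng <- sample(2:3, 1)
    dims <- sample(2:5, 3, replace = TRUE)
    lv <- random_level_grid(dims, ng)
    for (dim3d in c(TRUE, FALSE)) {
      m_pkg <- pkg_szm_matrix(lv, ng, dim3d)
      m_ora <- oracle_szm_matrix(lv, ng, dim3d)
      expect_equal(m_pkg, m_ora, ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("constant image: GLCM joint maximum 1 and joint entropy 0", {
  les <- lesion_image(array(5, c(4, 4, 3)), array(TRUE, c(4, 4, 3)))
  tf <- texture_features(les)
  for (agg in c("2d_avg", "2d_mrg", "3d_avg", "3d_mrg")) {
    expect_equal(unname(tf[paste0("glcm_joint_max_", agg)]), 1)
    expect_equal(unname(tf[paste0("glcm_joint_entropy_", agg)]), 0)
  }
})

test_that("a single constant row is one run: RLNU normalized 1", {
  n <- 7
  les <- lesion_image(array(2, c(n, 1, 1)), array(TRUE, c(n, 1, 1)))
  lv <- discretize(les)
  m <- pkg_rlm_counts(lv, 1L, c(1, 0, 0), n)
  expect_equal(sum(m), 1)            # a single run
  expect_equal(m[1, n], 1)           # of length n
  f <- radspat:::sizezone_features(m, seq_len(n), n)
  expect_equal(f[12], 1)             # run-length non-uniformity, normalized
})

test_that("zone distance maps give the city-block distance to outside", {
  m <- array(TRUE, c(5, 5, 5))
  d <- radspat:::roi_distance_map(m, dim3d = TRUE)
  expect_equal(d[1, 1, 1], 1)
  expect_equal(d[3, 3, 3], 3)
  m2 <- array(TRUE, c(3, 3, 1))
  d2 <- radspat:::roi_distance_map(m2, dim3d = FALSE)
  expect_equal(d2[2, 2, 1], 2)       # in-plane distance ignores the thin axis
})

test_that("texture block always returns 272 finite values in catalog order", {
  set.seed(104)
  for (rep in 1:5) {
    les <- random_lesion(seed = rep + 50)
    tf <- texture_features(les)
    expect_length(tf, 272)
    expect_true(all(is.finite(tf)))
  }
  cat_tex <- feature_catalog()
  cat_tex <- cat_tex$feature[cat_tex$family == "texture"]
  expect_identical(names(texture_features(random_lesion(seed = 1))), cat_tex)
})

test_that("single-voxel lesions resolve to fallbacks, never NaN", {
  les <- lesion_image(array(3, c(1, 1, 1)), array(TRUE, c(1, 1, 1)))
  tf <- texture_features(les)
  expect_true(all(is.finite(tf)))
  expect_equal(unname(tf["glcm_joint_max_3d_mrg"]), 1)  # degenerate self-pair
})
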