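test_that("analytic shapes match closed-form feature values", {
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L
  f <- gland_features(sq)
  expect_equal(f$area, 100)
  expect_equal(f$extent, 1)
  expect_equal(f$solidity, 1)
  expect_equal(f$filled_area, 100)
  expect_equal(f$convex_area, 100)
  expect_equal(f$box_aspect_ratio, 1)
  expect_lte(f$compactness, 1)

  # rasterized disk, radius 30
  d <- matrix(0L, 80, 80)
  ii <- matrix(1:80, 80, 80); jj <- t(ii)
  d[(ii - 40)^2 + (jj - 40)^2 <= 30^2] <- 1L
  fd <- gland_features(d)
  expect_equal(fd$equivalent_diameter, 60, tolerance = 1 / 60)
  expect_gte(fd$compactness, 0.95)
  expect_lte(fd$eccentricity, 0.1)

  # 60 x 20 axis-aligned rectangle
  r <- matrix(0L, 80, 100); r[11:30, 11:70] <- 1L
  fr <- gland_features(r)
  expect_equal(fr$orientation, 0, tolerance = 0.05)
  expect_equal(fr$box_aspect_ratio, 3)
  expect_equal(fr$eccentricity, sqrt(1 - (20 / 60)^2), tolerance = 0.02)
  expect_equal(fr$major_axis_length, 4 * sqrt(60^2 / 12), tolerance = 0.01)
})

test_that("features agree with an independent pixel-set oracle on random blobs", {
  set.seed(71)
  for (k in 1:50) {
    m <- random_blob_mask()
    got <- as.numeric(gland_features(m)[1, gland_feature_names()])
    want <- as.numeric(oracle_features(m)[gland_feature_names()])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("features are translation-invariant and 90-degree-rotation consistent", {
  set.seed(5)
  m <- random_blob_mask(40, 40)
  big <- matrix(0L, 70, 70); big[10:49, 10:49] <- m
  shifted <- matrix(0L, 70, 70); shifted[25:64, 20:59] <- m
  f1 <- gland_features(big); f2 <- gland_features(shifted)
  expect_equal(as.numeric(f1[1, -1]), as.numeric(f2[1, -1]), tolerance = 1e-12)

  rot <- t(big)[ncol(big):1, ] # 90-degree rotation
  fr <- gland_features(matrix(as.integer(rot), 70, 70))
  expect_equal(fr$area, f1$area)
  expect_equal(fr$perimeter, f1$perimeter, tolerance = 1e-9)
  d_or <- (f1$orientation - fr$orientation) %% pi
  expect_true(min(abs(d_or - pi / 2), abs(d_or - pi / 2 - pi), abs(d_or + pi / 2 - pi)) < 1e-6)
})

test_that("patient aggregation matches hand-computed statistics", {
  f3 <- tibble::tibble(!!!setNames(rep(list(c(1, 2, 3)), 13), gland_feature_names()))
  agg <- aggregate_patient(f3, "P1")
  expect_equal(agg$area_mean, 2)
  expect_equal(agg$area_median, 2)
  expect_equal(agg$area_std, 1)
  expect_equal(agg$area_max, 3)
  expect_equal(agg$area_skewness, 0)
  expect_equal(agg$n_glands, 3L)
  expect_identical(names(agg)[-(1:2)], patient_feature_names())

  f1 <- f3[1, ]
  a1 <- aggregate_patient(f1, "P2")
  expect_equal(a1$area_mean, 1)
  expect_equal(a1$area_std, 0)
  expect_equal(a1$area_kurtosis, 0)

  # permutation invariance
  set.seed(2)
  fm <- tibble::tibble(!!!setNames(lapply(1:13, function(i) runif(7)), gland_feature_names()))
  ap <- aggregate_patient(fm, "P3")
  aq <- aggregate_patient(fm[sample(7), ], "P3")
  expect_equal(ap, aq)

  expect_error(aggregate_patient(fm[0, ], "P4"), "empty")
})

test_that("missing labels are reported by name", {
  m <- matrix(0L, 10, 10); m[2:4, 2:4] <- 1L
  expect_error(gland_features(m, ids = 7), "7")
})
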