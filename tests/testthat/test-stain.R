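test_that("optical density transform is exact and invertible", {
  v <- array(0:255, c(16, 16, 1))
  od <- rgb_to_od(v)
  expect_true(all(od >= 0))
  expect_equal(as.numeric(rgb_to_od(array(255, c(1, 1, 1)))), -log10(256 / 256))
  expect_equal(as.numeric(rgb_to_od(array(0, c(1, 1, 1)))), -log10(1 / 256),
               tolerance = 1e-12)
  expect_true(all(diff(as.numeric(od)[order(0:255)]) <= 0)) # monotone decreasing
  expect_identical(as.numeric(od_to_rgb(od)), as.numeric(v)) # exact round trip
})

test_that("stain estimation recovers a known two-stain mixture", {
  M <- glandsurv:::he_stain_matrix()
  set.seed(2)
  C <- rbind(runif(5000, 0, 1.2), runif(5000, 0, 0.8))
  img <- od_to_rgb(array(t(M %*% C), c(50, 100, 3)))
  est <- estimate_stains(img)
  cos_sim <- diag(crossprod(est$stain_matrix, M))
  expect_true(all(cos_sim > 0.99))
  expect_false(est$low_confidence)
  # H identified as the larger blue-OD column, stored first
  expect_gt(est$stain_matrix["B", "H"], est$stain_matrix["B", "E"])
})

test_that("degenerate stain inputs are flagged or rejected", {
  expect_error(estimate_stains(array(255, c(64, 64, 3))), "[0-9]+")
  # pure single-stain image
  M <- glandsurv:::he_stain_matrix()
  set.seed(3)
  C <- rbind(runif(4000, 0.2, 1.2), rep(0, 4000))
  img <- od_to_rgb(array(t(M %*% C), c(50, 80, 3)))
  est <- estimate_stains(img)
  expect_true(est$low_confidence)
})

test_that("normalization to the image's own profile is an identity up to quantization", {
  s <- simulate_gland_image(96, 96, gland_regime("regular"), n_glands = 4,
                            seed = 3, stain_variation = 0)
  # exact profile of the rendering model
  od <- rgb_to_od(s$image)
  V <- t(matrix(od, ncol = 3))
  H <- glandsurv:::stain_code(V, glandsurv:::he_stain_matrix(), lambda = 0)
  prof <- stain_profile(glandsurv:::he_stain_matrix(),
                        apply(H, 1, quantile, 0.99))
  out <- stain_normalize(s$image, prof, source = prof)
  expect_lte(max(abs(out - s$image)), 2)
})

test_that("raising the target concentration scale darkens the output", {
  s <- simulate_gland_image(96, 96, gland_regime("regular"), n_glands = 4, seed = 5)
  src <- estimate_stains(s$image)
  dark <- stain_profile(src$stain_matrix, src$concentration_scale * 2)
  out1 <- stain_normalize(s$image, src, source = src)
  out2 <- stain_normalize(s$image, dark, source = src)
  expect_gt(mean(rgb_to_od(out2)), mean(rgb_to_od(out1)))
})

test_that("two tintings of the same tissue normalize to nearly the same image", {
  a <- simulate_gland_image(96, 96, gland_regime("regular"), n_glands = 4,
                            seed = 3, stain_variation = 0)
  b <- simulate_gland_image(96, 96, gland_regime("regular"), n_glands = 4,
                            seed = 3, stain_variation = 0.18)
  expect_identical(a$truth, b$truth) # same tissue, different tint
  tgt <- stain_profile(glandsurv:::he_stain_matrix(), c(1, 0.7))
  na <- stain_normalize(a$image, tgt)
  nb <- stain_normalize(b$image, tgt)
  for (ch in 1:3) {
    expect_lt(mean(abs(na[, , ch] - nb[, , ch])), 5)
  }
})

test_that("normalization is idempotent and keeps background white", {
  s <- simulate_gland_image(96, 96, gland_regime("regular"), n_glands = 3,
                            seed = 9, background = "white")
  tgt <- stain_profile(glandsurv:::he_stain_matrix(), c(1, 0.7))
  n1 <- stain_normalize(s$image, tgt)
  n2 <- stain_normalize(n1, tgt)
  expect_lt(abs(mean(rgb_to_od(n2)) - mean(rgb_to_od(n1))) / mean(rgb_to_od(n1)),
            0.01)
  bg <- !s$tissue
  before <- mean(s$image[, , 1][bg] + s$image[, , 2][bg] + s$image[, , 3][bg]) / 3
  after <- mean(n1[, , 1][bg] + n1[, , 2][bg] + n1[, , 3][bg]) / 3
  expect_gte(before, 245)
  expect_gte(after, 245)
})

test_that("stain profiles survive a JSON round trip", {
  p <- stain_profile(glandsurv:::he_stain_matrix(), c(1.3, 0.8))
  path <- tempfile(fileext = ".json")
  write_stain_profile(p, path)
  q <- read_stain_profile(path)
  expect_equal(q$stain_matrix, p$stain_matrix, tolerance = 1e-12)
  expect_equal(q$concentration_scale, p$concentration_scale)
})
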