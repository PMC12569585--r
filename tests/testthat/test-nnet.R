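test_that("model builds are seeded and satisfy the shape contracts", {
  m1 <- build_model("dcan", 0.125, seed = 5)
  m2 <- build_model("dcan", 0.125, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model("dcan", 0.125, seed = 6)
  expect_false(identical(m1$params$enc1$w, m3$params$enc1$w))
  expect_error(build_model("dcan", width_multiplier = 0), "width_multiplier")

  x <- array(runif(96 * 96 * 3, 0, 255), c(96, 96, 3))
  t0 <- Sys.time()
  p <- predict_probs(m1, x)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_s3_class(p, "probability_pair")
  expect_identical(dim(p$object_map), c(96L, 96L))
  expect_true(all(p$object_map >= 0 & p$object_map <= 1))
  expect_lt(elapsed, 1) # desk-scale speed gate (96 x 96 forward pass)
  expect_identical(p, predict_probs(m1, x)) # deterministic inference

  u <- build_model("unet", 0.125, seed = 5)
  pu <- predict_probs(u, x)
  expect_identical(dim(pu), c(96L, 96L))
})

test_that("backpropagation matches finite differences", {
  set.seed(3)
  ns <- asNamespace("glandsurv")
  x <- array(rnorm(16 * 16 * 3, 0, 0.3), c(16, 16, 3))
  obj <- matrix(rbinom(256, 1, 0.4), 16, 16)
  con <- matrix(rbinom(256, 1, 0.2), 16, 16)
  for (kind in c("dcan", "unet")) {
    m <- build_model(kind, 0.125, seed = 5)
    # random heads so every path carries gradient
    for (nm in names(m$params)) {
      m$params[[nm]]$w <- m$params[[nm]]$w +
        matrix(rnorm(length(m$params[[nm]]$w), 0, 0.05),
               nrow(m$params[[nm]]$w))
    }
    loss_of <- function(params) {
      fw <- if (kind == "dcan") ns$forward_dcan(params, x) else ns$forward_unet(params, x)
      l <- ns$softmax_ce_loss(fw$main$object, obj)
      if (kind == "dcan") {
        l <- l + ns$softmax_ce_loss(fw$main$contour, con)
        for (br in c("object", "contour")) for (lv in 2:4) {
          tg <- if (br == "object") obj else con
          l <- l + 0.5 * ns$softmax_ce_loss(fw$s[[sprintf("s%d_%s", lv, br)]], tg)
        }
      }
      l
    }
    fw <- if (kind == "dcan") ns$forward_dcan(m$params, x) else ns$forward_unet(m$params, x)
    if (kind == "dcan") {
      gmo <- ns$softmax_ce_grad(fw$main$object, obj)
      gmc <- ns$softmax_ce_grad(fw$main$contour, con)
      g_levels <- list()
      for (br in c("object", "contour")) for (lv in 2:4) {
        tg <- if (br == "object") obj else con
        g_levels[[sprintf("s%d_%s", lv, br)]] <-
          (if (br == "object") gmo else gmc) +
          0.5 * ns$softmax_ce_grad(fw$s[[sprintf("s%d_%s", lv, br)]], tg)
      }
      grads <- ns$backward_dcan(m$params, fw, g_levels)
    } else {
      grads <- ns$backward_unet(m$params, fw,
                                ns$softmax_ce_grad(fw$main$object, obj))
    }
    for (nm in names(m$params)) {
      for (t in 1:3) {
        i <- sample(length(m$params[[nm]]$w), 1)
        eps <- 1e-5
        p2 <- m$params
        p2[[nm]]$w[i] <- p2[[nm]]$w[i] + eps; lp <- loss_of(p2)
        p2[[nm]]$w[i] <- p2[[nm]]$w[i] - 2 * eps; lm <- loss_of(p2)
        num <- (lp - lm) / (2 * eps)
        expect_equal(grads[[nm]]$w[i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("the deep-supervision loss has its closed-form values", {
  n <- 8
  y <- matrix(rbinom(n * n, 1, 0.5), n, n)
  con <- matrix(rbinom(n * n, 1, 0.3), n, n)
  half <- probability_pair(matrix(0.5, n, n), matrix(0.5, n, n))
  expect_equal(dcan_loss(half, list(), y, con, aux_weight = 0), 2 * log(2),
               tolerance = 1e-9)
  # aux weight 0 ignores auxiliary outputs entirely
  junk <- probability_pair(matrix(0.9, n, n), matrix(0.1, n, n))
  expect_equal(dcan_loss(half, list(junk, junk), y, con, aux_weight = 0),
               2 * log(2), tolerance = 1e-9)
  expect_gt(dcan_loss(half, list(junk), y, con, aux_weight = 1), 2 * log(2))
  # near-perfect predictions drive the loss to zero
  eps <- 1e-6
  perf <- probability_pair(abs(y - eps), abs(con - eps))
  expect_lt(dcan_loss(perf, list(), y, con), 1e-5)
  expect_gte(dcan_loss(perf, list(), y, con), 0)
})

test_that("the auxiliary schedule decays linearly to zero by mid-training", {
  w <- vapply(1:10, aux_linear_decay, numeric(1), epochs = 10)
  expect_equal(w[1], 1)
  expect_true(all(diff(w) <= 0))
  expect_equal(w[6], 0)
})

test_that("augmentation is seeded, frequency-calibrated and geometry-preserving", {
  s <- simulate_gland_image(64, 64, gland_regime("regular"), 3, seed = 2)
  obj <- matrix(as.numeric(s$truth > 0), 64, 64)
  con <- matrix(as.numeric(contour_target(s$truth, 2)), 64, 64)
  cfg <- train_config(patch_size = 64, crop_size = 48)
  a1 <- augment_sample(s$image, obj, con, cfg, seed = 9)
  a2 <- augment_sample(s$image, obj, con, cfg, seed = 9)
  expect_identical(a1, a2)
  expect_identical(dim(a1$object_target), c(48L, 48L))
  expect_error(augment_sample(s$image[1:32, 1:32, ], obj[1:32, 1:32],
                              con[1:32, 1:32], cfg, seed = 1), "crop")

  # isometries conserve foreground mass (no crop)
  cfg_full <- train_config(patch_size = 64, crop_size = 64)
  for (seed in 1:8) {
    a <- augment_sample(s$image, obj, con, cfg_full, seed = seed)
    expect_equal(sum(a$object_target), sum(obj))
    expect_equal(sum(a$image), sum(s$image))
  }

  # empirical frequencies over many seeded draws
  tiny <- matrix(0, 8, 8); timg <- array(0, c(8, 8, 3))
  cfg8 <- train_config(patch_size = 8, crop_size = 8)
  draws <- vapply(1:10000, function(sd) {
    a <- augment_sample(timg, tiny, tiny, cfg8, seed = sd)
    c(attr(a, "rotation"), as.integer(attr(a, "flip")))
  }, numeric(2))
  expect_lt(abs(mean(draws[2, ]) - 0.5), 0.02)
  for (r in c(0, 90, 180, 270)) {
    expect_lt(abs(mean(draws[1, ] == r) - 0.25), 0.02)
  }
})

test_that("contour targets separate touching instances and commute with rotation", {
  truth <- matrix(0L, 40, 40)
  truth[10:30, 8:19] <- 1L
  truth[10:30, 20:32] <- 2L # touching along a vertical line
  ct <- contour_target(truth, thickness = 2)
  leftover <- (truth > 0) & !ct
  expect_gte(max(glandsurv::label_instances(leftover)), 2)
  expect_identical(contour_target(matrix(0L, 10, 10)), matrix(FALSE, 10, 10))

  # 20x20 square, thickness 1: brute-force neighbourhood construction
  sq <- matrix(0L, 30, 30); sq[6:25, 6:25] <- 1L
  ct1 <- contour_target(sq, thickness = 1)
  bnd <- oracle_boundary(sq == 1)
  manual <- matrix(FALSE, 30, 30)
  for (r in seq_len(nrow(bnd))) {
    for (di in -1:1) for (dj in -1:1) {
      if (di^2 + dj^2 <= 1) { # disk of radius 1 = 4-neighbourhood + centre
        manual[bnd[r, 1] + di, bnd[r, 2] + dj] <- TRUE
      }
    }
  }
  expect_identical(ct1, manual)

  rot <- function(m) { r <- t(m); r[rev(seq_len(nrow(r))), ] }
  truth_r <- matrix(as.integer(rot(truth)), 40, 40)
  expect_identical(contour_target(truth_r, 2), rot(contour_target(truth, 2)))
})

test_that("training runs, descends, and checkpoints reproduce forward passes", {
  samples <- desk_image_set(2, 500)
  cfg <- desk_config(epochs = 1, seed = 9)
  m <- train_model(build_model("dcan", 0.125, seed = 9), samples, cfg)
  expect_length(m$history, 1)
  expect_true(is.finite(m$history))
  expect_error(train_model(build_model("dcan", 0.125), list(), cfg), "non-empty")

  path <- tempfile(fileext = ".rds")
  prof <- stain_profile(glandsurv:::he_stain_matrix(), c(1, 0.7))
  save_checkpoint(m, path, stain_target = prof)
  m2 <- load_checkpoint(path)
  x <- samples[[1]]$image
  expect_identical(predict_probs(m2, x), predict_probs(m, x))
  expect_false(is.na(m2$stain_hash))
})

test_that("a single batch can be overfitted to high pixel accuracy", {
  samples <- desk_image_set(2, 600)
  cfg <- desk_config(epochs = 100, seed = 3)
  m <- train_model(build_model("dcan", 0.125, seed = 3), samples, cfg)
  acc <- mean(vapply(samples, function(s) {
    p <- predict_probs(m, s$image)
    mean((p$object_map >= 0.5) == (s$truth > 0))
  }, numeric(1)))
  expect_gt(acc, 0.95)
  # loss is permutation-invariant in pixel order
  y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  pmap <- matrix(runif(64), 8, 8)
  ix <- sample(64)
  l1 <- glandsurv:::bce_prob(as.numeric(pmap), as.numeric(y))
  l2 <- glandsurv:::bce_prob(as.numeric(pmap)[ix], as.numeric(y)[ix])
  expect_equal(l1, l2)
})

test_that("padded inputs reproduce the unpadded forward pass away from the pad", {
  m <- build_model("dcan", 0.125, seed = 21)
  s <- simulate_gland_image(96, 96, gland_regime("regular"), 3, seed = 31)
  x <- glandsurv:::prepare_input(s$image)
  base <- glandsurv:::forward_dcan(m$params, x)$main$object
  pad <- 32L # multiple of the downsampling factor
  xp <- array(0, c(96 + 2 * pad, 96 + 2 * pad, 3))
  xp[pad + 1:96, pad + 1:96, ] <- x
  padded <- glandsurv:::forward_dcan(m$params, xp)$main$object
  inner <- 41:56 # > receptive-field margin from every pad edge
  expect_equal(padded[pad + inner, pad + inner, 2], base[inner, inner, 2],
               tolerance = 1e-12)
})

test_that("patch extraction covers large images with the configured overlap", {
  img <- array(runif(120 * 200 * 3), c(120, 200, 3))
  tr <- matrix(0L, 120, 200)
  p <- extract_patches(img, tr, size = 100, stride = 50)
  expect_equal(length(p), 2 * 3)
  expect_true(all(vapply(p, function(q) all(dim(q$image)[1:2] == 100), logical(1))))
  small <- extract_patches(img[1:80, 1:80, ], tr[1:80, 1:80], size = 100)
  expect_length(small, 1)
})
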