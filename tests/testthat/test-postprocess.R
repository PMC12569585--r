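test_that("fusion combines object and contour maps as specified", {
  n <- 20
  all_on <- probability_pair(matrix(1, n, n), matrix(0, n, n))
  expect_true(all(fuse_probability_maps(all_on)))
  con_on <- probability_pair(matrix(1, n, n), matrix(0.9, n, n))
  expect_false(any(fuse_probability_maps(con_on)))

  # two blobs joined by a thin high-contour ridge separate after fusion
  obj <- matrix(0, 40, 40)
  obj[10:30, 5:18] <- 1; obj[10:30, 22:35] <- 1; obj[18:22, 19:21] <- 1
  con <- matrix(0, 40, 40); con[, 19:21] <- 1
  pair <- probability_pair(obj, con)
  expect_equal(max(label_instances(obj > 0.5)), 1)
  expect_equal(max(label_instances(fuse_probability_maps(pair))), 2)
})

test_that("the 400-pixel minimum area rule is strict", {
  m399 <- matrix(0L, 40, 40); m399[2:20, 2:22] <- 1L  # 19 x 21 = 399
  expect_equal(max(clean_mask(m399, smooth_radius = 0)), 0)
  m400 <- matrix(0L, 40, 40); m400[2:21, 2:21] <- 1L  # 20 x 20 = 400
  expect_equal(max(clean_mask(m400, smooth_radius = 0)), 1)
})

test_that("holes are filled and jagged boundaries smoothed", {
  d <- matrix(0L, 60, 60)
  ii <- matrix(1:60, 60, 60); jj <- t(ii)
  rim <- (ii - 30)^2 + (jj - 30)^2 <= 20^2
  hole <- (ii - 30)^2 + (jj - 30)^2 <= 8^2
  d[rim & !hole] <- 1L
  out <- clean_mask(d, smooth_radius = 0)
  expect_equal(sum(out > 0), sum(rim)) # hole filled -> solid disk area
  out3 <- clean_mask(d)
  expect_equal(sum(out3 > 0), sum(rim), tolerance = 0.01) # smoothing only nibbles the rim

  set.seed(9)
  jag <- matrix(0L, 60, 60); jag[15:45, 15:45] <- 1L
  edge <- which(glandsurv:::boundary_mask(jag == 1), arr.ind = TRUE)
  flip <- edge[sample(nrow(edge), 40), ]
  jag[flip] <- 0L
  p_before <- glandsurv:::crofton_perimeter(jag)
  sm <- clean_mask(jag, min_area = 100, smooth_radius = 3)
  expect_lte(glandsurv:::crofton_perimeter(sm > 0), p_before)
})

test_that("cleanup is idempotent and respects the area floor on random masks", {
  set.seed(31)
  for (k in 1:100) {
    m <- matrix(0L, 64, 64)
    for (b in 1:3) {
      cy <- runif(1, 10, 54); cx <- runif(1, 10, 54); r <- runif(1, 4, 14)
      ii <- matrix(1:64, 64, 64); jj <- t(ii)
      m[(ii - cy)^2 + (jj - cx)^2 <= r^2] <- 1L
    }
    m[sample(64 * 64, 150)] <- 1L # speckle
    c1 <- clean_mask(m, min_area = 80)
    c2 <- clean_mask(c1 > 0, min_area = 80)
    expect_identical(c2, c1)
    if (max(c1) > 0) {
      expect_gte(min(tabulate(c1[c1 > 0])), 80)
    }
    # label count matches an independent flood-fill oracle
    expect_equal(max(c1), max(oracle_label4(c1 > 0)))
  }
})

test_that("labelling is 4-connected and consecutive", {
  m <- matrix(0L, 6, 6)
  m[1, 1] <- 1L; m[2, 2] <- 1L; m[5, 5] <- 1L
  lab <- label_instances(m)
  expect_equal(max(lab), 3) # diagonal pixels are separate components
  expect_setequal(unique(as.integer(lab[lab > 0])), 1:3)
})

test_that("cores regrow into the object mask without crossing instances", {
  obj <- matrix(0, 30, 30)
  obj[5:25, 5:14] <- 1; obj[5:25, 16:25] <- 1; obj[5:25, 15] <- 1
  cores <- matrix(0L, 30, 30)
  cores[10:20, 7:12] <- 1L; cores[10:20, 18:23] <- 2L
  grown <- grow_labels(cores, obj > 0)
  expect_equal(max(grown), 2)
  expect_true(all(grown[obj > 0] > 0))
  # each original core keeps its identity
  expect_true(all(grown[cores == 1L] == 1L))
  expect_true(all(grown[cores == 2L] == 2L))
})
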