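small_spec <- function(...) {
  cohort_spec(glands_mean = 4, glands_dispersion = 6, ...)
}

test_that("cohort simulation is deterministic and validates its spec", {
  a <- simulate_cohort(small_spec(n_patients = 20, seed = 5))
  b <- simulate_cohort(small_spec(n_patients = 20, seed = 5))
  expect_identical(a$patients, b$patients)
  expect_identical(a$survival, b$survival)
  expect_error(cohort_spec(true_beta = c(not_a_feature = 1)), "not_a_feature")
  expect_error(cohort_spec(censoring_rate = 1), "censoring_rate")
})

test_that("zero censoring gives all events; calibration hits the target rate", {
  co0 <- simulate_cohort(small_spec(n_patients = 50, censoring_rate = 0, seed = 2))
  expect_true(all(co0$survival$event == 1L))

  co <- simulate_cohort(small_spec(n_patients = 1000, censoring_rate = 0.3, seed = 8))
  expect_lt(abs(mean(co$survival$event == 0) - 0.3), 0.05)
  expect_true(all(co$survival$time_months > 0))
})

test_that("a null hazard model carries no concordance signal", {
  co <- simulate_cohort(small_spec(n_patients = 500, true_beta = numeric(0),
                                   censoring_rate = 0, seed = 4))
  set.seed(1)
  fake_lp <- rnorm(500)
  ci <- concordance_index(co$survival, fake_lp)
  expect_lt(abs(ci - 0.5), 0.05)
})

test_that("true-linear-predictor concordance matches a Monte-Carlo oracle", {
  spec <- small_spec(n_patients = 500, true_beta = c(eccentricity_mean = 1.5),
                     censoring_rate = 0, seed = 14)
  co <- simulate_cohort(spec)
  ci <- concordance_index(co$survival, co$linear_predictor$lp)
  # oracle: resample LP pairs from the cohort's empirical LP law and draw
  # fresh Weibull death times under the same hazard model
  set.seed(99)
  n_mc <- 1e5
  lp_i <- sample(co$linear_predictor$lp, n_mc, replace = TRUE)
  lp_j <- sample(co$linear_predictor$lp, n_mc, replace = TRUE)
  ti <- spec$baseline_scale * (-log(runif(n_mc)) * exp(-lp_i))^(1 / spec$baseline_shape)
  tj <- spec$baseline_scale * (-log(runif(n_mc)) * exp(-lp_j))^(1 / spec$baseline_shape)
  keep <- lp_i != lp_j
  mc <- mean(((lp_i > lp_j) == (ti < tj))[keep])
  expect_lt(abs(ci - mc), 0.02)
})

test_that("deformed-regime glands are measurably more irregular", {
  co <- simulate_cohort(small_spec(n_patients = 40, seed = 6))
  ecc <- tapply(co$glands$eccentricity, co$glands$regime, mean)
  sol <- tapply(co$glands$solidity, co$glands$regime, mean)
  expect_gt(ecc[["deformed"]], ecc[["regular"]])
  expect_lt(sol[["deformed"]], sol[["regular"]])
})

test_that("cohort tables are written as CSV with the documented layout", {
  co <- simulate_cohort(small_spec(n_patients = 10, seed = 3))
  dir <- tempfile()
  write_cohort_csv(co, dir)
  surv <- read.csv(file.path(dir, "survival.csv"))
  expect_identical(names(surv)[1:3], c("patient_id", "time_months", "event"))
  expect_equal(nrow(surv), 10)
  expect_true(all(patient_feature_names() %in% names(surv)))
  expect_true(file.exists(file.path(dir, "spec.yaml")))
})
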