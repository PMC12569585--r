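toy_outcomes <- function(time, event) tibble::tibble(time_months = time, event = event)

test_that("single-covariate fit matches brute-force partial-likelihood maximization", {
  set.seed(8)
  n <- 40
  x <- rbinom(n, 1, 0.5)
  time <- round(rexp(n, rate = exp(0.8 * x) / 20), 4)
  time <- time + seq_len(n) * 1e-6 # break ties so the 1-D oracle is clean
  out <- toy_outcomes(time, rep(1L, n))
  fit <- fit_cox(tibble::tibble(x = x), out, ridge_penalty = 0,
                 standardize = FALSE)
  opt <- stats::optimize(function(b) -oracle_cox_loglik1(b, x, time, rep(1, n)),
                         c(-5, 5), tol = 1e-10)
  expect_equal(unname(fit$beta), opt$minimum, tolerance = 1e-6)
  expect_true(fit$converged)
  # penalized log-likelihood at the optimum beats the null model
  expect_gte(fit$loglik, oracle_cox_loglik1(0, x, time, rep(1, n)))
})

test_that("the fit agrees with survival::coxph and shrinks under the penalty", {
  set.seed(9)
  n <- 120
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  lp <- 0.9 * scale(X$a)[, 1] - 0.5 * scale(X$b)[, 1]
  time <- rexp(n, rate = exp(lp) / 30)
  event <- rbinom(n, 1, 0.8)
  time[event == 0] <- time[event == 0] * runif(sum(event == 0))
  out <- toy_outcomes(time, event)
  fit <- fit_cox(X, out, ridge_penalty = 0)
  ref <- survival::coxph(
    survival::Surv(time, event) ~ scale(a) + scale(b), data = X, ties = "efron"
  )
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-5)

  heavy <- fit_cox(X, out, ridge_penalty = 1e6)
  expect_lt(max(abs(heavy$beta)), 1e-3) # lambda -> Inf drives beta -> 0
  expect_error(fit_cox(X, toy_outcomes(time, rep(0L, n))), "events")
})

test_that("risk prediction applies the stored standardization", {
  set.seed(10)
  X <- tibble::tibble(a = rnorm(50, 100, 10), b = rnorm(50))
  out <- toy_outcomes(rexp(50, 1 / 20), rbinom(50, 1, 0.7) * 1L)
  fit <- fit_cox(X, out, ridge_penalty = 0.1)
  r <- predict(fit, X)
  manual <- scale(as.matrix(X)) %*% fit$beta
  expect_equal(r, as.numeric(manual), tolerance = 1e-10)
  td <- tidy(fit); gl <- glance(fit)
  expect_identical(td$term, c("a", "b"))
  expect_equal(td$estimate / c(sd(X$a), sd(X$b)), td$estimate_raw)
  expect_true(gl$converged)
})

test_that("the concordance index follows Harrell's pair rules exactly", {
  out <- toy_outcomes(c(2, 4, 4, 6, 8, 9), c(1, 1, 0, 1, 0, 0))
  risk <- c(3.0, 2.0, 2.0, 1.0, 0.5, 0.8)
  expect_equal(concordance_index(out, risk),
               oracle_cindex(out$time_months, out$event, risk))
  # perfectly anti-ordered risks, all events
  o2 <- toy_outcomes(1:6, rep(1, 6))
  expect_equal(concordance_index(o2, 6:1), 1)
  expect_equal(concordance_index(o2, rep(2, 6)), 0.5)
  expect_error(concordance_index(toy_outcomes(c(1, 1), c(0, 0)), c(1, 2)),
               "comparable")
  # invariance under strictly monotone transforms
  set.seed(3)
  o3 <- toy_outcomes(rexp(30, 1 / 10), rbinom(30, 1, 0.6) * 1L)
  r3 <- rnorm(30)
  expect_equal(concordance_index(o3, r3), concordance_index(o3, exp(2 * r3)))
})

test_that("cross-validation is seeded, fold-standardized and leave-one-out capable", {
  co <- simulate_cohort(cohort_spec(n_patients = 60, glands_mean = 4, seed = 44))
  feats <- co$patients[, c("patient_id", names(co$spec$true_beta))]
  cv1 <- cox_cross_validate(feats, co$survival, k = 5, ridge_penalty = 0.1, seed = 7)
  cv2 <- cox_cross_validate(feats, co$survival, k = 5, ridge_penalty = 0.1, seed = 7)
  expect_identical(cv1$risk, cv2$risk)
  expect_identical(cv1$mean_c_index, cv2$mean_c_index)
  expect_equal(nrow(cv1$folds), 5)

  loo <- cox_cross_validate(feats[1:10, ], co$survival[1:10, ], k = 10,
                            ridge_penalty = 0.5, seed = 1)
  expect_equal(nrow(loo$risk), 10)
  expect_error(cox_cross_validate(feats[1:4, ], co$survival[1:4, ], k = 5),
               "exceed")

  # lambda grid selection returns one of the candidates
  cvg <- cox_cross_validate(feats, co$survival, k = 3,
                            ridge_penalty = c(0.01, 0.1, 1), seed = 2)
  expect_true(all(cvg$folds$lambda %in% c(0.01, 0.1, 1)))
})

test_that("median-split stratification follows the documented tie rules", {
  st <- stratify_risk(tibble::tibble(patient_id = sprintf("P%02d", 1:6),
                                     risk = c(1, 2, 3, 4, 5, 6)))
  expect_equal(sum(st$group == "High Risk"), 3)
  expect_equal(sum(st$group == "Low Risk"), 3)

  all_tied <- stratify_risk(rep(1.5, 8))
  expect_true(all(all_tied$group == "Low Risk"))

  # the cohort-sized case: 161 distinct scores -> 80 / 81
  set.seed(1)
  st161 <- stratify_risk(rnorm(161))
  expect_equal(sort(as.numeric(table(st161$group))), c(80, 81))
})

test_that("Kaplan-Meier estimates match hand-computed products", {
  # events at 1,2,3,4, no censoring: S(2) = (1 - 1/4)(1 - 1/3) = 0.5
  km <- kaplan_meier(toy_outcomes(1:4, rep(1, 4)))
  expect_equal(km_survival_at(km, "all", 2), 0.5)
  expect_equal(km_survival_at(km, "all", 0.5), 1)
  # no events: S identically 1
  km0 <- kaplan_meier(toy_outcomes(c(3, 5, 7), c(0, 0, 0)))
  expect_true(all(km0$surv == 1))
  # events at 6 and 10, censoring at 8: S(10) = (1 - 1/3)(1 - 1/1) = 0
  km2 <- kaplan_meier(toy_outcomes(c(6, 8, 10), c(1, 0, 1)))
  expect_equal(km_survival_at(km2, "all", 10), 0)
  expect_equal(km_survival_at(km2, "all", 9), 2 / 3)
})

test_that("the log-rank test matches a hand-computed table and the null", {
  # identical groups -> statistic 0, p = 1
  base <- toy_outcomes(c(2, 5, 9, 2, 5, 9), c(1, 1, 0, 1, 1, 0))
  lr0 <- logrank_test(base, c("A", "A", "A", "B", "B", "B"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # 6-patient worked example, O/E/V computed by hand:
  # times (group): 1(A,event) 2(B,event) 3(A,event) 4(B,cens) 5(A,event) 6(B,event)
  # t=1: nA=3 nB=3 d=1 E_A=0.5 V=0.25 ; t=2: nA=2 nB=3 d=1 E_A=0.4 V=0.24
  # t=3: nA=2 nB=2 d=1 E_A=0.5 V=0.25 ; t=5: nA=1 nB=1 d=1 E_A=0.5 V=0.25
  # t=6: nA=0 nB=1 d=1 E_A=0   V=0
  # O_A=3, E_A=1.9, V=0.99 -> chi2 = (3-1.9)^2/0.99
  out <- toy_outcomes(c(1, 3, 5, 2, 4, 6), c(1, 1, 1, 1, 0, 1))
  grp <- c("A", "A", "A", "B", "B", "B")
  lr <- logrank_test(out, grp)
  expect_equal(lr$statistic, (3 - 1.9)^2 / 0.99, tolerance = 1e-9)
  expect_equal(lr$p_value, pchisq((3 - 1.9)^2 / 0.99, 1, lower.tail = FALSE))
  expect_error(logrank_test(toy_outcomes(c(1, 2), c(0, 0)), c("A", "B")),
               "events")
})

test_that("plot methods return ggplot objects", {
  co <- simulate_cohort(cohort_spec(n_patients = 30, glands_mean = 3, seed = 2))
  km <- kaplan_meier(co$survival, rep(c("A", "B"), 15))
  expect_s3_class(autoplot(km), "ggplot")
  cv <- cox_cross_validate(co$patients[, c("patient_id", names(co$spec$true_beta))],
                           co$survival, k = 3, ridge_penalty = 0.5, seed = 1)
  expect_s3_class(autoplot(cv), "ggplot")
  s <- simulate_gland_image(64, 64, gland_regime("regular"), 2, seed = 1)
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(plot_label_map(s$truth), "ggplot")
})
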