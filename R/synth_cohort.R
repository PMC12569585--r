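# Synthetic patient cohorts: gland populations are drawn per patient from a
# mixture of shape regimes, measured with the package's own morphometry,
# aggregated, and survival times follow a Weibull-baseline Cox model on the
# (z-scored) aggregated features.

#' Specify a synthetic survival cohort
#'
#' @param n_patients Number of patients (`>= 2`).
#' @param glands_mean,glands_dispersion Negative-binomial mean and size for
#'   the per-patient gland count (truncated at 2).
#' @param regime_mixture Length-2 Beta shape parameters for each patient's
#'   fraction of deformed glands (so malignancy burden varies by patient).
#' @param regimes Named list with `regular` and `deformed`
#'   [gland_regime()]s used to draw glands.
#' @param true_beta Named coefficient vector over patient-level aggregate
#'   feature names (see [patient_feature_names()]), on the cohort z-score
#'   scale. Drives the hazard.
#' @param baseline_scale,baseline_shape Weibull baseline survival
#'   parameters (months; both `> 0`).
#' @param censoring_rate Target censored fraction in `[0, 1)`; independent
#'   exponential censoring calibrated by bisection.
#' @param seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 300,
                        glands_mean = 10, glands_dispersion = 8,
                        regime_mixture = c(2, 2),
                        regimes = list(regular = gland_regime("regular"),
                                       deformed = gland_regime("deformed")),
                        true_beta = c(eccentricity_mean = 1.25,
                                      solidity_mean = -1.0),
                        baseline_scale = 60, baseline_shape = 1.2,
                        censoring_rate = 0.3, seed = 1) {
  if (n_patients < 2) abort("`n_patients` must be >= 2.")
  stopifnot_scalar_number(baseline_scale, "baseline_scale", 1e-9)
  stopifnot_scalar_number(baseline_shape, "baseline_shape", 1e-9)
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("`censoring_rate` must lie in [0, 1).")
  }
  if (length(true_beta) > 0) {
    bad <- setdiff(names(true_beta), patient_feature_names())
    if (length(bad) > 0) {
      abort(sprintf(
        "`true_beta` names unknown aggregate feature(s): %s.",
        paste(bad, collapse = ", ")
      ))
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), glands_mean = glands_mean,
         glands_dispersion = glands_dispersion,
         regime_mixture = regime_mixture, regimes = regimes,
         true_beta = true_beta, baseline_scale = baseline_scale,
         baseline_shape = baseline_shape, censoring_rate = censoring_rate,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Exponential censoring rate hit by bisection so the expected censored
# fraction, given the sampled death times, equals the target.
calibrate_censoring <- function(times, target) {
  f <- function(rate) mean(1 - exp(-rate * times)) - target
  lo <- 1e-9; hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 10
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Simulate a synthetic survival cohort
#'
#' Draws each patient's gland population (count, deformed fraction, shapes),
#' rasterizes every gland and measures it with [gland_features()],
#' aggregates to the 78-column patient vector, and generates survival by
#' inverse-transform sampling from the Weibull-baseline Cox law
#' `S(t | x) = exp(-(t/scale)^shape * exp(beta' z))`, where `z` are the
#' cohort-z-scored aggregate features named in `true_beta`. Censoring times
#' are independent exponentials calibrated so the realized censored
#' fraction matches the target.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with tibbles `patients` (78 aggregate
#'   columns), `glands` (per-gland features + regime), `survival`
#'   (`patient_id`, `time_months`, `event`), `linear_predictor`
#'   (`patient_id`, `lp`, `death_time`), the realized censored fraction and
#'   the spec.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  patient_ids <- sprintf("P%04d", seq_len(spec$n_patients))
  glands <- vector("list", spec$n_patients)
  patients <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    rec <- with_seed(derive_seed(spec$seed, i), {
      n_g <- max(2L, rnbinom(1L, mu = spec$glands_mean,
                             size = spec$glands_dispersion))
      frac_deformed <- rbeta(1L, spec$regime_mixture[1], spec$regime_mixture[2])
      is_def <- runif(n_g) < frac_deformed
      vals <- matrix(0, n_g, 13L)
      regs <- character(n_g)
      for (g in seq_len(n_g)) {
        regime <- if (is_def[g]) spec$regimes$deformed else spec$regimes$regular
        mask <- single_gland_mask(regime)
        pts <- which(mask == 1L, arr.ind = TRUE)
        vals[g, ] <- compute_gland_record(pts[, 1L], pts[, 2L], mask == 1L)
        regs[g] <- regime$name
      }
      colnames(vals) <- gland_feature_names()
      feats <- as_tibble(vals)
      feats$regime <- regs
      feats$patient_id <- patient_ids[i]
      feats
    })
    glands[[i]] <- rec
    patients[[i]] <- aggregate_patient(rec, patient_id = patient_ids[i])
  }
  glands <- dplyr::bind_rows(glands)
  patients <- dplyr::bind_rows(patients)

  beta <- spec$true_beta
  if (length(beta) > 0) {
    Z <- scale(as.matrix(patients[, names(beta), drop = FALSE]))
    Z[is.nan(Z)] <- 0
    lp <- as.numeric(Z %*% beta)
  } else {
    lp <- rep(0, spec$n_patients)
  }

  surv <- with_seed(derive_seed(spec$seed, 0L), {
    u <- runif(spec$n_patients)
    death <- spec$baseline_scale * (-log(u) * exp(-lp))^(1 / spec$baseline_shape)
    if (spec$censoring_rate > 0) {
      rate <- calibrate_censoring(death, spec$censoring_rate)
      cens <- rexp(spec$n_patients, rate = rate)
    } else {
      cens <- rep(Inf, spec$n_patients)
    }
    tibble(
      patient_id = patient_ids,
      time_months = pmin(death, cens),
      event = as.integer(death <= cens),
      death_time = death
    )
  })

  structure(
    list(
      patients = patients,
      glands = glands,
      survival = surv[, c("patient_id", "time_months", "event")],
      linear_predictor = tibble(patient_id = patient_ids, lp = lp,
                                death_time = surv$death_time),
      censoring_realized = mean(surv$event == 0L),
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d patients, %d glands, %.0f%% censored\n",
    nrow(x$patients), nrow(x$glands), 100 * x$censoring_realized
  ))
  invisible(x)
}

#' Write cohort tables to CSV
#'
#' Writes `survival.csv` (patient_id, time_months, event, then the 78
#' feature columns) plus `glands.csv`, and the spec as `spec.yaml`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  joined <- dplyr::left_join(cohort$survival, cohort$patients,
                             by = "patient_id")
  utils::write.csv(joined, file.path(dir, "survival.csv"), row.names = FALSE)
  utils::write.csv(cohort$glands, file.path(dir, "glands.csv"),
                   row.names = FALSE)
  spec <- cohort$spec
  yaml::write_yaml(
    list(n_patients = spec$n_patients, glands_mean = spec$glands_mean,
         glands_dispersion = spec$glands_dispersion,
         regime_mixture = spec$regime_mixture,
         true_beta = as.list(spec$true_beta),
         baseline_scale = spec$baseline_scale,
         baseline_shape = spec$baseline_shape,
         censoring_rate = spec$censoring_rate, seed = spec$seed),
    file.path(dir, "spec.yaml")
  )
  invisible(dir)
}
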