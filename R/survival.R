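# Ridge-penalized Cox proportional-hazards modelling with cross-validated
# concordance, median-split risk stratification, Kaplan-Meier curves and
# the two-sample log-rank test.

as_survival_records <- function(outcomes) {
  req <- c("time_months", "event")
  if (!all(req %in% names(outcomes))) {
    abort("`outcomes` must contain columns `time_months` and `event`.")
  }
  if (any(outcomes$time_months <= 0)) abort("All times must be > 0.")
  if (!all(outcomes$event %in% c(0, 1))) abort("`event` must be 0/1.")
  outcomes
}

# Efron-tie-corrected penalized Cox partial log-likelihood, gradient and
# Hessian. X standardized n x p, times/events length n, lambda >= 0
# (penalty lambda/2 * ||beta||^2).
cox_loglik <- function(beta, X, time, event, lambda, want_deriv = TRUE) {
  n <- length(time)
  p <- ncol(X)
  ord <- order(time, -event)
  X <- X[ord, , drop = FALSE]
  time <- time[ord]; event <- event[ord]
  eta <- as.numeric(X %*% beta)
  w <- exp(eta)
  wx <- X * w
  # reverse cumulative sums over the risk set (time descending)
  S0 <- rev(cumsum(rev(w)))
  S1 <- apply(wx, 2L, function(col) rev(cumsum(rev(col))))
  S1 <- matrix(S1, nrow = n)
  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  ev_times <- sort(unique(time[event == 1]), decreasing = TRUE)
  s2 <- matrix(0, p, p)
  ptr <- n + 1L # rows [ptr..n] are already accumulated into s2
  for (t0 in ev_times) {
    D <- which(time == t0 & event == 1)
    d <- length(D)
    first <- match(t0, time) # first index with this time (risk set start)
    s0 <- S0[first]
    s1 <- S1[first, ]
    s0d <- sum(w[D])
    s1d <- colSums(wx[D, , drop = FALSE])
    ll <- ll + sum(eta[D])
    if (want_deriv) {
      if (first < ptr) {
        rows <- first:(ptr - 1L)
        s2 <- s2 + crossprod(X[rows, , drop = FALSE], wx[rows, , drop = FALSE])
        ptr <- first
      }
      s2d <- crossprod(X[D, , drop = FALSE], wx[D, , drop = FALSE])
    }
    for (j in seq_len(d) - 1L) {
      f <- j / d
      a0 <- s0 - f * s0d
      ll <- ll - log(a0)
      if (want_deriv) {
        a1 <- s1 - f * s1d
        a2 <- s2 - f * s2d
        grad <- grad + a1 / a0
        hess <- hess + a2 / a0 - tcrossprod(a1) / a0^2
      }
    }
  }
  if (want_deriv) {
    grad <- colSums(X[event == 1, , drop = FALSE]) - grad - lambda * beta
    hess <- hess + diag(lambda, p)
  }
  list(loglik = ll - lambda / 2 * sum(beta^2), grad = grad, neghess = hess)
}

#' Fit a ridge-penalized Cox proportional-hazards model
#'
#' Maximizes the Efron-tie-corrected Cox partial log-likelihood with an L2
#' penalty `lambda/2 * ||beta||^2` by Newton iterations with step-halving
#' (the penalized log-likelihood never decreases across iterations);
#' convergence when the relative log-likelihood change is below 1e-9 or
#' after 100 iterations. Features are z-scored internally (per-column mean
#' and scale stored and re-applied at prediction), which makes the
#' isotropic penalty meaningful across the mixed-unit morphometry columns;
#' zero-variance columns get coefficient 0.
#'
#' @param features Data frame / tibble of numeric covariates (a
#'   `patient_id` column, if present, is carried along, not used as a
#'   covariate).
#' @param outcomes Tibble with `time_months` and `event` (0/1), aligned
#'   row-wise with `features`.
#' @param ridge_penalty Scalar `lambda >= 0`.
#' @param standardize Z-score features before fitting (default `TRUE`).
#' @return A `cox_fit` with `beta` (standardized scale), `beta_raw`
#'   (original scale), centering/scale vectors, and a convergence report.
#' @export
fit_cox <- function(features, outcomes, ridge_penalty = 0.1,
                    standardize = TRUE) {
  outcomes <- as_survival_records(outcomes)
  stopifnot_scalar_number(ridge_penalty, "ridge_penalty", 0)
  ids <- features[["patient_id"]]
  X <- as.matrix(features[, setdiff(names(features), c("patient_id", "n_glands")),
                          drop = FALSE])
  storage.mode(X) <- "double"
  if (nrow(X) != nrow(outcomes)) {
    abort("`features` and `outcomes` must have the same number of rows.")
  }
  if (any(!is.finite(X))) abort("All feature values must be finite.")
  if (sum(outcomes$event) < 2) abort("At least 2 events are required.")
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl < 1e-12] <- Inf # zero-variance -> column zeroed out
    Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
    scl[!is.finite(scl)] <- 0
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
    Xs <- X
  }
  p <- ncol(Xs)
  beta <- numeric(p)
  time <- outcomes$time_months; event <- outcomes$event
  cur <- cox_loglik(beta, Xs, time, event, ridge_penalty)
  iter <- 0L; converged <- FALSE
  while (iter < 100L) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$neghess, cur$grad),
                     error = function(e) cur$grad / max(diag(cur$neghess), 1))
    new_beta <- beta + step
    new <- cox_loglik(new_beta, Xs, time, event, ridge_penalty)
    halvings <- 0L
    while ((!is.finite(new$loglik) || new$loglik < cur$loglik) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new <- cox_loglik(new_beta, Xs, time, event, ridge_penalty)
      halvings <- halvings + 1L
    }
    if (!is.finite(new$loglik) || new$loglik < cur$loglik) break
    rel <- abs(new$loglik - cur$loglik) / (abs(cur$loglik) + 1e-12)
    beta <- new_beta; cur <- new
    if (rel < 1e-9) { converged <- TRUE; break }
  }
  grad_norm <- sqrt(sum(cur$grad^2))
  if (!converged && grad_norm > 1e-4) {
    warn(sprintf(
      "Cox fit did not fully converge after %d iterations (gradient norm %.3g).",
      iter, grad_norm
    ))
  }
  scl_safe <- ifelse(scl > 0, scl, Inf)
  structure(
    list(
      beta = setNames(beta, colnames(Xs)),
      beta_raw = setNames(beta / scl_safe, colnames(Xs)),
      center = ctr, scale = scl,
      ridge_penalty = ridge_penalty,
      loglik = cur$loglik, iterations = iter,
      gradient_norm = grad_norm, converged = converged,
      n = nrow(Xs), n_events = sum(event),
      patient_id = ids
    ),
    class = "cox_fit"
  )
}

#' Predict risk scores (linear predictors) from a Cox fit
#'
#' @param object A [fit_cox()] result.
#' @param newdata Feature table with the fitted columns.
#' @param ... Unused.
#' @return Numeric vector of risk scores (higher = shorter expected
#'   survival).
#' @export
predict.cox_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, names(object$beta), drop = FALSE])
  scl <- ifelse(object$scale > 0, object$scale, 1)
  used <- object$scale > 0
  Xs <- sweep(sweep(X, 2L, object$center, "-"), 2L, scl, "/")
  Xs[, !used] <- 0
  as.numeric(Xs %*% object$beta)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "ridge Cox fit: %d features, n = %d (%d events), lambda = %.3g\n",
    length(x$beta), x$n, x$n_events, x$ridge_penalty
  ))
  cat(sprintf("log-likelihood %.4f after %d Newton iterations (%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the higher risk score
#' belongs to the patient with the shorter survival time. A pair is
#' comparable when the shorter time carries an event (the usual censoring
#' rules; at tied times, one event and one censored observation are
#' comparable with the event treated as earlier; two tied events are not).
#' Tied risk scores count 1/2.
#'
#' @param outcomes Tibble with `time_months` and `event`.
#' @param risk Numeric risk scores, aligned with `outcomes`.
#' @return Scalar in `[0, 1]`.
#' @export
concordance_index <- function(outcomes, risk) {
  outcomes <- as_survival_records(outcomes)
  t <- outcomes$time_months; e <- outcomes$event
  n <- length(t)
  if (length(risk) != n) abort("`risk` must align with `outcomes`.")
  dt <- outer(t, t, "-") # dt[i,j] = t_i - t_j
  comparable <- (dt < 0 & e == 1) | (dt == 0 & outer(e, 1 - e, "*") == 1)
  # comparable[i,j]: i is the (strictly or tie-event) earlier, event subject
  dr <- outer(risk, risk, "-")
  conc <- sum(comparable & dr > 0) + 0.5 * sum(comparable & dr == 0)
  denom <- sum(comparable)
  if (denom == 0) abort("No comparable pairs.")
  conc / denom
}

make_folds <- function(n, k, events, seed, max_tries = 100L) {
  with_seed(derive_seed(seed, 97L), {
    for (try in seq_len(max_tries)) {
      fold <- sample(rep(seq_len(k), length.out = n))
      ok <- all(vapply(seq_len(k), function(f) {
        sum(events[fold != f]) >= 2
      }, logical(1)))
      if (ok) return(fold)
    }
    abort(sprintf(
      "Could not build %d folds with >= 2 training events each (n = %d, %d events).",
      k, n, sum(events)
    ))
  })
}

#' Cross-validated ridge Cox modelling
#'
#' Splits patients into `k` seeded folds (resampled, still seeded, if a
#' training part would hold fewer than 2 events), fits the ridge Cox model
#' on each training part -- feature standardization is re-estimated inside
#' each training fold -- and scores the held-out fold. Returns per-fold
#' concordance and the pooled out-of-fold risk score per patient, which is
#' what downstream stratification uses. When `ridge_penalty` has several
#' values, the penalty is chosen per outer fold by an inner 3-fold
#' concordance grid search on the training part.
#'
#' @param features Feature tibble (optionally with `patient_id`).
#' @param outcomes Tibble with `time_months`, `event`, aligned row-wise.
#' @param k Number of folds (default 5; `k = n` gives leave-one-out).
#' @param ridge_penalty Scalar or vector of candidate `lambda`s.
#' @param seed Integer seed controlling the fold assignment.
#' @return A `cox_cv`: per-fold tibble (`fold`, `c_index`, `lambda`,
#'   `n_test`), `mean_c_index`, `risk` tibble (`patient_id`, `fold`,
#'   `risk`), and the refit-on-all-data `fit`.
#' @export
cox_cross_validate <- function(features, outcomes, k = 5, ridge_penalty = 0.1,
                               seed = 1) {
  outcomes <- as_survival_records(outcomes)
  n <- nrow(outcomes)
  if (n < k) abort("`k` cannot exceed the number of patients.")
  ids <- features[["patient_id"]] %||% sprintf("row%04d", seq_len(n))
  fold <- make_folds(n, k, outcomes$event, seed)
  risk <- numeric(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    lambda <- ridge_penalty
    if (length(ridge_penalty) > 1L) {
      lambda <- select_lambda(features[tr, , drop = FALSE], outcomes[tr, ],
                              ridge_penalty, seed = derive_seed(seed, 1000L + f))
    }
    fit <- fit_cox(features[tr, , drop = FALSE], outcomes[tr, ],
                   ridge_penalty = lambda)
    risk[te] <- predict(fit, features[te, , drop = FALSE])
    ci <- tryCatch(concordance_index(outcomes[te, ], risk[te]),
                   error = function(e) NA_real_)
    per_fold[[f]] <- tibble(fold = f, c_index = ci, lambda = lambda,
                            n_test = sum(te))
  }
  folds_tbl <- dplyr::bind_rows(per_fold)
  lambda_all <- if (length(ridge_penalty) > 1L) {
    stats::median(folds_tbl$lambda)
  } else {
    ridge_penalty
  }
  structure(
    list(
      folds = folds_tbl,
      mean_c_index = mean(folds_tbl$c_index, na.rm = TRUE),
      risk = tibble(patient_id = ids, fold = fold, risk = risk),
      fit = fit_cox(features, outcomes, ridge_penalty = lambda_all),
      k = k, seed = seed
    ),
    class = "cox_cv"
  )
}

# Inner-CV lambda selection by mean concordance.
select_lambda <- function(features, outcomes, grid, seed, k_inner = 3L) {
  scores <- vapply(grid, function(lam) {
    cv <- tryCatch(
      cox_cross_validate(features, outcomes, k = k_inner,
                         ridge_penalty = lam, seed = seed),
      error = function(e) NULL
    )
    if (is.null(cv)) NA_real_ else cv$mean_c_index
  }, numeric(1))
  if (all(is.na(scores))) return(grid[[1]])
  grid[[which.max(scores)]]
}

#' @export
print.cox_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated ridge Cox: mean C-index %.3f\n",
              x$k, x$mean_c_index))
  print(x$folds)
  invisible(x)
}

#' Median-split risk stratification
#'
#' Splits patients at the median of their (out-of-fold) risk scores:
#' strictly above the median is "High Risk", at or below is "Low Risk"
#' (documented tie rule; with all-equal scores everyone is Low Risk).
#'
#' @param risk Tibble with `patient_id` and `risk` (as from
#'   [cox_cross_validate()]`$risk`), or a bare numeric vector.
#' @return Tibble `patient_id`, `risk`, `group` (factor High/Low Risk)
#'   with the threshold as attribute `threshold`.
#' @export
stratify_risk <- function(risk) {
  if (is.numeric(risk)) {
    risk <- tibble(patient_id = sprintf("row%04d", seq_along(risk)),
                   risk = as.numeric(risk))
  }
  if (nrow(risk) < 2) abort("Need at least 2 patients to stratify.")
  thr <- median(risk$risk)
  out <- risk |>
    dplyr::mutate(group = factor(
      ifelse(.data$risk > thr, "High Risk", "Low Risk"),
      levels = c("Low Risk", "High Risk")
    ))
  attr(out, "threshold") <- thr
  out
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times of each group (computed via
#' [survival::survfit()]).
#'
#' @param outcomes Tibble with `time_months`, `event`.
#' @param group Factor/character of group membership (default: one group).
#' @return A `km_fit`: tibble `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (right-continuous step values).
#' @export
kaplan_meier <- function(outcomes, group = NULL) {
  outcomes <- as_survival_records(outcomes)
  group <- group %||% rep("all", nrow(outcomes))
  if (length(group) != nrow(outcomes)) abort("`group` must align with `outcomes`.")
  df <- data.frame(time = outcomes$time_months, event = outcomes$event,
                   group = as.character(group))
  out <- purrr::map_dfr(split(df, df$group), function(d) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    tibble(group = d$group[[1]], time = sf$time, n_risk = sf$n.risk,
           n_event = sf$n.event, n_censor = sf$n.censor, surv = sf$surv)
  })
  class(out) <- c("km_fit", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' @param km A [kaplan_meier()] result.
#' @param group Group name.
#' @param t Time (months).
#' @return `S(t)` for that group (1 before the first event).
#' @export
km_survival_at <- function(km, group, t) {
  d <- km[km$group == group & km$time <= t, ]
  if (nrow(d) == 0) return(1)
  tail(d$surv, 1L)
}

#' Two-sample log-rank test
#'
#' Standard log-rank comparison of two survival distributions: at each
#' distinct event time the observed events in group 1 are compared with
#' their hypergeometric expectation; the statistic `(O - E)^2 / V` is
#' chi-square with 1 degree of freedom under the null (computed via
#' [survival::survdiff()]).
#'
#' @param outcomes Tibble with `time_months`, `event`.
#' @param group Two-level factor/character membership vector.
#' @return List with `statistic`, `p_value`, `df = 1`, and per-group
#'   observed/expected event counts.
#' @export
logrank_test <- function(outcomes, group) {
  outcomes <- as_survival_records(outcomes)
  group <- as.character(group)
  if (length(unique(group)) != 2) abort("`group` must have exactly 2 levels.")
  if (sum(outcomes$event) == 0) abort("No events; log-rank test undefined.")
  df <- data.frame(time = outcomes$time_months, event = outcomes$event,
                   group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  stat <- as.numeric(sd$chisq)
  list(
    statistic = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    df = 1L,
    observed = as.numeric(sd$obs),
    expected = as.numeric(sd$exp),
    groups = sub("^group=", "", names(sd$n))
  )
}
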