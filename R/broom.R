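# broom-style accessors for fitted objects.

#' Tidy a ridge Cox fit
#'
#' @param x A [fit_cox()] result.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (standardized scale),
#'   `estimate_raw` (original feature scale).
#' @exportS3Method generics::tidy
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    estimate_raw = unname(x$beta_raw)
  )
}

#' One-row summary of a ridge Cox fit
#'
#' @param x A [fit_cox()] result.
#' @param ... Unused.
#' @exportS3Method generics::glance
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(
    n = x$n, n_events = x$n_events, n_features = length(x$beta),
    ridge_penalty = x$ridge_penalty, loglik = x$loglik,
    iterations = x$iterations, converged = x$converged,
    gradient_norm = x$gradient_norm
  )
}

#' Per-fold results of a cross-validated Cox model
#'
#' @param x A [cox_cross_validate()] result.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.cox_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validated Cox model
#'
#' @param x A [cox_cross_validate()] result.
#' @param ... Unused.
#' @exportS3Method generics::glance
#' @export
glance.cox_cv <- function(x, ...) {
  tibble(
    k = x$k, mean_c_index = x$mean_c_index,
    sd_c_index = sd(x$folds$c_index),
    lambda = x$fit$ridge_penalty, seed = x$seed
  )
}
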