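# Internal helpers shared across modules.

# Derive an independent child seed from a base seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 1103515245 * stream) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so seeded operations never perturb user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite scalar in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

# Clamp to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_label_map <- function(x) {
  is.matrix(x) && (is.numeric(x) || is.integer(x)) && all(x >= 0) &&
    all(x == floor(x))
}

assert_label_map <- function(x, arg = "labels") {
  if (!is_label_map(x)) {
    abort(sprintf("`%s` must be an integer matrix with values >= 0.", arg))
  }
  invisible(x)
}

assert_same_shape <- function(a, b, names = c("pred", "truth")) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf(
      "`%s` (%s) and `%s` (%s) must have identical dimensions.",
      names[1], paste(dim(a), collapse = "x"),
      names[2], paste(dim(b), collapse = "x")
    ))
  }
  invisible(NULL)
}
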