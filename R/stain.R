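# Structure-preserving (Vahadane-style) H&E stain normalization:
# Beer-Lambert optical density, sparse non-negative two-stain dictionary
# learning, and concentration-rescaled recombination against a target.

#' RGB to optical density
#'
#' Beer-Lambert transform `OD = -log10((I + 1) / 256)` per channel. The
#' `+1` keeps the transform total on 8-bit input (no `log(0)`), and makes
#' [od_to_rgb()] an exact inverse on integers.
#'
#' @param image Numeric array (any shape) of 8-bit intensities in `[0, 255]`.
#' @return Array of the same shape, optical densities `>= 0`.
#' @export
rgb_to_od <- function(image) {
  if (min(image) < 0 || max(image) > 255) {
    abort("`image` intensities must lie in [0, 255].")
  }
  -log10((image + 1) / 256)
}

#' Optical density back to 8-bit RGB
#'
#' @param od Array of optical densities.
#' @return Array of intensities in `[0, 255]` (rounded).
#' @export
od_to_rgb <- function(od) {
  clamp(round(256 * 10^(-od) - 1), 0, 255)
}

#' Construct a stain profile
#'
#' @param stain_matrix 3x2 non-negative matrix; columns are unit-norm
#'   optical-density vectors (hematoxylin first, then eosin).
#' @param concentration_scale Length-2 robust (99th percentile) per-stain
#'   concentration maxima.
#' @param low_confidence Logical; `TRUE` when the second stain component is
#'   degenerate (near single-stain tissue).
#' @return A `stain_profile` object.
#' @export
stain_profile <- function(stain_matrix, concentration_scale,
                          low_confidence = FALSE) {
  stain_matrix <- as.matrix(stain_matrix)
  if (!all(dim(stain_matrix) == c(3L, 2L)) || any(stain_matrix < 0)) {
    abort("`stain_matrix` must be a non-negative 3x2 matrix.")
  }
  nrm <- sqrt(colSums(stain_matrix^2))
  if (any(nrm == 0)) abort("`stain_matrix` columns must be non-zero.")
  stain_matrix <- sweep(stain_matrix, 2L, nrm, "/")
  colnames(stain_matrix) <- c("H", "E")
  rownames(stain_matrix) <- c("R", "G", "B")
  structure(
    list(stain_matrix = stain_matrix,
         concentration_scale = as.numeric(concentration_scale),
         low_confidence = isTRUE(low_confidence)),
    class = "stain_profile"
  )
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("H&E stain profile\n")
  print(round(x$stain_matrix, 4))
  cat("concentration scale (99th pct): ",
      paste(round(x$concentration_scale, 3), collapse = ", "), "\n", sep = "")
  if (x$low_confidence) cat("NOTE: second stain component is low-confidence\n")
  invisible(x)
}

# Non-negative lasso coding of OD pixels against a fixed 3x2 dictionary W
# (unit-norm columns). V is 3 x n. Coordinate descent, vectorized over
# pixels; exact for this 2-atom problem after a few sweeps.
stain_code <- function(V, W, lambda = 0, n_iter = 25L) {
  g <- crossprod(W) # 2x2 Gram, diagonal 1
  WtV <- crossprod(W, V) # 2 x n
  H <- pmax(WtV - lambda, 0) # warm start (ignores cross term)
  for (it in seq_len(n_iter)) {
    H[1L, ] <- pmax(WtV[1L, ] - g[1L, 2L] * H[2L, ] - lambda, 0)
    H[2L, ] <- pmax(WtV[2L, ] - g[1L, 2L] * H[1L, ] - lambda, 0)
  }
  H
}

# Macenko-style geometric initialization of the two stain directions: the
# extreme angles of tissue OD pixels in the plane of the top two principal
# components, clipped non-negative.
init_stain_matrix <- function(V) {
  sv <- svd(V %*% t(V))
  basis <- sv$u[, 1:2]
  if (sum(basis[, 1]) < 0) basis[, 1] <- -basis[, 1]
  proj <- crossprod(basis, V)
  ang <- atan2(proj[2L, ], proj[1L, ])
  lo <- quantile(ang, 0.01, names = FALSE)
  hi <- quantile(ang, 0.99, names = FALSE)
  W <- cbind(
    basis %*% c(cos(lo), sin(lo)),
    basis %*% c(cos(hi), sin(hi))
  )
  W <- pmax(W, 1e-6)
  sweep(W, 2L, sqrt(colSums(W^2)), "/")
}

#' Estimate an H&E stain profile by sparse non-negative factorization
#'
#' Factorizes tissue optical densities `V ~ W H` with a non-negative 3x2
#' dictionary `W` (unit-norm columns) and non-negative sparse
#' concentrations `H`, by alternating lasso-regularized coding and
#' multiplicative-style dictionary updates (at most 50 alternations or
#' relative dictionary change below 1e-4). Background pixels (OD magnitude
#' below `od_threshold`) are excluded from estimation. The hematoxylin
#' column is identified as the one with the larger blue-channel OD
#' component and is stored first.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param sparsity_weight Non-negative lasso weight on concentrations
#'   (default 0.01).
#' @param od_threshold Background exclusion threshold on the OD Euclidean
#'   norm (default 0.15).
#' @return A [stain_profile()]; `low_confidence` is set when the tissue is
#'   effectively single-stain (second component nearly parallel to the
#'   first or carrying negligible concentration).
#' @export
estimate_stains <- function(image, sparsity_weight = 0.01,
                            od_threshold = 0.15) {
  stopifnot_scalar_number(sparsity_weight, "sparsity_weight", 0)
  od <- rgb_to_od(image)
  V_all <- t(matrix(od, ncol = 3L)) # 3 x n
  keep <- sqrt(colSums(V_all^2)) >= od_threshold
  n_tissue <- sum(keep)
  if (n_tissue < 100L) {
    abort(sprintf(
      "Too few tissue pixels for stain estimation: %d above OD threshold %.2f (need >= 100).",
      n_tissue, od_threshold
    ))
  }
  V <- V_all[, keep, drop = FALSE]
  W <- init_stain_matrix(V)
  for (it in seq_len(50L)) {
    H <- stain_code(V, W, lambda = sparsity_weight)
    W_old <- W
    for (k in 1:2) {
      hk <- H[k, ]
      denom <- sum(hk^2)
      if (denom < 1e-12) next
      resid <- V - W[, -k, drop = FALSE] %*% H[-k, , drop = FALSE]
      wk <- pmax(as.numeric(resid %*% hk) / denom, 0)
      nw <- sqrt(sum(wk^2))
      if (nw > 1e-12) {
        W[, k] <- wk / nw
        H[k, ] <- H[k, ] * nw
      }
    }
    if (sqrt(sum((W - W_old)^2)) / sqrt(sum(W_old^2)) < 1e-4) break
  }
  # debiasing polish: refit the dictionary without the lasso penalty (the
  # sparsity shapes the search; the final basis is the least-squares cone)
  for (it in seq_len(100L)) {
    H <- stain_code(V, W, lambda = 0)
    W_old <- W
    for (k in 1:2) {
      hk <- H[k, ]
      denom <- sum(hk^2)
      if (denom < 1e-12) next
      resid <- V - W[, -k, drop = FALSE] %*% H[-k, , drop = FALSE]
      wk <- pmax(as.numeric(resid %*% hk) / denom, 0)
      nw <- sqrt(sum(wk^2))
      if (nw > 1e-12) {
        W[, k] <- wk / nw
        H[k, ] <- H[k, ] * nw
      }
    }
    if (sqrt(sum((W - W_old)^2)) / sqrt(sum(W_old^2)) < 1e-6) break
  }
  # H first: larger blue-channel OD component
  if (W[3L, 2L] > W[3L, 1L]) W <- W[, c(2L, 1L)]
  # concentration scales from unpenalized coding, matching how
  # stain_normalize codes patches (the lasso only shapes the dictionary)
  H <- stain_code(V, W, lambda = 0)
  scale99 <- apply(H, 1L, quantile, probs = 0.99, names = FALSE)
  cosang <- sum(W[, 1L] * W[, 2L])
  low_conf <- scale99[2L] < 0.05 * max(scale99[1L], 1e-12) || cosang > 0.95
  stain_profile(W, scale99, low_confidence = low_conf)
}

#' Normalize a patch to a target stain profile
#'
#' Codes the patch's optical densities against the source stain matrix,
#' rescales each stain's concentrations by the ratio of target to source
#' concentration scales, and recombines with the target stain matrix
#' (structure-preserving normalization: concentrations, i.e. tissue
#' structure, are kept; colour basis and dynamic range are replaced).
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param target Target [stain_profile()].
#' @param source Source profile; estimated from `image` when `NULL`.
#' @return Normalized RGB array, clipped to `[0, 255]`.
#' @export
stain_normalize <- function(image, target, source = NULL) {
  if (!inherits(target, "stain_profile")) abort("`target` must be a stain_profile.")
  if (is.null(source)) source <- estimate_stains(image)
  if (!inherits(source, "stain_profile")) abort("`source` must be a stain_profile.")
  od <- rgb_to_od(image)
  V <- t(matrix(od, ncol = 3L))
  H <- stain_code(V, source$stain_matrix, lambda = 0)
  ratio <- ifelse(source$concentration_scale > 1e-12,
                  target$concentration_scale / source$concentration_scale, 1)
  H <- H * ratio
  od_new <- t(target$stain_matrix %*% H)
  out <- od_to_rgb(array(od_new, dim(image)))
  out
}

#' Write a stain profile to JSON
#' @param profile A [stain_profile()].
#' @param path Output path.
#' @export
write_stain_profile <- function(profile, path) {
  jsonlite::write_json(
    list(stain_matrix = as.numeric(profile$stain_matrix), # column-major 3x2
         concentration_scale = profile$concentration_scale,
         low_confidence = profile$low_confidence),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a stain profile from JSON
#' @param path JSON path written by [write_stain_profile()].
#' @return A [stain_profile()].
#' @export
read_stain_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_profile(matrix(unlist(x$stain_matrix), 3L, 2L),
                x$concentration_scale, isTRUE(x$low_confidence))
}

# Stable content hash of a stain profile, recorded in checkpoints so
# inference can verify it is normalizing against the training target.
stain_profile_hash <- function(profile) {
  v <- c(as.numeric(profile$stain_matrix), profile$concentration_scale)
  paste(format(sum(v * seq_along(v)) %% 1e9, digits = 12), collapse = "")
}
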