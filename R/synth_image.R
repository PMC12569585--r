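# Synthetic H&E gland images with instance ground truth.
#
# Glands are deformed ellipses: polar radius r(theta) = base * (1 +
# amplitude * smooth-noise(theta)) around an ellipse, rasterized onto the
# canvas, with an optional concentric pale lumen so the hematoxylin-dark
# epithelium forms the ring that contour-aware segmentation targets.

#' Gland shape regime
#'
#' Parameter bundle describing one shape population. The two built-in
#' presets mirror the benign/malignant contrast: `regular` glands are
#' near-elliptic with lumens, `deformed` glands are elongated, irregular
#' and more often lumen-free.
#'
#' @param name `"regular"` or `"deformed"` (selects preset defaults), or
#'   any other string with all parameters given explicitly.
#' @param axis_length_range Semi-major-axis range in pixels, `c(min, max)`.
#' @param aspect_ratio_range Major/minor aspect-ratio range (`>= 1`).
#' @param boundary_noise_amplitude Boundary deformation amplitude as a
#'   fraction of the local radius (`>= 0`).
#' @param lumen_probability Probability a gland carries a lumen.
#' @param touching_probability Probability a gland is allowed to be placed
#'   touching an already-placed gland.
#' @return A `gland_regime` object.
#' @export
gland_regime <- function(name = c("regular", "deformed"),
                         axis_length_range = NULL,
                         aspect_ratio_range = NULL,
                         boundary_noise_amplitude = NULL,
                         lumen_probability = NULL,
                         touching_probability = NULL) {
  name <- name[[1]]
  preset <- switch(name,
    regular = list(axis = c(10, 16), aspect = c(1, 1.5), amp = 0.08,
                   lumen = 0.9, touch = 0.2),
    deformed = list(axis = c(8, 20), aspect = c(1, 2.5), amp = 0.35,
                    lumen = 0.4, touch = 0.35),
    list(axis = NULL, aspect = NULL, amp = NULL, lumen = NULL, touch = NULL)
  )
  r <- list(
    name = name,
    axis_length_range = axis_length_range %||% preset$axis,
    aspect_ratio_range = aspect_ratio_range %||% preset$aspect,
    boundary_noise_amplitude = boundary_noise_amplitude %||% preset$amp,
    lumen_probability = lumen_probability %||% preset$lumen,
    touching_probability = touching_probability %||% preset$touch
  )
  if (any(vapply(r, is.null, logical(1)))) {
    abort("Custom regimes must specify all parameters.")
  }
  if (r$axis_length_range[1] > r$axis_length_range[2] ||
      r$aspect_ratio_range[1] > r$aspect_ratio_range[2]) {
    abort("Regime ranges must satisfy min <= max.")
  }
  if (r$boundary_noise_amplitude < 0) abort("`boundary_noise_amplitude` must be >= 0.")
  for (p in c("lumen_probability", "touching_probability")) {
    stopifnot_scalar_number(r[[p]], p, 0, 1)
  }
  structure(r, class = "gland_regime")
}

# Smooth 2pi-periodic noise: a few low-order Fourier harmonics with random
# coefficients, normalized to max |s| = 1 (returns a function of theta).
periodic_noise <- function() {
  ks <- 2:5
  a <- rnorm(length(ks)) / ks
  b <- rnorm(length(ks)) / ks
  grid <- seq(0, 2 * pi, length.out = 256)
  sg <- colSums(a * sin(outer(ks, grid)) + b * cos(outer(ks, grid)))
  m <- max(abs(sg))
  if (m < 1e-9) m <- 1
  function(theta) {
    colSums(a * sin(outer(ks, theta)) + b * cos(outer(ks, theta))) / m
  }
}

# Sample one gland's geometry from a regime.
sample_gland_shape <- function(regime) {
  a <- runif(1, regime$axis_length_range[1], regime$axis_length_range[2])
  aspect <- runif(1, regime$aspect_ratio_range[1], regime$aspect_ratio_range[2])
  list(
    a = a,
    b = a / aspect,
    phi = runif(1, -pi / 2, pi / 2),
    noise = periodic_noise(),
    amp = regime$boundary_noise_amplitude,
    has_lumen = runif(1) < regime$lumen_probability,
    lumen_scale = runif(1, 0.4, 0.6)
  )
}

# Rasterize a gland shape centred at (cy, cx) on an nr x nc canvas.
# Returns row/col indices for the gland and its lumen.
rasterize_gland <- function(shape, cy, cx, nr, nc) {
  rmax <- shape$a * (1 + shape$amp) + 2
  r0 <- max(1L, floor(cy - rmax)); r1 <- min(nr, ceiling(cy + rmax))
  c0 <- max(1L, floor(cx - rmax)); c1 <- min(nc, ceiling(cx + rmax))
  if (r0 > r1 || c0 > c1) {
    return(list(gland = cbind(integer(), integer()),
                lumen = cbind(integer(), integer())))
  }
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  xp <- cos(shape$phi) * dx + sin(shape$phi) * dy
  yp <- -sin(shape$phi) * dx + cos(shape$phi) * dy
  u <- xp / shape$a
  v <- yp / shape$b
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  lim <- 1 + shape$amp * shape$noise(as.numeric(theta))
  inside <- rho <= lim
  in_lumen <- shape$has_lumen & (rho <= shape$lumen_scale * lim)
  gi <- which(inside, arr.ind = TRUE)
  li <- which(matrix(in_lumen, nrow(rho), ncol(rho)), arr.ind = TRUE)
  list(
    gland = cbind(gi[, 1L] + r0 - 1L, gi[, 2L] + c0 - 1L),
    lumen = cbind(li[, 1L] + r0 - 1L, li[, 2L] + c0 - 1L)
  )
}

# Largest 4-connected component of a pixel set; returns a logical keep mask
# over the rows of `pts`.
largest_component_keep <- function(pts, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m[pts] <- TRUE
  lab <- label_instances(m)
  if (max(lab) <= 1L) return(rep(TRUE, nrow(pts)))
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  lab[pts] == best
}

# Smooth spatial noise field (unit sd), via Gaussian-blurred white noise.
smooth_field <- function(nr, nc, sigma = 6) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  f <- EBImage::gblur(z, sigma = sigma)
  f <- as.matrix(f)
  s <- sd(f)
  if (s < 1e-9) s <- 1
  f / s
}

# Reference H&E optical-density stain matrix (Ruifrok-style), unit columns.
he_stain_matrix <- function() {
  m <- cbind(H = c(0.65, 0.70, 0.29), E = c(0.07, 0.99, 0.11))
  rownames(m) <- c("R", "G", "B")
  sweep(m, 2L, sqrt(colSums(m^2)), "/")
}

#' Simulate an H&E gland image with instance ground truth
#'
#' Places `n_glands` deformed-ellipse glands on a stroma background and
#' renders them through a Beer-Lambert two-stain model: epithelium is
#' hematoxylin-rich, stroma eosin-rich, lumens pale. Touching pairs are
#' allowed with the regime's `touching_probability`; the ground truth keeps
#' touching glands as distinct labels so contour learning is exercised.
#' Glands that cannot be placed after repeated attempts are dropped and the
#' realized count reported.
#'
#' @param width,height Canvas size in pixels (each `>= 64`).
#' @param regime A [gland_regime()].
#' @param n_glands Number of glands to attempt to place.
#' @param seed Integer seed; output is bit-reproducible.
#' @param stain_variation Relative perturbation of the rendering stain
#'   matrix and concentration gain (default 0.12), emulating lab-to-lab
#'   stain variation.
#' @param background `"stroma"` renders eosin-pink stroma over the whole
#'   canvas; `"white"` places an elliptic tissue region on a near-white
#'   slide background (glands only inside the tissue), as on a scanned
#'   slide.
#' @return A `gland_sample`: list with `image` (`H x W x 3`, 0-255),
#'   `truth` (integer label matrix, consecutive labels, each 4-connected),
#'   `regimes` (per-instance regime name), `n_requested`, `n_placed`.
#' @export
simulate_gland_image <- function(width, height, regime = gland_regime("regular"),
                                 n_glands = 5, seed = 1,
                                 stain_variation = 0.12,
                                 background = c("stroma", "white")) {
  background <- match.arg(background)
  if (width < 64 || height < 64) abort("Canvas must be at least 64 x 64 pixels.")
  if (n_glands < 0) abort("`n_glands` must be >= 0.")
  if (!inherits(regime, "gland_regime")) abort("`regime` must be a gland_regime.")
  nr <- as.integer(height); nc <- as.integer(width)
  with_seed(derive_seed(seed, 1L), {
    tissue <- matrix(TRUE, nr, nc)
    if (background == "white") {
      cy <- nr * runif(1, 0.4, 0.6); cx <- nc * runif(1, 0.4, 0.6)
      ay <- nr * runif(1, 0.3, 0.42); ax <- nc * runif(1, 0.3, 0.42)
      rr <- matrix(seq_len(nr), nr, nc); cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      tissue <- ((rr - cy) / ay)^2 + ((cc - cx) / ax)^2 <= 1
    }
    truth <- matrix(0L, nr, nc)
    lumen_mask <- matrix(FALSE, nr, nc)
    placed <- 0L
    regimes <- character()
    min_axis <- regime$axis_length_range[1]
    if (n_glands > 0 && (nr < 2 * min_axis + 4 || nc < 2 * min_axis + 4)) {
      abort(sprintf(
        "Placement failure: canvas %dx%d cannot hold any gland with semi-axis >= %.1f.",
        nc, nr, min_axis
      ))
    }
    box3 <- matrix(1, 3, 3)
    for (g in seq_len(n_glands)) {
      allow_touch <- runif(1) < regime$touching_probability
      occupied_dil <- NULL
      done <- FALSE
      for (attempt in seq_len(50L)) {
        shape <- sample_gland_shape(regime)
        margin <- shape$b
        cy <- runif(1, 1 + margin, nr - margin)
        cx <- runif(1, 1 + margin, nc - margin)
        ras <- rasterize_gland(shape, cy, cx, nr, nc)
        if (nrow(ras$gland) < 30L) next
        if (!all(tissue[ras$gland])) next
        occ_at <- truth[ras$gland] > 0L
        if (allow_touch && placed > 0L) {
          if (mean(occ_at) > 0.35) next
          pts <- ras$gland[!occ_at, , drop = FALSE]
        } else {
          if (any(occ_at)) next
          if (placed > 0L) {
            if (is.null(occupied_dil)) {
              occupied_dil <- EBImage::dilate(
                matrix(as.numeric(truth > 0L), nr, nc), box3) > 0
            }
            if (any(occupied_dil[ras$gland])) next
          }
          pts <- ras$gland
        }
        if (nrow(pts) < 30L || nrow(pts) < 0.5 * nrow(ras$gland)) next
        keep <- largest_component_keep(pts, nr, nc)
        pts <- pts[keep, , drop = FALSE]
        if (nrow(pts) < 30L) next
        placed <- placed + 1L
        truth[pts] <- placed
        if (nrow(ras$lumen) > 0) {
          sel <- truth[ras$lumen] == placed
          lumen_mask[ras$lumen[sel, , drop = FALSE]] <- TRUE
        }
        regimes <- c(regimes, regime$name)
        done <- TRUE
        break
      }
    }
    if (n_glands > 0 && placed == 0L) {
      abort(sprintf(
        "Placement failure: none of %d glands could be placed on a %dx%d canvas.",
        n_glands, nc, nr
      ))
    }
    epithelium <- truth > 0L & !lumen_mask
    # concentration fields: smooth texture plus per-pixel granularity; the
    # granular term leaves some nearly pure-hematoxylin (nuclei-like) and
    # pure-eosin (collagen-like) pixels, as in real H&E
    tex_h <- smooth_field(nr, nc)
    tex_e <- smooth_field(nr, nc)
    grain_h <- matrix(rnorm(nr * nc), nr, nc)
    grain_e <- matrix(rnorm(nr * nc), nr, nc)
    c_h <- 0.12 + 0.03 * tex_h + 0.05 * grain_h
    c_e <- 0.45 + 0.08 * tex_e + 0.10 * grain_e
    c_h[epithelium] <- 0.85 + 0.06 * tex_h[epithelium] + 0.07 * grain_h[epithelium]
    c_e[epithelium] <- 0.18 + 0.05 * tex_e[epithelium] + 0.08 * grain_e[epithelium]
    c_h[lumen_mask] <- 0.04
    c_e[lumen_mask] <- 0.06
    if (background == "white") {
      c_h[!tissue] <- 0.005
      c_e[!tissue] <- 0.005
    }
    c_h <- pmax(c_h, 0.01); c_e <- pmax(c_e, 0.01)
    M <- he_stain_matrix()
    if (stain_variation > 0) {
      M <- pmax(M + stain_variation * matrix(runif(6, -1, 1), 3, 2) * M, 1e-3)
      M <- sweep(M, 2L, sqrt(colSums(M^2)), "/")
      gain <- 1 + stain_variation * runif(2, -1, 1)
    } else {
      gain <- c(1, 1)
    }
    od <- cbind(as.numeric(c_h) * gain[1], as.numeric(c_e) * gain[2]) %*% t(M)
    image <- od_to_rgb(array(od, c(nr, nc, 3L)))
    structure(
      list(image = image, truth = truth, regimes = regimes,
           n_requested = as.integer(n_glands), n_placed = placed,
           lumen = lumen_mask, tissue = tissue, seed = as.integer(seed)),
      class = "gland_sample"
    )
  })
}

#' @export
print.gland_sample <- function(x, ...) {
  cat(sprintf("synthetic gland sample: %dx%d, %d/%d glands placed (%s)\n",
              ncol(x$truth), nrow(x$truth), x$n_placed, x$n_requested,
              paste(unique(x$regimes), collapse = "/")))
  invisible(x)
}

# Rasterize one free-standing gland and return its binary mask (used by the
# cohort generator, which works at the gland level rather than full tiles).
single_gland_mask <- function(regime) {
  shape <- sample_gland_shape(regime)
  half <- ceiling(shape$a * (1 + shape$amp)) + 2L
  n <- 2L * half + 1L
  ras <- rasterize_gland(shape, half + 1, half + 1, n, n)
  m <- matrix(0L, n, n)
  m[ras$gland] <- 1L
  lab <- label_instances(m)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    lab <- matrix(as.integer(lab == which.max(sizes)), n, n)
  }
  lab
}
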