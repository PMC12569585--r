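# Gland morphometry: 13 per-gland shape descriptors and their patient-level
# aggregation into a fixed-order feature vector.

# Canonical feature order used everywhere downstream.
GLAND_FEATURES <- c(
  "area", "major_axis_length", "minor_axis_length", "eccentricity",
  "orientation", "convex_area", "filled_area", "equivalent_diameter",
  "solidity", "extent", "perimeter", "box_aspect_ratio", "compactness"
)

AGGREGATORS <- c("mean", "median", "std", "skewness", "kurtosis", "max")

#' Names of the 13 per-gland morphological features
#' @return Character vector in canonical column order.
#' @export
gland_feature_names <- function() GLAND_FEATURES

#' Names of the 78 patient-level aggregate columns
#' @return Character vector, `feature_statistic`, features varying slowest.
#' @export
patient_feature_names <- function() {
  as.vector(t(outer(GLAND_FEATURES, AGGREGATORS, paste, sep = "_")))
}

# Crofton 4-direction perimeter estimate from 2x2 configuration counts.
# Matches the integral-geometry LUT convention; rotation-90 invariant.
crofton_perimeter <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  # code over all 2x2 windows: bottom-right 1, bottom-left 4, top-right 2,
  # top-left 8 (rows = y, cols = x)
  br <- p[2:(nr + 2L), 2:(nc + 2L)]
  bl <- p[2:(nr + 2L), 1:(nc + 1L)]
  tr <- p[1:(nr + 1L), 2:(nc + 2L)]
  tl <- p[1:(nr + 1L), 1:(nc + 1L)]
  code <- br + 4L * bl + 2L * tr + 8L * tl
  s2 <- sqrt(2)
  coefs <- c(
    pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
    pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
    pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
    pi / 4, pi / 2, 0, 0
  ) # for codes 1..15
  counts <- tabulate(code, nbins = 15L)
  sum(counts * coefs)
}

# Convex area: number of pixels whose centers lie inside the convex hull of
# the object's boundary-pixel corners. Guarantees area <= convex_area and an
# exact match for convex rasterized shapes.
convex_area_pixels <- function(rows, cols) {
  if (length(rows) <= 2L) return(length(rows))
  # corners of every pixel (cheap enough for gland-sized blobs)
  cr <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  cc <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  h <- grDevices::chull(cc, cr)
  hx <- cc[h]; hy <- cr[h] # chull returns clockwise order
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  grid <- expand.grid(r = r0:r1, c = c0:c1)
  inside <- rep(TRUE, nrow(grid))
  nv <- length(hx)
  for (k in seq_len(nv)) {
    k2 <- if (k == nv) 1L else k + 1L
    ex <- hx[k2] - hx[k]; ey <- hy[k2] - hy[k]
    cross <- ex * (grid$r - hy[k]) - ey * (grid$c - hx[k])
    # clockwise hull in (x, y) = (col, row with y down): inside is cross <= 0
    inside <- inside & (cross <= 1e-9)
  }
  sum(inside)
}

filled_area_pixels <- function(mask) {
  f <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  sum(f != 0)
}

compute_gland_record <- function(rows, cols, mask) {
  n <- length(rows)
  x <- cols; y <- -rows # y up so orientation is CCW from the x-axis
  xc <- mean(x); yc <- mean(y)
  # second central moments with the pixel-as-unit-square (+1/12) correction
  mu20 <- mean((x - xc)^2) + 1 / 12
  mu02 <- mean((y - yc)^2) + 1 / 12
  mu11 <- mean((x - xc) * (y - yc))
  common <- (mu20 + mu02) / 2
  delta <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- common + delta
  l2 <- max(common - delta, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (orient <= -pi / 2) orient <- orient + pi
  bh <- diff(range(rows)) + 1L
  bw <- diff(range(cols)) + 1L
  conv <- convex_area_pixels(rows, cols)
  filled <- filled_area_pixels(mask)
  perim <- crofton_perimeter(mask)
  c(
    area = as.numeric(n),
    major_axis_length = major,
    minor_axis_length = minor,
    eccentricity = ecc,
    orientation = orient,
    convex_area = as.numeric(conv),
    filled_area = as.numeric(filled),
    equivalent_diameter = sqrt(4 * n / pi),
    solidity = n / conv,
    extent = n / (as.numeric(bh) * bw),
    perimeter = perim,
    box_aspect_ratio = max(bh, bw) / min(bh, bw),
    compactness = min(1, 4 * pi * n / perim^2)
  )
}

#' Per-gland morphological features
#'
#' Computes the 13 shape descriptors of each labelled instance: area, major
#' and minor moment-ellipse axis lengths, eccentricity, orientation, convex
#' area, filled area, equivalent diameter, solidity, extent, perimeter
#' (Crofton 4-direction estimate), bounding-box aspect ratio, and
#' compactness (`4*pi*area/perimeter^2`, clamped to 1).
#'
#' Axes derive from the second central moments of the pixel set with the
#' usual pixel-as-unit-square correction, so a single pixel has positive
#' axis lengths. Orientation is the major-axis angle, counter-clockwise
#' from the x-axis (columns), in `(-pi/2, pi/2]`.
#'
#' @param labels Integer instance label matrix (0 = background).
#' @param ids Optional instance ids to measure; default all.
#' @return A tibble with one row per instance: `label` plus the 13 features
#'   in canonical order ([gland_feature_names()]).
#' @export
gland_features <- function(labels, ids = NULL) {
  assert_label_map(labels)
  present <- sort(unique(as.integer(labels[labels > 0])))
  if (is.null(ids)) {
    ids <- present
  } else {
    missing <- setdiff(ids, present)
    if (length(missing) > 0) {
      abort(sprintf(
        "Label(s) %s not present in the label map.",
        paste(missing, collapse = ", ")
      ))
    }
  }
  if (length(ids) == 0L) {
    out <- tibble(label = integer())
    for (f in GLAND_FEATURES) out[[f]] <- numeric()
    return(out)
  }
  sel_mat <- matrix(labels %in% ids, nrow(labels), ncol(labels))
  idx <- which(sel_mat, arr.ind = TRUE)
  lab_at <- labels[sel_mat]
  recs <- matrix(0, length(ids), length(GLAND_FEATURES),
                 dimnames = list(NULL, GLAND_FEATURES))
  for (i in seq_along(ids)) {
    sel <- lab_at == ids[[i]]
    rows <- idx[sel, 1L]
    cols <- idx[sel, 2L]
    r0 <- min(rows); c0 <- min(cols)
    sub <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    recs[i, ] <- compute_gland_record(rows, cols, sub)
  }
  dplyr::bind_cols(tibble(label = as.integer(ids)), as_tibble(recs))
}

# Moment statistics with fixed degenerate-case conventions:
# sample (n-1) std; bias-uncorrected moment skewness; excess (Fisher)
# kurtosis; n = 1 or zero variance -> std/skew/kurtosis = 0.
agg_stats <- function(v) {
  n <- length(v)
  m <- mean(v)
  if (n < 2L) {
    return(c(mean = m, median = m, std = 0, skewness = 0, kurtosis = 0, max = m))
  }
  s <- sd(v)
  m2 <- mean((v - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) {
    sk <- 0; ku <- 0
  } else {
    sk <- mean((v - m)^3) / m2^1.5
    ku <- mean((v - m)^4) / m2^2 - 3
  }
  c(mean = m, median = median(v), std = s, skewness = sk, kurtosis = ku,
    max = max(v))
}

#' Aggregate per-gland features into one patient-level vector
#'
#' Applies the six aggregation statistics (mean, median, standard
#' deviation, skewness, kurtosis, maximum) to each of the 13 features
#' across all glands of one patient, yielding the 78-column patient
#' descriptor. Std is the sample (n-1) estimate; skewness and excess
#' kurtosis are the bias-uncorrected moment estimators; a single gland or a
#' zero-variance feature yields 0 for std/skewness/kurtosis.
#'
#' @param features Tibble of per-gland features (as from
#'   [gland_features()]); extra columns such as `label` are ignored.
#' @param patient_id Identifier stored in the output row.
#' @return One-row tibble: `patient_id`, `n_glands`, then the 78 aggregate
#'   columns in the order of [patient_feature_names()].
#' @export
aggregate_patient <- function(features, patient_id = NA_character_) {
  if (nrow(features) == 0L) {
    abort("Cannot aggregate an empty gland feature table.")
  }
  missing <- setdiff(GLAND_FEATURES, names(features))
  if (length(missing) > 0) {
    abort(sprintf("Missing feature column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  vals <- unlist(lapply(GLAND_FEATURES, function(f) {
    s <- agg_stats(features[[f]])
    setNames(s, paste(f, names(s), sep = "_"))
  }))
  dplyr::bind_cols(
    tibble(patient_id = patient_id, n_glands = nrow(features)),
    as_tibble(as.list(vals))
  )
}

#' Aggregate a multi-patient gland feature table
#'
#' @param features Tibble with a `patient_id` column plus the 13 feature
#'   columns, one row per gland.
#' @return Tibble with one row per patient (see [aggregate_patient()]).
#' @export
aggregate_patients <- function(features) {
  if (!"patient_id" %in% names(features)) {
    abort("`features` must contain a `patient_id` column.")
  }
  features |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(~ aggregate_patient(.x, patient_id = .x$patient_id[[1]]))
}
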