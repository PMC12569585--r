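# Fusion of object/contour probability maps and mask cleanup.

#' Create a probability-map pair
#'
#' Container for the paired gland-object and gland-contour probability maps
#' emitted by the two-branch model.
#'
#' @param object_map,contour_map Numeric matrices in `[0, 1]`, same shape.
#' @return A `probability_pair` object.
#' @export
probability_pair <- function(object_map, contour_map) {
  assert_same_shape(object_map, contour_map, c("object_map", "contour_map"))
  if (min(object_map, contour_map) < 0 || max(object_map, contour_map) > 1) {
    abort("Probability maps must lie in [0, 1].")
  }
  structure(list(object_map = object_map, contour_map = contour_map),
            class = "probability_pair")
}

#' Fuse object and contour probability maps into a binary mask
#'
#' A pixel is foreground iff its object probability reaches
#' `object_threshold` AND its contour probability stays below
#' `contour_threshold`. Subtracting confident contour pixels is what cuts
#' touching glands apart before connected-component labelling.
#'
#' @param pair A [probability_pair()].
#' @param object_threshold,contour_threshold Thresholds in `(0, 1)`.
#' @return Logical matrix.
#' @export
fuse_probability_maps <- function(pair, object_threshold = 0.5,
                                  contour_threshold = 0.5) {
  stopifnot_scalar_number(object_threshold, "object_threshold", 0, 1)
  stopifnot_scalar_number(contour_threshold, "contour_threshold", 0, 1)
  pair$object_map >= object_threshold & pair$contour_map < contour_threshold
}

remove_small <- function(labels, min_area) {
  if (max(labels) == 0L) return(labels)
  sizes <- tabulate(labels[labels > 0L], nbins = max(labels))
  drop <- which(sizes < min_area)
  if (length(drop) > 0) labels[labels %in% drop] <- 0L
  labels
}

#' Clean a fused binary mask into an instance label map
#'
#' Cleanup pipeline applied after fusion: (1) remove 4-connected components
#' with area strictly below `min_area` (the 400-px rule — a component of
#' exactly `min_area` pixels is kept); (2) morphological closing then
#' opening with a disk structuring element of radius `smooth_radius`;
#' (3) fill holes per component; (4) re-apply the minimum-area rule and
#' relabel. The closing-then-opening pair is an idempotent morphological
#' filter, which keeps repeated cleanup stable.
#'
#' @param mask Logical or 0/1 matrix (e.g. from [fuse_probability_maps()]).
#' @param min_area Minimum instance area in pixels (default 400).
#' @param smooth_radius Disk radius in pixels for smoothing (default 3).
#' @return Integer instance label map with consecutive labels.
#' @export
clean_mask <- function(mask, min_area = 400, smooth_radius = 3) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  stopifnot_scalar_number(min_area, "min_area", 0)
  m <- label_instances(mask)
  m <- remove_small(m, min_area)
  b <- matrix(as.numeric(m > 0L), nrow(m), ncol(m))
  if (smooth_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(smooth_radius) + 1L, "disc")
    b <- EBImage::closing(b, brush)
    b <- EBImage::opening(b, brush)
  }
  lab <- label_instances(b > 0)
  if (max(lab) > 0L) {
    filled <- EBImage::fillHull(lab)
    lab <- matrix(as.integer(filled), nrow(lab), ncol(lab))
  }
  lab <- remove_small(lab, min_area)
  relabel_consecutive(lab)
}

#' Grow labelled cores back into the object mask
#'
#' Fusing subtracts the contour band, so cleaned instances are eroded
#' cores. This step re-expands each label into the plain object mask by
#' iterative 4-neighbour region growing (ties to the lower label), which
#' restores full gland extent while keeping touching instances separate --
#' the standard completion of contour-aware instance segmentation.
#'
#' @param labels Cleaned integer label map (cores).
#' @param mask Logical object mask to grow into (e.g. `object_map >=
#'   object_threshold`).
#' @param iterations Maximum growth steps (default 10; growth also stops
#'   when no pixel changes).
#' @return Integer label map covering `mask` pixels reachable from cores.
#' @export
grow_labels <- function(labels, mask, iterations = 10) {
  assert_label_map(labels)
  assert_same_shape(labels, mask, c("labels", "mask"))
  lab <- labels
  lab[!mask & lab == 0L] <- 0L
  nr <- nrow(lab); nc <- ncol(lab)
  for (it in seq_len(iterations)) {
    free <- mask & lab == 0L
    if (!any(free)) break
    # lowest neighbouring label in the four cardinal directions (0 = none)
    shift <- function(fill) matrix(Inf, nr, nc)
    up <- shift(); up[-nr, ] <- lab[-1L, ]
    dn <- shift(); dn[-1L, ] <- lab[-nr, ]
    lf <- shift(); lf[, -nc] <- lab[, -1L]
    rt <- shift(); rt[, -1L] <- lab[, -nc]
    up[up == 0] <- Inf; dn[dn == 0] <- Inf
    lf[lf == 0] <- Inf; rt[rt == 0] <- Inf
    best <- pmin(up, dn, lf, rt)
    best[!is.finite(best)] <- 0
    newly <- free & best > 0L
    if (!any(newly)) break
    lab[newly] <- as.integer(best[newly])
  }
  lab
}

#' Instance segmentation from a probability pair
#'
#' The full post-processing chain: fuse object and contour maps, clean
#' (minimum area, disk smoothing, hole filling), then grow the separated
#' cores back into the thresholded object mask and re-apply the
#' minimum-area rule.
#'
#' When cores are regrown, the minimum-area rule binds the FINAL grown
#' instances; the pre-grow cleanup uses a reduced floor (`min_area *
#' core_fraction`) because subtracting the contour band erodes every core.
#'
#' @param pair A [probability_pair()].
#' @param object_threshold,contour_threshold Fusion thresholds.
#' @param min_area,smooth_radius See [clean_mask()].
#' @param grow Re-expand cores into the object mask (default `TRUE`).
#' @param core_fraction Fraction of `min_area` required of a core before
#'   growth (default 0.25; ignored when `grow = FALSE`).
#' @return Integer instance label map.
#' @export
segment_probability_pair <- function(pair, object_threshold = 0.5,
                                     contour_threshold = 0.5,
                                     min_area = 400, smooth_radius = 3,
                                     grow = TRUE, core_fraction = 0.25) {
  fused <- fuse_probability_maps(pair, object_threshold, contour_threshold)
  core_min <- if (grow) max(1, ceiling(min_area * core_fraction)) else min_area
  lab <- clean_mask(fused, min_area = core_min, smooth_radius = smooth_radius)
  if (grow && max(lab) > 0L) {
    lab <- grow_labels(lab, pair$object_map >= object_threshold)
  }
  lab <- remove_small(lab, min_area)
  relabel_consecutive(lab)
}
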