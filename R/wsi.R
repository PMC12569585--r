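# Tiled whole-image inference: tissue masking, tile planning at the
# working (20x) magnification, per-tile normalize/predict/fuse/clean, and
# seam-aware stitching into one instance map.

rgb_saturation <- function(image) {
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  s <- (mx - mn) / pmax(mx, 1)
  s
}

#' Tissue mask of an RGB thumbnail
#'
#' Otsu threshold on the saturation channel followed by morphological
#' closing. Near-uniform images short-circuit: uniformly tinted images are
#' all tissue, uniformly pale images contain none (with a warning).
#'
#' @param image `H x W x 3` RGB array in `[0, 255]` (at least 64 px a side).
#' @return Logical matrix; attribute `fraction` carries the mask fraction.
#' @export
tissue_mask <- function(image) {
  d <- dim(image)
  if (d[1] < 64 || d[2] < 64) abort("Thumbnail must be at least 64 px a side.")
  s <- rgb_saturation(image)
  if (sd(s) < 0.02) {
    mask <- matrix(mean(s) > 0.15, d[1], d[2])
    if (!any(mask)) warn("No tissue found (uniform pale image).")
  } else {
    thr <- EBImage::otsu(EBImage::Image(s), range = c(0, 1))
    # Otsu on an all-tissue image splits tissue against itself; if the
    # "background" class is still clearly stained, call everything tissue.
    if (mean(s[s <= thr]) > 0.15) thr <- -1
    mask <- s > thr
    mask <- EBImage::closing(
      matrix(as.numeric(mask), d[1], d[2]), EBImage::makeBrush(5, "disc")
    ) > 0
    if (!any(mask)) warn("No tissue found.")
  }
  attr(mask, "fraction") <- mean(mask)
  mask
}

#' Plan non-overlapping inference tiles
#'
#' Lays a sliding-window grid of non-overlapping tiles over the working
#' image. Coordinates are 0-based, (x right, y down), half-open, recorded
#' at the working (20x) magnification: when the base magnification is 40x
#' the working image is the 2x-downsampled one. Edge tiles are clipped to
#' the image bounds. Tiles whose tissue fraction falls below
#' `min_tissue_fraction` are excluded.
#'
#' @param dims `c(height, width)` of the image at base magnification.
#' @param base_magnification 20 or 40.
#' @param tile_size Tile side in pixels at working magnification.
#' @param tissue Optional logical tissue mask at working magnification.
#' @param min_tissue_fraction Minimum tile tissue fraction (default 0.05).
#' @return Tibble `x`, `y`, `w`, `h`, `tissue_fraction`, with attributes
#'   `downsample_factor` and `working_dims`.
#' @export
plan_tiles <- function(dims, base_magnification = 20, tile_size = 500,
                       tissue = NULL, min_tissue_fraction = 0.05) {
  if (!base_magnification %in% c(20, 40)) {
    abort("`base_magnification` must be 20 or 40.")
  }
  ds <- if (base_magnification == 40) 2L else 1L
  wd <- floor(dims / ds)
  if (any(wd < tile_size)) {
    abort(sprintf(
      "Working image (%s) is smaller than the %d-px tile.",
      paste(wd, collapse = "x"), tile_size
    ))
  }
  ys <- seq(0L, wd[1] - 1L, by = tile_size)
  xs <- seq(0L, wd[2] - 1L, by = tile_size)
  grid <- expand.grid(y = ys, x = xs)
  tiles <- tibble(
    x = as.integer(grid$x), y = as.integer(grid$y),
    w = pmin(as.integer(tile_size), wd[2] - as.integer(grid$x)),
    h = pmin(as.integer(tile_size), wd[1] - as.integer(grid$y))
  )
  tiles$tissue_fraction <- if (is.null(tissue)) {
    rep(1, nrow(tiles))
  } else {
    vapply(seq_len(nrow(tiles)), function(i) {
      mean(tissue[(tiles$y[i] + 1L):(tiles$y[i] + tiles$h[i]),
                  (tiles$x[i] + 1L):(tiles$x[i] + tiles$w[i])])
    }, numeric(1))
  }
  tiles <- tiles[tiles$tissue_fraction >= min_tissue_fraction, , drop = FALSE]
  attr(tiles, "downsample_factor") <- ds
  attr(tiles, "working_dims") <- wd
  tiles
}

downsample2 <- function(image) {
  d <- dim(image)
  h <- floor(d[1] / 2) * 2L; w <- floor(d[2] / 2) * 2L
  img <- image[seq_len(h), seq_len(w), , drop = FALSE]
  out <- array(0, c(h / 2, w / 2, d[3]))
  for (c in seq_len(d[3])) {
    m <- img[, , c]
    out[, , c] <- (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
                   m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)]) / 4
  }
  out
}

# Union-find with path compression.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Merge labels adjacent across tile seams; returns the relabelled map.
merge_across_seams <- function(labels, tiles) {
  k <- max(labels)
  if (k == 0L) return(labels)
  parent <- seq_len(k)
  link <- function(a, b) {
    ra <- uf_find(parent, a); rb <- uf_find(parent, b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  seam_cols <- setdiff(unique(tiles$x), 0L)
  seam_rows <- setdiff(unique(tiles$y), 0L)
  for (cx in seam_cols) {
    a <- labels[, cx]; b <- labels[, cx + 1L]
    sel <- a > 0L & b > 0L & a != b
    for (i in which(sel)) link(a[i], b[i])
  }
  for (ry in seam_rows) {
    a <- labels[ry, ]; b <- labels[ry + 1L, ]
    sel <- a > 0L & b > 0L & a != b
    for (i in which(sel)) link(a[i], b[i])
  }
  roots <- vapply(seq_len(k), function(i) uf_find(parent, i), integer(1))
  out <- labels
  out[labels > 0L] <- roots[labels[labels > 0L]]
  relabel_consecutive(out)
}

#' Segment a whole image by tiled inference
#'
#' Runs the full inference pipeline of the study: build a tissue mask,
#' plan non-overlapping tiles at 20x (downsampling by 2 when the input is
#' 40x), then per tile stain-normalize to the training target, predict the
#' object/contour probability pair, fuse, and clean. Tile results are
#' stitched with global renumbering; instances whose pixels are adjacent
#' across a tile seam are merged into one, and the minimum-area rule is
#' re-applied to the stitched map. A failing tile is recorded in the run
#' log and skipped, not fatal.
#'
#' @param image `H x W x 3` RGB array at base magnification.
#' @param model A trained [build_model()] (dcan).
#' @param stain_target Optional [stain_profile()]; when given, every tile
#'   is normalized to it before prediction.
#' @param base_magnification 20 or 40.
#' @param tile_size Tile side at working magnification (default 500).
#' @param batch_size Tiles per inference batch (default 8; grouping only,
#'   results are independent of it).
#' @param object_threshold,contour_threshold Fusion thresholds.
#' @param min_area,smooth_radius Cleanup parameters (see [clean_mask()]).
#' @param min_tissue_fraction Tile inclusion threshold.
#' @param tile_order Optional permutation of tile indices (processing
#'   order; the stitched result is independent of it).
#' @return A `wsi_segmentation`: list with `labels` (instance map at
#'   working magnification), `instances` (tibble label/centroid/area),
#'   `tiles`, and `log` (config echo, per-tile failures, tissue fraction).
#' @export
segment_image <- function(image, model, stain_target = NULL,
                          base_magnification = 20, tile_size = 500,
                          batch_size = 8,
                          object_threshold = 0.5, contour_threshold = 0.5,
                          min_area = 400, smooth_radius = 3,
                          min_tissue_fraction = 0.05, tile_order = NULL) {
  if (base_magnification == 40) image <- downsample2(image)
  d <- dim(image)
  tissue <- tissue_mask(image)
  labels <- matrix(0L, d[1], d[2])
  tiles <- tryCatch(
    plan_tiles(d[1:2], base_magnification = 20, tile_size = tile_size,
               tissue = tissue, min_tissue_fraction = min_tissue_fraction),
    error = function(e) NULL
  )
  failures <- list()
  if (!is.null(tiles) && nrow(tiles) > 0) {
    ord <- tile_order %||% seq_len(nrow(tiles))
    next_label <- 0L
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (batch in batches) {
      for (ti in batch) {
        res <- tryCatch({
          rows <- (tiles$y[ti] + 1L):(tiles$y[ti] + tiles$h[ti])
          cols <- (tiles$x[ti] + 1L):(tiles$x[ti] + tiles$w[ti])
          patch <- image[rows, cols, , drop = FALSE]
          if (!is.null(stain_target)) {
            patch <- tryCatch(stain_normalize(patch, stain_target),
                              error = function(e) patch)
          }
          pair <- predict_probs(model, patch)
          lab <- segment_probability_pair(
            pair, object_threshold = object_threshold,
            contour_threshold = contour_threshold,
            min_area = min_area, smooth_radius = smooth_radius
          )
          list(rows = rows, cols = cols, lab = lab)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            list(tile = ti, message = conditionMessage(res))
          next
        }
        if (max(res$lab) > 0L) {
          sub <- labels[res$rows, res$cols]
          sel <- res$lab > 0L
          sub[sel] <- res$lab[sel] + next_label
          labels[res$rows, res$cols] <- sub
          next_label <- next_label + max(res$lab)
        }
      }
    }
    labels <- merge_across_seams(labels, tiles)
    labels <- remove_small(labels, min_area)
    labels <- relabel_consecutive(labels)
  }
  instances <- if (max(labels) > 0L) {
    idx <- which(labels > 0L, arr.ind = TRUE)
    tibble(label = labels[labels > 0L], row = idx[, 1L], col = idx[, 2L]) |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(centroid_row = mean(.data$row),
                       centroid_col = mean(.data$col),
                       area = dplyr::n(), .groups = "drop")
  } else {
    tibble(label = integer(), centroid_row = numeric(),
           centroid_col = numeric(), area = integer())
  }
  structure(
    list(labels = labels, instances = instances, tiles = tiles,
         log = list(
           base_magnification = base_magnification,
           tile_size = tile_size, batch_size = batch_size,
           object_threshold = object_threshold,
           contour_threshold = contour_threshold,
           min_area = min_area, smooth_radius = smooth_radius,
           tissue_fraction = attr(tissue, "fraction"),
           stain_hash = if (!is.null(stain_target))
             stain_profile_hash(stain_target) else NA_character_,
           failures = failures
         )),
    class = "wsi_segmentation"
  )
}

#' @export
print.wsi_segmentation <- function(x, ...) {
  cat(sprintf(
    "whole-image segmentation: %dx%d px, %d instances, %d tiles, %d failures\n",
    ncol(x$labels), nrow(x$labels), nrow(x$instances),
    if (is.null(x$tiles)) 0L else nrow(x$tiles), length(x$log$failures)
  ))
  invisible(x)
}

#' Write the run log of a whole-image segmentation as JSON
#' @param seg A [segment_image()] result.
#' @param path Output path.
#' @export
write_run_log <- function(seg, path) {
  jsonlite::write_json(seg$log, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
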