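#' Label connected foreground components
#'
#' Labels the foreground (non-zero) pixels of a binary mask into
#' 4-connected components, numbered consecutively `1..K` in raster-scan
#' order of their first pixel. 4-connectivity keeps diagonally touching
#' blobs separate, which is the behaviour the contour-based instance
#' separation relies on.
#'
#' @param mask A logical or 0/1 numeric matrix.
#' @return An integer matrix of the same shape; 0 is background.
#' @export
label_instances <- function(mask) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
  relabel_consecutive(matrix(as.integer(lab), nrow(mask), ncol(mask)))
}

# Renumber labels to consecutive 1..K in raster-scan (column-major) order of
# first occurrence; 0 stays background.
relabel_consecutive <- function(labels) {
  v <- as.integer(labels)
  ids <- unique(v[v > 0L])
  if (length(ids) == 0L) {
    return(matrix(0L, nrow(labels), ncol(labels)))
  }
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out <- v
  out[v > 0L] <- lut[v[v > 0L]]
  matrix(out, nrow(labels), ncol(labels))
}

# Pixels of `mask` that are 4-adjacent to background (or the image border).
boundary_mask <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  m & !inner
}

# Coordinates (row, col) of boundary pixels of one labelled object.
boundary_points <- function(labels, id) {
  which(boundary_mask(labels == id), arr.ind = TRUE)
}

#' Write an instance label map as a 16-bit PNG
#'
#' Labels (up to 65535) are stored losslessly in a standard RGB PNG with
#' the high byte in the red channel and the low byte in the green channel.
#'
#' @param labels Integer label matrix (0 background, values < 65536).
#' @param path Output file path.
#' @export
write_label_png <- function(labels, path) {
  assert_label_map(labels)
  if (max(labels) > 65535) abort("Label values exceed 16-bit PNG range.")
  v <- as.integer(labels)
  img <- array(0, c(nrow(labels), ncol(labels), 3L))
  img[, , 1] <- (v %/% 256L) / 255
  img[, , 2] <- (v %% 256L) / 255
  png::writePNG(img, target = path)
  invisible(path)
}

#' Read an instance label map written by [write_label_png()]
#'
#' @param path PNG file path.
#' @return Integer label matrix.
#' @export
read_label_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    return(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)))
  }
  hi <- round(img[, , 1] * 255)
  lo <- round(img[, , 2] * 255)
  matrix(as.integer(hi * 256 + lo), nrow(img), ncol(img))
}

#' Write an RGB image as an 8-bit PNG
#'
#' @param image `H x W x 3` array with values in `[0, 255]`.
#' @param path Output file path.
#' @export
write_rgb_png <- function(image, path) {
  stopifnot(length(dim(image)) == 3L)
  png::writePNG(clamp(image, 0, 255) / 255, target = path)
  invisible(path)
}

#' Read an 8-bit RGB PNG into a `[0, 255]` array
#'
#' @param path PNG file path.
#' @return `H x W x 3` numeric array with values in `[0, 255]`.
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  round(img[, , 1:3, drop = FALSE] * 255)
}
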