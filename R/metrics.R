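# Object-level segmentation evaluation: detection F1, object Dice and
# object Hausdorff, following the GlaS-challenge conventions.

# Overlap (pixel-count) table between two label maps as a dense matrix
# [truth x pred]; rows/cols indexed by label id.
overlap_table <- function(pred, truth) {
  kp <- max(pred); kt <- max(truth)
  O <- matrix(0, nrow = kt, ncol = kp)
  sel <- pred > 0L & truth > 0L
  if (any(sel)) {
    tab <- table(truth = truth[sel], pred = pred[sel])
    O[cbind(
      as.integer(rownames(tab))[row(tab)],
      as.integer(colnames(tab))[col(tab)]
    )] <- as.numeric(tab)
  }
  O
}

label_areas <- function(labels) {
  if (max(labels) == 0L) return(numeric(0))
  tabulate(labels[labels > 0L], nbins = max(labels))
}

#' Match predicted gland objects to ground truth
#'
#' A predicted object is a true positive iff it covers strictly more than
#' 50% of the area of some ground-truth object; each ground-truth object
#' can be claimed at most once. Candidate pairs are matched greedily by
#' decreasing overlap, ties broken by lower truth label then lower
#' predicted label, so results are deterministic.
#'
#' @param pred,truth Integer instance label maps of the same shape.
#' @return List with `matches` (tibble `truth`, `pred`, `overlap`), counts
#'   `tp`, `fp`, `fn`, and the detection `f1`.
#' @export
match_gland_objects <- function(pred, truth) {
  assert_label_map(pred, "pred"); assert_label_map(truth, "truth")
  assert_same_shape(pred, truth)
  kp <- max(pred); kt <- max(truth)
  if (kp == 0L || kt == 0L) {
    f1 <- if (kp == 0L && kt == 0L) 1 else 0
    return(list(
      matches = tibble(truth = integer(), pred = integer(), overlap = numeric()),
      tp = 0L, fp = as.integer(kp), fn = as.integer(kt), f1 = f1
    ))
  }
  O <- overlap_table(pred, truth)
  at <- label_areas(truth)
  cand <- which(O > 0.5 * at[row(O)], arr.ind = TRUE)
  matches <- tibble(truth = integer(), pred = integer(), overlap = numeric())
  if (nrow(cand) > 0) {
    ov <- O[cand]
    ord <- order(-ov, cand[, 1L], cand[, 2L])
    used_t <- logical(kt); used_p <- logical(kp)
    keep_t <- integer(); keep_p <- integer(); keep_o <- numeric()
    for (r in ord) {
      ti <- cand[r, 1L]; pj <- cand[r, 2L]
      if (!used_t[ti] && !used_p[pj]) {
        used_t[ti] <- TRUE; used_p[pj] <- TRUE
        keep_t <- c(keep_t, ti); keep_p <- c(keep_p, pj)
        keep_o <- c(keep_o, O[ti, pj])
      }
    }
    matches <- tibble(truth = keep_t, pred = keep_p, overlap = keep_o)
  }
  tp <- nrow(matches); fp <- kp - tp; fn <- kt - tp
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  list(matches = matches, tp = as.integer(tp), fp = as.integer(fp),
       fn = as.integer(fn), f1 = f1)
}

dice_pair <- function(a_area, b_area, overlap) {
  if (a_area + b_area == 0) return(1)
  2 * overlap / (a_area + b_area)
}

#' Object-level Dice index
#'
#' The GlaS object Dice: each ground-truth object is paired with its
#' largest-overlap predicted object (and vice versa); per-object Dice
#' values are averaged with area-proportional weights in both directions
#' and the two directions averaged. Objects with no overlap partner
#' contribute 0. Two empty maps score 1 (perfect agreement on emptiness);
#' one empty map scores 0.
#'
#' @param pred,truth Integer instance label maps of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
object_dice <- function(pred, truth) {
  assert_label_map(pred, "pred"); assert_label_map(truth, "truth")
  assert_same_shape(pred, truth)
  kp <- max(pred); kt <- max(truth)
  if (kp == 0L && kt == 0L) return(1)
  if (kp == 0L || kt == 0L) return(0)
  O <- overlap_table(pred, truth)
  at <- label_areas(truth); ap <- label_areas(pred)
  # truth direction
  d_t <- vapply(seq_len(kt), function(i) {
    j <- which.max(O[i, ])
    if (O[i, j] == 0) 0 else dice_pair(at[i], ap[j], O[i, j])
  }, numeric(1))
  # prediction direction
  d_p <- vapply(seq_len(kp), function(j) {
    i <- which.max(O[, j])
    if (O[i, j] == 0) 0 else dice_pair(ap[j], at[i], O[i, j])
  }, numeric(1))
  0.5 * (sum(at / sum(at) * d_t) + sum(ap / sum(ap) * d_p))
}

# Hausdorff distance between two boundary point sets (row/col matrices).
hausdorff_points <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  sqrt(max(max(apply(d2, 1L, min)), max(apply(d2, 2L, min))))
}

#' Object-level Hausdorff distance
#'
#' Area-weighted symmetric average of per-object-pair Hausdorff distances
#' between boundary point sets (pixels 4-adjacent to non-object), with the
#' same best-overlap pairing as [object_dice()]. Objects without an
#' overlap partner are paired with the nearest object (smallest Hausdorff
#' distance) of the other map. If one map has no objects at all, every
#' object of the other map is assigned the image-diagonal length as a
#' penalty distance.
#'
#' @param pred,truth Integer instance label maps of the same shape.
#' @return Non-negative scalar, in pixels.
#' @export
object_hausdorff <- function(pred, truth) {
  assert_label_map(pred, "pred"); assert_label_map(truth, "truth")
  assert_same_shape(pred, truth)
  kp <- max(pred); kt <- max(truth)
  if (kp == 0L && kt == 0L) return(0)
  diag_len <- sqrt(sum(dim(truth)^2))
  at <- label_areas(truth); ap <- label_areas(pred)
  if (kp == 0L || kt == 0L) return(diag_len)
  O <- overlap_table(pred, truth)
  bt <- lapply(seq_len(kt), function(i) boundary_points(truth, i))
  bp <- lapply(seq_len(kp), function(j) boundary_points(pred, j))
  pair_h <- function(i, j) hausdorff_points(bt[[i]], bp[[j]])
  nearest_h <- function(bnd, others) {
    min(vapply(others, function(o) hausdorff_points(bnd, o), numeric(1)))
  }
  h_t <- vapply(seq_len(kt), function(i) {
    j <- which.max(O[i, ])
    if (O[i, j] > 0) pair_h(i, j) else nearest_h(bt[[i]], bp)
  }, numeric(1))
  h_p <- vapply(seq_len(kp), function(j) {
    i <- which.max(O[, j])
    if (O[i, j] > 0) pair_h(i, j) else nearest_h(bp[[j]], bt)
  }, numeric(1))
  0.5 * (sum(at / sum(at) * h_t) + sum(ap / sum(ap) * h_p))
}

#' Full object-level segmentation score
#'
#' @param pred,truth Integer instance label maps of the same shape.
#' @return One-row tibble: `f1`, `object_dice`, `object_hausdorff`, `tp`,
#'   `fp`, `fn`.
#' @export
segmentation_score <- function(pred, truth) {
  m <- match_gland_objects(pred, truth)
  tibble(
    f1 = m$f1,
    object_dice = object_dice(pred, truth),
    object_hausdorff = object_hausdorff(pred, truth),
    tp = m$tp, fp = m$fp, fn = m$fn
  )
}
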