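# Training: contour targets, augmentation, the deep-supervision loss and
# the SGD loop.

#' Training configuration
#'
#' Defaults follow the full-scale recipe: SGD with initial learning rate
#' 1e-4 and batch size 4, 500-px patch extraction with a random 480-px
#' crop, rotations from \{0, 90, 180, 270\} degrees and horizontal flips
#' with probability 0.5, auxiliary deep-supervision losses discounted
#' linearly to zero over the first half of training. Desk-scale runs
#' typically raise the learning rate and add momentum (the optimizer is
#' still plain SGD when `momentum = 0`).
#'
#' @param learning_rate Positive SGD step size.
#' @param batch_size Samples per gradient update.
#' @param epochs Training epochs.
#' @param patch_size Extraction patch size in pixels.
#' @param crop_size Random-crop size (must not exceed `patch_size`).
#' @param hflip_probability Horizontal-flip probability.
#' @param contour_thickness Contour-target dilation radius in pixels.
#' @param aux_discount_schedule Function `(epoch, epochs) -> weight in
#'   [0,1]`, non-increasing in epoch.
#' @param momentum SGD momentum coefficient (0 = plain SGD).
#' @param grad_clip Per-layer gradient norm cap applied before the update
#'   (stabilizes the normalization-free nets; `Inf` disables).
#' @param seed Integer seed governing shuffling and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4, epochs = 78,
                         patch_size = 500, crop_size = 480,
                         hflip_probability = 0.5, contour_thickness = 2,
                         aux_discount_schedule = aux_linear_decay,
                         momentum = 0, grad_clip = 1, seed = 1) {
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.")
  if (crop_size > patch_size) abort("`crop_size` cannot exceed `patch_size`.")
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), patch_size = as.integer(patch_size),
         crop_size = as.integer(crop_size),
         rotation_set = c(0L, 90L, 180L, 270L),
         hflip_probability = hflip_probability,
         contour_thickness = as.integer(contour_thickness),
         aux_discount_schedule = aux_discount_schedule,
         momentum = momentum, grad_clip = grad_clip,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Linear auxiliary-loss decay
#'
#' Deep-supervision weight: 1 at epoch 1, decaying linearly to 0 over the
#' first half of training, 0 afterwards.
#'
#' @param epoch Current epoch (1-based).
#' @param epochs Total epochs.
#' @return Weight in `[0, 1]`.
#' @export
aux_linear_decay <- function(epoch, epochs) {
  half <- max(1, floor(epochs / 2))
  max(0, 1 - (epoch - 1) / half)
}

#' Build a gland-contour target from instance ground truth
#'
#' Extracts each instance's boundary (pixels 4-adjacent to anything that is
#' not the instance -- background or a neighbouring gland), unions them and
#' dilates with a disk of radius `thickness`. Because boundaries between
#' touching instances are included, removing contour pixels from the
#' object target always separates touching glands.
#'
#' @param truth Integer instance label matrix.
#' @param thickness Dilation radius in pixels (`>= 1`).
#' @return Logical contour mask.
#' @export
contour_target <- function(truth, thickness = 2) {
  assert_label_map(truth, "truth")
  if (thickness < 1) abort("`thickness` must be >= 1.")
  k <- max(truth)
  if (k == 0L) return(matrix(FALSE, nrow(truth), ncol(truth)))
  bnd <- matrix(FALSE, nrow(truth), ncol(truth))
  for (id in seq_len(k)) {
    if (!any(truth == id)) next
    bnd <- bnd | boundary_mask(truth == id)
  }
  t <- as.integer(thickness)
  off <- -t:t
  brush <- outer(off, off, function(a, b) as.numeric(a^2 + b^2 <= t^2))
  EBImage::dilate(matrix(as.numeric(bnd), nrow(bnd), ncol(bnd)), brush) > 0
}

rotate_ccw_mat <- function(m) {
  r <- t(m)
  r[rev(seq_len(nrow(r))), , drop = FALSE]
}

apply_geom <- function(x, k_rot, flip, crop = NULL) {
  is_arr <- length(dim(x)) == 3L
  one <- function(m) {
    if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (k_rot > 0) for (i in seq_len(k_rot)) m <- rotate_ccw_mat(m)
    if (!is.null(crop)) {
      m <- m[crop[1]:(crop[1] + crop[3] - 1L),
             crop[2]:(crop[2] + crop[3] - 1L), drop = FALSE]
    }
    m
  }
  if (is_arr) {
    slices <- lapply(seq_len(dim(x)[3]), function(c) one(x[, , c]))
    out <- array(0, c(dim(slices[[1]]), length(slices)))
    for (c in seq_along(slices)) out[, , c] <- slices[[c]]
    out
  } else {
    one(x)
  }
}

#' Jointly augment an image and its targets
#'
#' Applies one geometric transform -- a rotation drawn uniformly from
#' \{0, 90, 180, 270\} degrees, a horizontal flip with the configured
#' probability, and a random square crop -- identically to the image, the
#' object target and the contour target. Deterministic per `seed`.
#'
#' @param image `H x W x 3` array.
#' @param object_target,contour_target Matrices of the same spatial shape.
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @return List `image`, `object_target`, `contour_target`, with the drawn
#'   `rotation`, `flip` and crop `offset` attached as attributes.
#' @export
augment_sample <- function(image, object_target, contour_target, config,
                           seed = 1) {
  d <- dim(image)
  assert_same_shape(object_target, contour_target,
                    c("object_target", "contour_target"))
  if (d[1] != nrow(object_target) || d[2] != ncol(object_target)) {
    abort("Targets must match the image's spatial shape.")
  }
  cs <- min(config$crop_size, d[1], d[2])
  if (config$crop_size > min(d[1], d[2])) {
    abort(sprintf("Input (%dx%d) is smaller than the %d-px crop.",
                  d[1], d[2], config$crop_size))
  }
  with_seed(derive_seed(seed, 23L), {
    k_rot <- sample(0:3, 1L)
    flip <- runif(1) < config$hflip_probability
    # crop window chosen on the rotated/flipped canvas
    rd <- if (k_rot %% 2L == 1L) c(d[2], d[1]) else c(d[1], d[2])
    top <- if (rd[1] > cs) sample.int(rd[1] - cs + 1L, 1L) else 1L
    left <- if (rd[2] > cs) sample.int(rd[2] - cs + 1L, 1L) else 1L
    crop <- c(top, left, cs)
    out <- list(
      image = apply_geom(image, k_rot, flip, crop),
      object_target = apply_geom(object_target, k_rot, flip, crop),
      contour_target = apply_geom(contour_target, k_rot, flip, crop)
    )
    attr(out, "rotation") <- 90L * k_rot
    attr(out, "flip") <- flip
    attr(out, "offset") <- crop[1:2]
    out
  })
}

# Binary cross-entropy of a probability map vs a 0/1 target (mean/pixel).
bce_prob <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Deep-supervision loss of the two-branch model
#'
#' `CE(object) + CE(contour) + aux_weight * sum over auxiliary levels of
#' [CE_aux(object) + CE_aux(contour)]`, each CE the mean per-pixel binary
#' cross-entropy of the branch's probability map against its binary
#' target.
#'
#' @param main A [probability_pair()] (the fused full-resolution outputs).
#' @param aux List of [probability_pair()]s (per-level outputs); may be
#'   empty.
#' @param object_target,contour_target Binary matrices.
#' @param aux_weight Deep-supervision discount weight in `[0, 1]` (from
#'   [aux_linear_decay()] at the current epoch).
#' @return Non-negative scalar loss.
#' @export
dcan_loss <- function(main, aux, object_target, contour_target,
                      aux_weight = 0) {
  assert_same_shape(main$object_map, object_target,
                    c("object_map", "object_target"))
  assert_same_shape(main$contour_map, contour_target,
                    c("contour_map", "contour_target"))
  obj <- as.numeric(object_target != 0)
  con <- as.numeric(contour_target != 0)
  loss <- bce_prob(as.numeric(main$object_map), obj) +
    bce_prob(as.numeric(main$contour_map), con)
  if (aux_weight > 0 && length(aux) > 0) {
    for (a in aux) {
      loss <- loss + aux_weight * (
        bce_prob(as.numeric(a$object_map), obj) +
          bce_prob(as.numeric(a$contour_map), con)
      )
    }
  }
  loss
}

#' Extract overlapping training patches from an image/truth pair
#'
#' @param image `H x W x 3` array.
#' @param truth Instance label matrix.
#' @param size Patch size in pixels (default 500).
#' @param stride Step between patch origins (default `size / 2`,
#'   i.e. 50% overlap).
#' @return List of `list(image, truth)` patches covering the image.
#' @export
extract_patches <- function(image, truth, size = 500, stride = size / 2) {
  d <- dim(image)
  if (d[1] < size || d[2] < size) {
    return(list(list(image = image, truth = truth)))
  }
  starts <- function(n) {
    last <- n - size + 1L
    s <- seq(1L, last, by = as.integer(stride))
    if (tail(s, 1L) != last) s <- c(s, last)
    s
  }
  out <- list()
  for (i in starts(d[1])) {
    for (j in starts(d[2])) {
      out[[length(out) + 1L]] <- list(
        image = image[i:(i + size - 1L), j:(j + size - 1L), , drop = FALSE],
        truth = truth[i:(i + size - 1L), j:(j + size - 1L)]
      )
    }
  }
  out
}

# softmax cross-entropy gradient wrt 2-channel logits, mean-per-pixel
softmax_ce_grad <- function(logits, target) {
  p_fg <- softmax2(logits)
  n <- length(target)
  g <- array(0, dim(logits))
  g[, , 2L] <- (p_fg - target) / n
  g[, , 1L] <- -g[, , 2L]
  g
}

softmax_ce_loss <- function(logits, target) {
  p_fg <- softmax2(logits)
  bce_prob(as.numeric(p_fg), as.numeric(target))
}

#' Train a gland segmentation model
#'
#' Minibatch SGD on the cross-entropy objective -- both branches plus
#' discounted deep supervision for the two-branch model, object branch
#' only for U-Net. Shuffling and augmentation draws derive from the
#' config seed, so the whole trajectory is reproducible.
#'
#' @param model A [build_model()] result.
#' @param samples List of `gland_sample`s or `list(image, truth)` pairs,
#'   already stain-normalized to the shared target.
#' @param config A [train_config()].
#' @return The model with updated weights, per-epoch mean loss in
#'   `$history`, and the config stored in `$config`.
#' @export
train_model <- function(model, samples, config = train_config()) {
  if (length(samples) == 0) abort("Training requires a non-empty dataset.")
  prepped <- lapply(samples, function(s) {
    truth <- s$truth
    list(
      x = prepare_input(s$image),
      obj = matrix(as.numeric(truth > 0), nrow(truth), ncol(truth)),
      con = matrix(as.numeric(contour_target(truth, config$contour_thickness)),
                   nrow(truth), ncol(truth))
    )
  })
  vel <- lapply(model$params, function(l) list(w = l$w * 0, b = l$b * 0))
  history <- numeric(config$epochs)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    w_aux <- config$aux_discount_schedule(epoch, config$epochs)
    ord <- with_seed(derive_seed(config$seed, 7000L + epoch),
                     sample(length(prepped)))
    losses <- numeric(0)
    batch_grads <- NULL
    n_in_batch <- 0L
    for (si in ord) {
      step <- step + 1L
      s <- prepped[[si]]
      aug <- augment_sample(s$x, s$obj, s$con, config,
                            seed = derive_seed(config$seed, 100000L + step))
      x <- as_cube(aug$image)
      fw <- model_forward(model, x)
      if (model$kind == "dcan") {
        loss <- softmax_ce_loss(fw$main$object, aug$object_target) +
          softmax_ce_loss(fw$main$contour, aug$contour_target)
        g_main <- list(
          object = softmax_ce_grad(fw$main$object, aug$object_target),
          contour = softmax_ce_grad(fw$main$contour, aug$contour_target)
        )
        g_levels <- list()
        for (br in c("object", "contour")) {
          tgt <- if (br == "object") aug$object_target else aug$contour_target
          for (l in 2:4) {
            nm <- sprintf("s%d_%s", l, br)
            g <- g_main[[br]]
            if (w_aux > 0) {
              loss <- loss + w_aux * softmax_ce_loss(fw$s[[nm]], tgt)
              g <- g + w_aux * softmax_ce_grad(fw$s[[nm]], tgt)
            }
            g_levels[[nm]] <- g
          }
        }
        grads <- backward_dcan(model$params, fw, g_levels)
      } else {
        loss <- softmax_ce_loss(fw$main$object, aug$object_target)
        grads <- backward_unet(model$params, fw,
                               softmax_ce_grad(fw$main$object, aug$object_target))
      }
      if (!is.finite(loss)) {
        abort(sprintf(
          "Non-finite loss at epoch %d, sample %d; aborting training.",
          epoch, si
        ))
      }
      losses <- c(losses, loss)
      if (is.null(batch_grads)) {
        batch_grads <- grads
      } else {
        for (nm in names(grads)) {
          batch_grads[[nm]]$w <- batch_grads[[nm]]$w + grads[[nm]]$w
          batch_grads[[nm]]$b <- batch_grads[[nm]]$b + grads[[nm]]$b
        }
      }
      n_in_batch <- n_in_batch + 1L
      if (n_in_batch == config$batch_size || si == ord[length(ord)]) {
        for (nm in names(batch_grads)) {
          gw <- batch_grads[[nm]]$w / n_in_batch
          gb <- batch_grads[[nm]]$b / n_in_batch
          if (is.finite(config$grad_clip)) {
            nrm <- sqrt(sum(gw^2) + sum(gb^2))
            if (nrm > config$grad_clip) {
              gw <- gw * config$grad_clip / nrm
              gb <- gb * config$grad_clip / nrm
            }
          }
          vel[[nm]]$w <- config$momentum * vel[[nm]]$w + gw
          vel[[nm]]$b <- config$momentum * vel[[nm]]$b + gb
          model$params[[nm]]$w <- model$params[[nm]]$w -
            config$learning_rate * vel[[nm]]$w
          model$params[[nm]]$b <- model$params[[nm]]$b -
            config$learning_rate * vel[[nm]]$b
        }
        batch_grads <- NULL
        n_in_batch <- 0L
      }
    }
    history[epoch] <- mean(losses)
  }
  model$history <- history
  model$config <- config
  model
}
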