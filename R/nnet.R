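# Segmentation networks: a U-Net-style encoder-decoder and a two-branch
# contour-aware model (shared encoder, object and contour branches fusing
# multi-level feature maps via bilinear upsampling, with per-level
# auxiliary outputs for deep supervision). Built on the package's own
# conv/pool/upsample primitives; no external deep-learning runtime.

BASE_CHANNELS <- c(32, 64, 128, 256)

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

xavier_init <- function(k, cin, cout) {
  fan_in <- k * k * cin
  fan_out <- k * k * cout
  limit <- sqrt(6 / (fan_in + fan_out))
  list(
    w = matrix(runif(k * k * cin * cout, -limit, limit), k * k * cin, cout),
    b = rep(0, cout),
    k = as.integer(k)
  )
}

conv_fw <- function(x, layer) cpp_conv2d_fw(as_cube(x), layer$w, layer$b, layer$k)

# Leaky rectifier (slope 0.01). The nets carry no normalization layers, so
# a hard ReLU can die wholesale under SGD; the leak keeps gradient flowing.
LEAKY_SLOPE <- 0.01
relu <- function(x) {
  neg <- x < 0
  x[neg] <- LEAKY_SLOPE * x[neg]
  x
}
relu_grad <- function(g, a) g * ((a > 0) + LEAKY_SLOPE * (a <= 0))

#' Build a gland segmentation model
#'
#' `kind = "dcan"`: shared 4-level downsampling encoder; two upsampling
#' branches (gland object, gland contour), each classifying encoder levels
#' 2-4 and fusing them by bilinear upsampling into a full-resolution
#' two-class softmax map, with the per-level maps kept as auxiliary
#' deep-supervision outputs. `kind = "unet"`: symmetric encoder-decoder
#' with skip connections and a single object output. Weights are
#' Xavier-uniform initialized from `seed`, so two builds with the same seed
#' are identical.
#'
#' @param kind `"dcan"` or `"unet"`.
#' @param width_multiplier Channel-count scale (1 = 32/64/128/256 channels;
#'   0.125 is the desk-scale setting used throughout the tests).
#' @param seed Integer seed for weight initialization.
#' @param in_channels Input channels (3 for RGB).
#' @return A `gland_segmenter` object.
#' @export
build_model <- function(kind = c("dcan", "unet"), width_multiplier = 1,
                        seed = 1, in_channels = 3) {
  kind <- match.arg(kind)
  if (width_multiplier <= 0) abort("`width_multiplier` must be > 0.")
  ch <- pmax(4L, as.integer(round(BASE_CHANNELS * width_multiplier)))
  params <- with_seed(derive_seed(seed, 11L), {
    p <- list(
      enc1 = xavier_init(3, in_channels, ch[1]),
      enc2 = xavier_init(3, ch[1], ch[2]),
      enc3 = xavier_init(3, ch[2], ch[3]),
      enc4 = xavier_init(3, ch[3], ch[4])
    )
    if (kind == "dcan") {
      for (br in c("object", "contour")) {
        for (l in 2:4) {
          # classifier heads start at zero so initial logits are neutral
          # (the encoder still gets gradient once the heads move)
          cls <- xavier_init(1, ch[l], 2)
          cls$w[] <- 0
          p[[sprintf("cls%d_%s", l, br)]] <- cls
        }
      }
    } else {
      p$dec3 <- xavier_init(3, ch[4] + ch[3], ch[3])
      p$dec2 <- xavier_init(3, ch[3] + ch[2], ch[2])
      p$dec1 <- xavier_init(3, ch[2] + ch[1], ch[1])
      p$head <- xavier_init(1, ch[1], 2)
      p$head$w[] <- 0
    }
    p
  })
  structure(
    list(kind = kind, width_multiplier = width_multiplier, channels = ch,
         in_channels = as.integer(in_channels), params = params,
         seed = as.integer(seed), downsample_factor = 8L, history = NULL),
    class = "gland_segmenter"
  )
}

#' @export
print.gland_segmenter <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(l) length(l$w) + length(l$b),
                      numeric(1)))
  cat(sprintf("%s gland segmenter: channels %s, %d parameters\n",
              x$kind, paste(x$channels, collapse = "/"), n_par))
  if (!is.null(x$history)) {
    cat(sprintf("trained %d epochs, final loss %.4f\n",
                length(x$history), tail(x$history, 1L)))
  }
  invisible(x)
}

softmax2 <- function(logits) {
  # two-channel softmax; returns foreground-probability matrix
  m <- pmax(logits[, , 1L], logits[, , 2L])
  e1 <- exp(logits[, , 1L] - m)
  e2 <- exp(logits[, , 2L] - m)
  e2 / (e1 + e2)
}

encoder_fw <- function(params, x) {
  z1 <- conv_fw(x, params$enc1); a1 <- relu(z1)
  mp1 <- cpp_maxpool_fw(a1)
  z2 <- conv_fw(mp1$y, params$enc2); a2 <- relu(z2)
  mp2 <- cpp_maxpool_fw(a2)
  z3 <- conv_fw(mp2$y, params$enc3); a3 <- relu(z3)
  mp3 <- cpp_maxpool_fw(a3)
  z4 <- conv_fw(mp3$y, params$enc4); a4 <- relu(z4)
  list(x = x, a1 = a1, a2 = a2, a3 = a3, a4 = a4,
       mp1 = mp1, mp2 = mp2, mp3 = mp3)
}

forward_dcan <- function(params, x) {
  enc <- encoder_fw(params, x)
  H <- dim(x)[1]; W <- dim(x)[2]
  acts <- list(`2` = enc$a2, `3` = enc$a3, `4` = enc$a4)
  s <- list()
  main <- list()
  for (br in c("object", "contour")) {
    total <- array(0, c(H, W, 2L))
    for (l in 2:4) {
      cls <- conv_fw(acts[[as.character(l)]], params[[sprintf("cls%d_%s", l, br)]])
      up <- cpp_upsample_fw(cls, 2L^(l - 1L))
      s[[sprintf("s%d_%s", l, br)]] <- up
      total <- total + up
    }
    main[[br]] <- total
  }
  list(enc = enc, s = s, main = main)
}

encoder_bw <- function(params, enc, ga1, ga2, ga3, ga4) {
  grads <- list()
  g <- relu_grad(ga4, enc$a4)
  bw <- cpp_conv2d_bw(enc$mp3$y, params$enc4$w, g, params$enc4$k)
  grads$enc4 <- list(w = bw$gw, b = bw$gb)
  g <- cpp_maxpool_bw(bw$gx, enc$mp3$idx, dim(enc$a3)[1], dim(enc$a3)[2]) + ga3
  g <- relu_grad(g, enc$a3)
  bw <- cpp_conv2d_bw(enc$mp2$y, params$enc3$w, g, params$enc3$k)
  grads$enc3 <- list(w = bw$gw, b = bw$gb)
  g <- cpp_maxpool_bw(bw$gx, enc$mp2$idx, dim(enc$a2)[1], dim(enc$a2)[2]) + ga2
  g <- relu_grad(g, enc$a2)
  bw <- cpp_conv2d_bw(enc$mp1$y, params$enc2$w, g, params$enc2$k)
  grads$enc2 <- list(w = bw$gw, b = bw$gb)
  g <- cpp_maxpool_bw(bw$gx, enc$mp1$idx, dim(enc$a1)[1], dim(enc$a1)[2]) + ga1
  g <- relu_grad(g, enc$a1)
  bw <- cpp_conv2d_bw(enc$x, params$enc1$w, g, params$enc1$k)
  grads$enc1 <- list(w = bw$gw, b = bw$gb)
  grads
}

# g_levels: named list "s{l}_{br}" -> gradient wrt that upsampled score map
backward_dcan <- function(params, fw, g_levels) {
  enc <- fw$enc
  acts <- list(`2` = enc$a2, `3` = enc$a3, `4` = enc$a4)
  ga <- list(`2` = NULL, `3` = NULL, `4` = NULL)
  grads <- list()
  for (br in c("object", "contour")) {
    for (l in 2:4) {
      nm <- sprintf("s%d_%s", l, br)
      g_up <- g_levels[[nm]]
      a <- acts[[as.character(l)]]
      g_cls <- cpp_upsample_bw(g_up, 2L^(l - 1L), dim(a)[1], dim(a)[2])
      lname <- sprintf("cls%d_%s", l, br)
      bw <- cpp_conv2d_bw(a, params[[lname]]$w, g_cls, 1L)
      grads[[lname]] <- list(w = bw$gw, b = bw$gb)
      ga[[as.character(l)]] <- if (is.null(ga[[as.character(l)]])) bw$gx else
        ga[[as.character(l)]] + bw$gx
    }
  }
  zero1 <- array(0, dim(enc$a1))
  c(grads, encoder_bw(params, enc, zero1, ga$`2`, ga$`3`, ga$`4`))
}

cat3 <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

forward_unet <- function(params, x) {
  enc <- encoder_fw(params, x)
  u3 <- cpp_upsample_fw(enc$a4, 2L)
  c3 <- cat3(u3, enc$a3)
  d3 <- relu(conv_fw(c3, params$dec3))
  u2 <- cpp_upsample_fw(d3, 2L)
  c2 <- cat3(u2, enc$a2)
  d2 <- relu(conv_fw(c2, params$dec2))
  u1 <- cpp_upsample_fw(d2, 2L)
  c1 <- cat3(u1, enc$a1)
  d1 <- relu(conv_fw(c1, params$dec1))
  logits <- conv_fw(d1, params$head)
  list(enc = enc, c3 = c3, d3 = d3, c2 = c2, d2 = d2, c1 = c1, d1 = d1,
       main = list(object = logits))
}

backward_unet <- function(params, fw, g_logits) {
  enc <- fw$enc
  grads <- list()
  bw <- cpp_conv2d_bw(fw$d1, params$head$w, g_logits, 1L)
  grads$head <- list(w = bw$gw, b = bw$gb)
  g <- relu_grad(bw$gx, fw$d1)
  bw <- cpp_conv2d_bw(fw$c1, params$dec1$w, g, 3L)
  grads$dec1 <- list(w = bw$gw, b = bw$gb)
  n_u1 <- dim(fw$d2)[3]
  g_u1 <- bw$gx[, , seq_len(n_u1), drop = FALSE]
  ga1 <- bw$gx[, , n_u1 + seq_len(dim(enc$a1)[3]), drop = FALSE]
  g <- cpp_upsample_bw(as_cube(g_u1), 2L, dim(fw$d2)[1], dim(fw$d2)[2])
  g <- relu_grad(g, fw$d2)
  bw <- cpp_conv2d_bw(fw$c2, params$dec2$w, g, 3L)
  grads$dec2 <- list(w = bw$gw, b = bw$gb)
  n_u2 <- dim(fw$d3)[3]
  g_u2 <- bw$gx[, , seq_len(n_u2), drop = FALSE]
  ga2 <- bw$gx[, , n_u2 + seq_len(dim(enc$a2)[3]), drop = FALSE]
  g <- cpp_upsample_bw(as_cube(g_u2), 2L, dim(fw$d3)[1], dim(fw$d3)[2])
  g <- relu_grad(g, fw$d3)
  bw <- cpp_conv2d_bw(fw$c3, params$dec3$w, g, 3L)
  grads$dec3 <- list(w = bw$gw, b = bw$gb)
  n_u3 <- dim(enc$a4)[3]
  g_u3 <- bw$gx[, , seq_len(n_u3), drop = FALSE]
  ga3 <- bw$gx[, , n_u3 + seq_len(dim(enc$a3)[3]), drop = FALSE]
  ga4 <- cpp_upsample_bw(as_cube(g_u3), 2L, dim(enc$a4)[1], dim(enc$a4)[2])
  zero1 <- array(0, dim(enc$a1))
  c(grads, encoder_bw(params, enc, ga1, ga2, ga3, ga4))
}

# Scale 8-bit RGB to the network's input range.
prepare_input <- function(image) {
  if (inherits(image, "gland_sample")) image <- image$image
  x <- image / 255 - 0.5
  as_cube(x)
}

model_forward <- function(model, x) {
  if (model$kind == "dcan") forward_dcan(model$params, x)
  else forward_unet(model$params, x)
}

#' Predict gland probability maps
#'
#' Runs the model on one patch. Inputs whose spatial dimensions are not
#' divisible by the model's total downsampling factor (8) are zero-padded
#' on the right/bottom and the output cropped back. Inference is
#' deterministic.
#'
#' @param model A [build_model()] result.
#' @param image `H x W x 3` RGB array in `[0, 255]` (or a `gland_sample`).
#' @return For `"dcan"`, a [probability_pair()]; for `"unet"`, a single
#'   object-probability matrix.
#' @export
predict_probs <- function(model, image) {
  x <- prepare_input(image)
  H <- dim(x)[1]; W <- dim(x)[2]
  f <- model$downsample_factor
  Hp <- ceiling(H / f) * f; Wp <- ceiling(W / f) * f
  if (Hp != H || Wp != W) {
    # edge-replication padding keeps border statistics tissue-like
    ri <- c(seq_len(H), rep(H, Hp - H))
    ci <- c(seq_len(W), rep(W, Wp - W))
    x <- x[ri, ci, , drop = FALSE]
  }
  fw <- model_forward(model, x)
  if (model$kind == "dcan") {
    probability_pair(
      softmax2(fw$main$object)[seq_len(H), seq_len(W)],
      softmax2(fw$main$contour)[seq_len(H), seq_len(W)]
    )
  } else {
    softmax2(fw$main$object)[seq_len(H), seq_len(W)]
  }
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles weights, architecture description, training
#' configuration and the stain-target profile hash; reloading reproduces
#' forward passes bit-identically.
#'
#' @param model A `gland_segmenter`.
#' @param path File path.
#' @param stain_target Optional [stain_profile()] whose hash is recorded.
#' @export
save_checkpoint <- function(model, path, stain_target = NULL) {
  obj <- unclass(model)
  obj$stain_hash <- if (!is.null(stain_target)) {
    stain_profile_hash(stain_target)
  } else {
    NA_character_
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(obj, class = "gland_segmenter")
}
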