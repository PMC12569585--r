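# Shared desk-scale study fixtures. The tiny two-branch model takes ~1.5
# minutes to train, so it is trained once per session and reused by the
# network tests and the end-to-end acceptance check.

desk_image_set <- function(n, seed0) {
  lapply(seq_len(n), function(i) {
    reg <- if (i %% 2 == 0) gland_regime("deformed") else gland_regime("regular")
    simulate_gland_image(96, 96, reg, n_glands = 3 + (i %% 3), seed = seed0 + i)
  })
}

desk_config <- function(epochs = 40, seed = 42) {
  train_config(
    learning_rate = 0.5, momentum = 0.9, grad_clip = 0.5, batch_size = 4,
    epochs = epochs, patch_size = 96, crop_size = 96, contour_thickness = 2,
    seed = seed
  )
}

.model_cache <- new.env(parent = emptyenv())

trained_desk_model <- function() {
  if (is.null(.model_cache$model)) {
    .model_cache$model <- train_model(
      build_model("dcan", width_multiplier = 0.125, seed = 42),
      desk_image_set(40, 100), desk_config()
    )
  }
  .model_cache$model
}

desk_segment <- function(model, sample) {
  segment_probability_pair(predict_probs(model, sample$image),
                           min_area = 100, smooth_radius = 2)
}
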