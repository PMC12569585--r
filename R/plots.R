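# ggplot2 visualisations for the result types.

#' Kaplan-Meier curves
#'
#' @param object A [kaplan_meier()] result.
#' @param ... Unused.
#' @return A ggplot of right-continuous survival step curves per group.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(group = unique(object$group), time = 0, surv = 1),
    as_tibble(object)[, c("group", "time", "surv")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-fold concordance of a cross-validated Cox model
#'
#' @param object A [cox_cross_validate()] result.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cox_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data$c_index)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_c_index, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Fold", y = "C-index") +
    ggplot2::theme_minimal()
}

label_map_df <- function(labels) {
  idx <- which(labels >= 0, arr.ind = TRUE)
  tibble(row = idx[, 1L], col = idx[, 2L], label = as.integer(labels[idx]))
}

#' Plot an instance label map
#'
#' @param labels Integer instance label matrix.
#' @return A ggplot raster with one colour per instance.
#' @export
plot_label_map <- function(labels) {
  df <- label_map_df(labels)
  df$instance <- factor(ifelse(df$label == 0L, NA, df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$instance)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_discrete(na.value = "grey95") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Gland") +
    ggplot2::theme_void()
}

#' Plot a synthetic gland sample
#'
#' @param object A [simulate_gland_image()] result.
#' @param what `"image"` for the H&E rendering, `"truth"` for the labels.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.gland_sample <- function(object, what = c("image", "truth"), ...) {
  what <- match.arg(what)
  if (what == "truth") return(plot_label_map(object$truth))
  d <- dim(object$image)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  cols <- grDevices::rgb(object$image[, , 1] / 255, object$image[, , 2] / 255,
                         object$image[, , 3] / 255)
  df <- tibble(row = idx$row, col = idx$col, fill = as.vector(cols))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
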