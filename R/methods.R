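#' Tidiers for segmentation results
#'
#' `tidy()` on a `fundus_seg` returns the lesion feature table (one row);
#' `glance()` returns a one-row model-level summary: lesion area, final
#' energy, iterations run and whether the contour survived.
#'
#' @param x A `fundus_seg` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fundus_seg <- function(x, ...) {
  if (!any(x$mask)) {
    return(tibble(area_px = 0L, perimeter_px = NA_real_,
                  major_axis_px = NA_real_, minor_axis_px = NA_real_,
                  intensity_median = NA_real_, intensity_std = NA_real_,
                  n_pixels = 0L))
  }
  compute_lesion_features(x$mask, x$input)
}

#' @rdname tidy.fundus_seg
#' @export
glance.fundus_seg <- function(x, ...) {
  tibble(
    area_px = sum(x$mask),
    iterations = x$state$iteration,
    final_energy = if (nrow(x$trace)) x$trace$energy[nrow(x$trace)] else NA_real_,
    converged_region = any(x$mask),
    filter = x$filter
  )
}

raster_df <- function(img) {
  if (is_rgb(img)) {
    tibble(
      row = rep(seq_len(dim(img)[1]), dim(img)[2]),
      col = rep(seq_len(dim(img)[2]), each = dim(img)[1]),
      fill = grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                            as.vector(img[, , 3]), maxColorValue = 255)
    )
  } else {
    g <- clip255(img) / 255
    tibble(
      row = rep(seq_len(nrow(img)), ncol(img)),
      col = rep(seq_len(ncol(img)), each = nrow(img)),
      fill = grDevices::gray(as.vector(g))
    )
  }
}

#' Plot a segmentation result
#'
#' Renders the segmented monochrome field with the lesion boundary
#' overlaid.
#'
#' @param object A `fundus_seg` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fundus_seg <- function(object, ...) {
  df <- raster_df(object$input)
  edge <- object$mask &
    !(shift_clamp(object$mask, 1L, 0L) & shift_clamp(object$mask, -1L, 0L) &
        shift_clamp(object$mask, 0L, 1L) & shift_clamp(object$mask, 0L, -1L))
  bd <- which(edge, arr.ind = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(bd)) {
    p <- p + ggplot2::geom_point(
      data = tibble(row = bd[, 1], col = bd[, 2]),
      colour = "yellow", size = 0.3
    )
  }
  p
}

#' Plot the energy trace of a segmentation
#'
#' Diagnostic line plot of the recorded total energy against iteration.
#'
#' @param seg A `fundus_seg` object with a non-empty trace.
#' @return A ggplot object.
#' @export
plot_energy_trace <- function(seg) {
  if (!nrow(seg$trace)) abort("segmentation was run without an energy trace")
  ggplot2::ggplot(seg$trace, ggplot2::aes(.data$iteration, .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Iteration", y = "Total energy") +
    ggplot2::theme_minimal()
}

#' Plot a batch evaluation
#'
#' Per-metric summary (mean with 95% confidence interval) of a
#' `fundus_eval` score table.
#'
#' @param object A `fundus_eval` tibble from [evaluate_batch()].
#' @param metrics Metrics to show (default the bounded \[0, 1\] ones).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fundus_eval <- function(object,
                                 metrics = c("dice", "sensitivity",
                                             "specificity", "accuracy"),
                                 ...) {
  sm <- metric_summary(object)
  sm <- sm[sm$metric %in% metrics, ]
  ggplot2::ggplot(sm, ggplot2::aes(.data$metric, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.2) +
    ggplot2::labs(x = NULL, y = "Score") +
    ggplot2::theme_minimal()
}
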