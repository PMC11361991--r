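#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_raster labs
#'   facet_wrap autoplot scale_fill_gradient theme_minimal geom_hline
NULL

#' Plot a simulated trajectory
#'
#' Faceted time courses of the compartment volumes, pleural/abdominal
#' pressures and diaphragm displacement.
#'
#' @param object A `resp_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resp_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "signal", values_to = "value")
  ggplot(long, aes(x = .data$t, y = .data$value)) +
    geom_line(colour = "#2C6E9B") +
    facet_wrap(~signal, scales = "free_y", ncol = 2) +
    labs(x = "time (s)", y = NULL,
         title = "Coupled respiratory mechanics trajectory") +
    theme_minimal()
}

#' Plot a synthetic session recording
#'
#' Displacement and flow surrogates over time, with the noiseless truth
#' overlaid when retained.
#'
#' @param object A `session_recording` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.session_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "channel", values_to = "value")
  p <- ggplot(long, aes(x = .data$t, y = .data$value)) +
    geom_line(colour = "grey40", linewidth = 0.3) +
    facet_wrap(~channel, scales = "free_y", ncol = 1) +
    labs(x = "time (s)", y = NULL,
         title = sprintf("Synthetic session (%s)", attr(object, "condition"))) +
    theme_minimal()
  truth <- attr(object, "truth")
  if (!is.null(truth)) {
    tl <- tibble::tibble(t = truth$t, channel = "displacement",
                         value = truth$x_di)
    p <- p + geom_line(data = tl, colour = "#C0392B", linewidth = 0.4)
  }
  p
}

#' Plot a closed-loop pneumatic trace
#'
#' Pressure against its reference with the +/-10% band of the final target.
#'
#' @param object A `pneumatic_trace` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pneumatic_trace <- function(object, ...) {
  tgt <- object$target[length(object$target)]
  ggplot(object, aes(x = .data$t)) +
    geom_line(aes(y = .data$target), colour = "grey55", linetype = 2) +
    geom_line(aes(y = .data$pressure), colour = "#2C6E9B") +
    geom_hline(yintercept = c(0.9, 1.1) * tgt, colour = "#C0392B",
               linetype = 3) +
    labs(x = "time (s)", y = "pressure (kPa)",
         title = "On-off valve control") +
    theme_minimal()
}

#' Plot an M-mode image with an optional traced curve
#'
#' @param object An `mmode_image` matrix.
#' @param curve Optional [trace_mmode()] result to overlay.
#' @param spec The [image_spec()] used (needed for the depth axis of the
#'   overlay).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mmode_image <- function(object, curve = NULL, spec = NULL, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$intensity <- as.vector(unclass(object))
  p <- ggplot(df, aes(x = .data$col, y = .data$row,
                      fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    labs(x = "time (columns)", y = "depth (pixels)", title = "M-mode") +
    theme_minimal()
  if (!is.null(curve) && !is.null(spec)) {
    rows <- (curve$depth - spec$depth_range[1L]) / depth_pixel_size(spec) + 0.5
    p <- p + geom_line(data = tibble::tibble(col = curve$t_index, row = rows),
                       aes(x = .data$col, y = .data$row),
                       inherit.aes = FALSE, colour = "#E67E22")
  }
  p
}

#' Plot observed vs fitted traces of a model fit
#'
#' @param object A `resp_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resp_fit <- function(object, ...) {
  obs <- object$observed
  n <- nrow(obs)
  sim_d <- shift_overlap(object$fitted$x_di, object$lag, nrow(object$fitted))
  sim_v <- shift_overlap(object$fitted$v_l - object$fitted$v_l[1L],
                         object$lag, nrow(object$fitted))
  long <- dplyr::bind_rows(
    tibble::tibble(t = obs$t, channel = "displacement (cm)",
                   observed = obs$displacement, fitted = sim_d),
    tibble::tibble(t = obs$t, channel = "volume (L)",
                   observed = obs$volume, fitted = sim_v)) |>
    tidyr::pivot_longer(c("observed", "fitted"),
                        names_to = "source", values_to = "value")
  ggplot(long, aes(x = .data$t, y = .data$value, colour = .data$source)) +
    geom_line(linewidth = 0.4) +
    facet_wrap(~channel, scales = "free_y", ncol = 1) +
    labs(x = "time (s)", y = NULL, colour = NULL,
         title = "Observed vs fitted session") +
    theme_minimal()
}

#' Plot a paired spontaneous-vs-assisted comparison
#'
#' @param object A `comparison_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$pairs, c("spont", "assisted"),
                              names_to = "condition", values_to = "value")
  long$condition <- factor(long$condition, c("spont", "assisted"))
  ggplot(long, aes(x = .data$condition, y = .data$value,
                   group = .data$subject)) +
    geom_line(colour = "grey60") +
    geom_point(colour = "#2C6E9B") +
    labs(x = NULL, y = NULL,
         title = sprintf("Paired comparison (ratio of means %.2f, p = %.3g)",
                         object$ratio_means, object$p_value)) +
    theme_minimal()
}
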