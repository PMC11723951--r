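#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_vline geom_point
#'   geom_raster geom_abline geom_tile labs scale_fill_viridis_c
#'   scale_fill_gradient2 facet_grid theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a relative-fluorescence curve
#'
#' @param object A `frap_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$rel_fluor)) +
    geom_line(linewidth = 0.6) +
    geom_vline(xintercept = attr(object, "bleach_time"), linetype = "dashed") +
    labs(x = "time (s)", y = "relative fluorescence") +
    theme_minimal()
}

#' Plot a double-exponential FRAP fit over its data
#'
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_fit <- function(object, ...) {
  pred <- tibble(
    t = seq(0, max(object$data$t), length.out = 200)
  )
  pred$y <- object$F0 + object$a1 * (1 - exp(-pred$t / object$tau1)) +
    object$a2 * (1 - exp(-pred$t / object$tau2))
  ggplot(object$data, aes(x = .data$t, y = .data$y)) +
    geom_point(size = 0.7, alpha = 0.6) +
    geom_line(data = pred, colour = "firebrick") +
    labs(x = "time after bleach (s)", y = "relative fluorescence") +
    theme_minimal()
}

#' Plot a kymograph
#'
#' @param object A [kymograph()] matrix.
#' @param ... Unused.
#' @return A ggplot (position versus time, intensity as fill).
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(
    position = attr(object, "positions"),
    time = attr(object, "times")
  )
  df$intensity <- as.vector(unclass(object))
  ggplot(df, aes(x = .data$time, y = .data$position, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c(option = "inferno") +
    labs(x = "time (s)", y = "position along line (px)") +
    theme_minimal()
}

#' Normalized chromocenter-versus-nucleoplasm scatter plot
#'
#' Points on the dashed diagonal correspond to equivalent compartment
#' intensities (partition coefficient 1).
#'
#' @param scatter Output of [normalized_scatter()].
#' @return A ggplot.
#' @export
plot_normalized_scatter <- function(scatter) {
  ggplot(scatter, aes(x = .data$np_norm, y = .data$cc_norm,
                      colour = .data$nuclear_intensity)) +
    geom_point(alpha = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    scale_fill_viridis_c(aesthetics = "colour", option = "inferno") +
    facet_grid(cols = ggplot2::vars(.data$construct_id)) +
    labs(x = "normalized nucleoplasm intensity",
         y = "normalized chromocenter intensity",
         colour = "nuclear\nintensity") +
    theme_minimal()
}

#' Heatmap of z-scored panel features ordered by the linkage tree
#'
#' @param object A `panel_clustering`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.panel_clustering <- function(object, ...) {
  ord <- rownames(object$zscores)[object$tree$order]
  df <- as_tibble(object$zscores, rownames = "construct_id") |>
    tidyr::pivot_longer(-"construct_id", names_to = "feature",
                        values_to = "z")
  df$construct_id <- factor(df$construct_id, levels = ord)
  ggplot(df, aes(x = .data$feature, y = .data$construct_id, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "z-score") +
    theme_minimal()
}
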