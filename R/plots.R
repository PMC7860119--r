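# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   labs geom_col geom_histogram theme_minimal
#' @export
ggplot2::autoplot

#' Plot an MSD curve
#'
#' @param object An `msd_curve` from [compute_msd()].
#' @param fit Optional `diffusion_fit` whose constrained line is overlaid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_curve <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$tau_s, y = .data$msd)) +
    geom_point() +
    geom_line(alpha = 0.4) +
    labs(x = "lag time (s)", y = expression(MSD ~ (mu * m^2))) +
    theme_minimal()
  if (!is.null(fit)) {
    p <- p + geom_abline(slope = fit$slope, intercept = 4 * fit$sigma_um^2,
                         linetype = 2, colour = "firebrick")
  }
  p
}

#' Plot a kernel density summary
#'
#' @param object A `kde_summary` from [kde_summary()].
#' @param ... Unused.
#' @return A ggplot (density curve; histogram-less summary if `n < 2`).
#' @export
autoplot.kde_summary <- function(object, ...) {
  if (is.null(object$density)) {
    abort("no density available (n < 2 or zero variance)")
  }
  ggplot(object$density, aes(x = .data$x, y = .data$y)) +
    geom_line() +
    labs(x = "value", y = "density") +
    theme_minimal()
}

#' Plot a photobleaching trace with its filtered version and step levels
#'
#' @param trace Numeric intensity series.
#' @param steps Optional result of [detect_steps()] for the same trace.
#' @return A ggplot.
#' @export
plot_trace <- function(trace, steps = NULL) {
  df <- tibble(frame = seq_along(trace) - 1L, intensity = trace)
  p <- ggplot(df, aes(x = .data$frame, y = .data$intensity)) +
    geom_line(alpha = 0.5) +
    labs(x = "frame", y = "intensity (counts)") +
    theme_minimal()
  if (!is.null(steps)) {
    df$filtered <- steps$filtered
    p <- p + geom_line(data = df, aes(y = .data$filtered),
                       colour = "firebrick")
  }
  p
}

#' Plot segmented eisosome ROI areas and intensities
#'
#' @param object An `eisosome_rois` tibble from [segment_eisosomes()].
#' @param ... Unused.
#' @return A ggplot of per-ROI mean intensity against area.
#' @export
autoplot.eisosome_rois <- function(object, ...) {
  ggplot(object, aes(x = .data$area_um2, y = .data$mean_intensity)) +
    geom_point() +
    labs(x = expression(area ~ (mu * m^2)), y = "mean intensity (counts)") +
    theme_minimal()
}
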