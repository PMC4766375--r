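#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial density profile
#'
#' Step plot of microglial density against distance from the plaque
#' boundary for a single plaque.
#'
#' @param object A `radial_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.radial_profile <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(mid = (.data$inner_r + .data$outer_r) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density_per_mm2)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Distance from plaque centre (µm)",
                  y = expression("Density (cells/mm"^2 * ")"),
                  title = paste0("Plaque ", attr(object, "plaque_id"),
                                 " — stop: ", attr(object, "stop_reason")))
}

#' Plot an aggregated radial profile
#'
#' Mean density per radial bin (distance from the plaque edge) with SEM
#' error bars, mirroring the mean-plus-SEM presentation of plaque-centric
#' density quantification.
#'
#' @param object An `aggregate_profile` from [aggregate_profiles()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.aggregate_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_um,
                                   y = .data$mean_density)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_density - .data$sem,
                   ymax = .data$mean_density + .data$sem),
      width = attr(object, "step") / 4) +
    ggplot2::labs(x = "Distance from plaque edge (µm)",
                  y = expression("Mean density ± SEM (cells/mm"^2 * ")"))
}

#' Scatter plot of intensity against distance to plaque
#'
#' @param cells Data frame with `x_um`, `y_um`, `intensity`.
#' @param plaques Plaque table with `x_um`, `y_um`, `radius_um`.
#' @param reference `"centre"` or `"boundary"` (see
#'   [intensity_distance_correlation()]).
#' @return A ggplot with a linear trend line.
#' @export
plot_intensity_distance <- function(cells, plaques,
                                    reference = c("centre", "boundary")) {
  reference <- match.arg(reference)
  cc <- dplyr::filter(cells, !is.na(.data$intensity))
  cc$distance <- distance_to_nearest_plaque(cc$x_um, cc$y_um, plaques,
                                            reference)
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$distance, y = .data$intensity)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = sprintf("Distance to plaque %s (µm)", reference),
                  y = "Intensity (a.u.)")
}
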