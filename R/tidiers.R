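#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a radial profile
#'
#' Returns the annulus table as a plain tibble, with the plaque id and
#' stop reason as columns so profiles can be row-bound across plaques.
#'
#' @param x A `radial_profile`.
#' @param ... Unused.
#' @return A tibble with one row per annulus.
#' @exportS3Method generics::tidy
tidy.radial_profile <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x)) |>
    dplyr::mutate(plaque_id = attr(x, "plaque_id"),
                  stop_reason = attr(x, "stop_reason"),
                  .before = 1)
}

#' One-row summary of a radial profile
#'
#' @param x A `radial_profile`.
#' @param ... Unused.
#' @return A one-row tibble with the plaque id, number of annuli, final
#'   outer radius, intra-plaque cell count and stop reason.
#' @exportS3Method generics::glance
glance.radial_profile <- function(x, ...) {
  tibble::tibble(
    plaque_id = attr(x, "plaque_id"),
    step = attr(x, "step"),
    n_annuli = nrow(x),
    final_outer_r = if (nrow(x)) max(x$outer_r) else NA_real_,
    cells_inside_plaque = attr(x, "cells_inside_plaque"),
    total_cells = sum(x$cell_count) + attr(x, "cells_inside_plaque"),
    stop_reason = attr(x, "stop_reason"))
}

#' @rdname tidy.radial_profile
#' @exportS3Method generics::tidy
tidy.aggregate_profile <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.radial_profile
#' @exportS3Method generics::tidy
tidy.proliferation_summary <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}
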