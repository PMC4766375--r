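#' Read plaque and cell tables
#'
#' Readers for the package's CSV schemas. The plaque table has columns
#' `id, x_um, y_um, radius_um`; the cell table additionally carries
#' `is_microglia` (0/1), `is_proliferating` (0/1) and an optional
#' `intensity` column (empty fields become NA).
#'
#' @param path Path to a CSV file.
#' @return A tibble with the validated columns.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_plaque_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("id", "x_um", "y_um", "radius_um"), "plaque table")
  df
}

#' @rdname table_io
#' @export
read_cell_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("id", "x_um", "y_um", "radius_um"), "cell table")
  df
}

#' @rdname table_io
#' @export
read_ct_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("sample_id", "group", "gene", "ct"), "Ct table")
  df
}

#' @rdname table_io
#' @export
read_analyte_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("sample_id", "group", "analyte",
                        "concentration_pg_ml", "below_lod", "lod_pg_ml"),
                  "analyte table")
  df
}

#' @rdname table_io
#' @export
read_trial_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, c("subject_id", "trial_index", "outcome"),
                  "trial table")
  df
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Write radial profiles (and their aggregate) to JSON
#'
#' Serialises a list of `radial_profile` objects to a JSON document with
#' one entry per plaque (annuli with `inner_r`, `outer_r`, `count`,
#' `area_mm2`, `density_per_mm2`, plus `cells_inside_plaque` and
#' `stop_reason`) and an `aggregate` entry with per-bin mean/SEM/n.
#'
#' @param profiles A list of `radial_profile` objects, e.g. from
#'   [profile_field()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_profile_json <- function(profiles, path) {
  if (inherits(profiles, "radial_profile")) profiles <- list(profiles)
  per_plaque <- purrr::map(profiles, function(pr) {
    list(
      plaque_id = attr(pr, "plaque_id"),
      step = attr(pr, "step"),
      cells_inside_plaque = attr(pr, "cells_inside_plaque"),
      stop_reason = attr(pr, "stop_reason"),
      annuli = as.data.frame(pr))
  })
  agg <- aggregate_profiles(profiles)
  jsonlite::write_json(
    list(plaques = per_plaque, aggregate = as.data.frame(agg)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
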