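#' Correlation of per-cell intensity with distance to plaque
#'
#' For each cell carrying an intensity value, computes the distance to the
#' nearest plaque (centre by default, boundary optionally) and reports the
#' Pearson and Spearman correlation between intensity and distance. A
#' negative coefficient means intensity falls with distance from plaques —
#' the pattern expected of a mitogen-receptor reporter concentrated in
#' plaque-associated microglia.
#'
#' @param cells Data frame with columns `x_um`, `y_um`, `intensity`
#'   (cells with missing intensity are dropped); an `id` column is carried
#'   through if present.
#' @param plaques Data frame of plaques with `x_um`, `y_um`, `radius_um`.
#' @param reference `"centre"` (default) or `"boundary"`: measure the
#'   distance to the nearest plaque centre, or to its edge (clamped at 0
#'   inside a plaque).
#' @return A one-row tibble with `pearson_r`, `spearman_rho`, `n`, and
#'   `undefined` (TRUE when either variable has zero variance, in which
#'   case the coefficients are NA).
#' @export
intensity_distance_correlation <- function(cells, plaques,
                                           reference = c("centre", "boundary")) {
  reference <- match.arg(reference)
  stopifnot(NROW(plaques) >= 1)
  cc <- dplyr::filter(cells, !is.na(.data$intensity))
  if (nrow(cc) < 3) {
    stop("insufficient data: need at least 3 cells with intensity", call. = FALSE)
  }
  d <- distance_to_nearest_plaque(cc$x_um, cc$y_um, plaques, reference)
  undefined <- stats::sd(cc$intensity) == 0 || stats::sd(d) == 0
  tibble::tibble(
    pearson_r = if (undefined) NA_real_ else stats::cor(d, cc$intensity),
    spearman_rho = if (undefined) NA_real_ else
      stats::cor(d, cc$intensity, method = "spearman"),
    n = nrow(cc),
    reference = reference,
    undefined = undefined)
}

# Distance from points to the nearest plaque centre or boundary.
distance_to_nearest_plaque <- function(x, y, plaques,
                                       reference = c("centre", "boundary")) {
  reference <- match.arg(reference)
  if (NROW(plaques) == 0) return(rep(Inf, length(x)))
  d <- vapply(seq_len(nrow(plaques)), function(i) {
    dc <- sqrt((x - plaques$x_um[i])^2 + (y - plaques$y_um[i])^2)
    if (reference == "boundary") pmax(0, dc - plaques$radius_um[i]) else dc
  }, numeric(length(x)))
  d <- matrix(d, nrow = length(x))
  apply(d, 1, min)
}

#' Percent positive (stained) area of an intensity grid
#'
#' Fraction of pixels at or above a threshold, as a percentage — the
#' percent-stained-area readout used for immunofluorescence signal
#' quantified at constant acquisition settings.
#'
#' @param field Numeric matrix (or data frame coercible to one) of
#'   non-negative pixel intensities.
#' @param threshold Positivity threshold, in the grid's intensity units.
#' @return Percentage in \[0, 100\].
#' @examples
#' percent_positive_area(matrix(c(0, 1, 0, 1), 2), threshold = 0.5) # 50
#' @export
percent_positive_area <- function(field, threshold) {
  stopifnot(threshold >= 0)
  m <- as.matrix(field)
  if (length(m) == 0) stop("invalid input: empty intensity grid", call. = FALSE)
  storage.mode(m) <- "numeric"
  100 * sum(m >= threshold) / length(m)
}
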