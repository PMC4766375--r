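#' Describe a rectangular tissue field
#'
#' A field is the rectangle the histology tables live in, with an optional
#' reference (wild-type) microglial density used by the background stopping
#' rule of [profile_plaque()].
#'
#' @param width,height Field dimensions in microns.
#' @param reference_density Wild-type microglial density in cells/mm^2.
#'   `0` (the default) means no baseline is known and the background
#'   stopping rule is not applied.
#'
#' @return A `field_spec` list with elements `width`, `height`,
#'   `reference_density`.
#' @export
field_spec <- function(width, height, reference_density = 0) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(reference_density))
  if (width <= 0 || height <= 0) {
    stop("invalid field: width and height must be positive", call. = FALSE)
  }
  if (reference_density < 0) {
    stop("invalid field: reference_density must be >= 0", call. = FALSE)
  }
  structure(list(width = width, height = height,
                 reference_density = reference_density),
            class = "field_spec")
}

# Coerce one plaque row (data frame row or named vector) to a list with
# x, y, r. Tables use the column names x_um, y_um, radius_um.
plaque_xyr <- function(plaque) {
  p <- as.list(plaque)
  list(x = as.numeric(p$x_um), y = as.numeric(p$y_um),
       r = as.numeric(p$radius_um))
}

#' Construct the concentric annuli of a plaque-centred profile
#'
#' Grows concentric rings outward from a plaque's boundary in fixed radial
#' steps, applying the geometric stopping rules: a candidate ring whose
#' outer circle touches a neighbouring plaque is excluded
#' (`neighbour_contact`), one whose outer circle is not fully inside the
#' field rectangle is excluded (`tissue_border`), and profiling otherwise
#' stops at the configured maximum radius (`max_radius`). The
#' density-based `background_reached` rule is applied later, by
#' [profile_plaque()], because it needs cell counts.
#'
#' @param plaque One-row data frame (or named list) with columns `x_um`,
#'   `y_um`, `radius_um`.
#' @param neighbours Data frame of other plaques with the same columns;
#'   may be `NULL` or empty.
#' @param field A [field_spec()].
#' @param step Ring width in microns (default 20).
#' @param max_radius Outer-radius cap in microns (default 200).
#'
#' @return A tibble with columns `inner_r`, `outer_r` (microns) and
#'   attribute `stop_reason` (one of `"neighbour_contact"`,
#'   `"tissue_border"`, `"max_radius"`). Zero rows if no valid first
#'   annulus exists.
#' @export
build_annuli <- function(plaque, neighbours = NULL, field,
                         step = 20, max_radius = 200) {
  stopifnot(inherits(field, "field_spec"))
  if (step <= 0) stop("invalid step: must be positive", call. = FALSE)
  p <- plaque_xyr(plaque)
  if (p$x < 0 || p$x > field$width || p$y < 0 || p$y > field$height) {
    stop("invalid input: plaque centre outside field", call. = FALSE)
  }

  nb <- if (is.null(neighbours) || NROW(neighbours) == 0) NULL else neighbours
  nb_d <- nb_r <- numeric(0)
  if (!is.null(nb)) {
    nb_d <- sqrt((nb$x_um - p$x)^2 + (nb$y_um - p$y)^2)
    nb_r <- nb$radius_um
  }

  inner <- outer <- numeric(0)
  reason <- "max_radius"
  k <- 0
  repeat {
    cand_in <- p$r + k * step
    cand_out <- p$r + (k + 1) * step
    if (cand_out > max_radius) { reason <- "max_radius"; break }
    if (length(nb_d) && any(nb_d <= cand_out + nb_r)) {
      reason <- "neighbour_contact"; break
    }
    inside <- (p$x - cand_out >= 0) && (p$x + cand_out <= field$width) &&
      (p$y - cand_out >= 0) && (p$y + cand_out <= field$height)
    if (!inside) { reason <- "tissue_border"; break }
    inner <- c(inner, cand_in); outer <- c(outer, cand_out)
    k <- k + 1
  }

  out <- tibble::tibble(inner_r = inner, outer_r = outer)
  attr(out, "stop_reason") <- reason
  out
}

#' Radial density profile of microglia around one plaque
#'
#' The plaque-centric adaptation of Sholl analysis: concentric annuli of
#' fixed width are grown from the plaque boundary ([build_annuli()]), every
#' microglial cell is assigned to the single region (plaque interior, one
#' annulus, or beyond the final ring) holding the majority of its disk
#' area, and per-annulus density (cells/mm^2) is reported. Profiling stops
#' at the first of: contact with a neighbouring plaque, the tissue border,
#' the density falling back to the reference (wild-type) level, or the
#' maximum radius.
#'
#' @param cells Data frame of cells with columns `x_um`, `y_um`,
#'   `radius_um` and optionally `is_microglia` (0/1; if present only
#'   flagged cells are counted).
#' @param plaque One-row data frame with `x_um`, `y_um`, `radius_um`, and
#'   optionally `id`.
#' @param neighbours Other plaques (same columns), or `NULL`.
#' @param field A [field_spec()]; its `reference_density` drives the
#'   background stopping rule (disabled when 0).
#' @param step,max_radius Ring width and outer cap in microns.
#' @param background_tolerance Fractional tolerance on the reference
#'   density: profiling stops after the first annulus whose density is at
#'   most `reference_density * (1 + background_tolerance)` (that annulus
#'   is kept). Must be non-negative.
#'
#' @return A `radial_profile`: a tibble with columns `inner_r`, `outer_r`,
#'   `cell_count`, `area_mm2`, `density_per_mm2`, and attributes
#'   `plaque_id`, `step`, `cells_inside_plaque`, `stop_reason`.
#'
#' @details
#' Cell assignment uses exact lens areas: the cumulative fraction of the
#' cell disk inside each boundary circle is computed analytically and the
#' cell belongs to the first region whose cumulative fraction reaches 1/2,
#' so an exact 50/50 split goes to the inner region. Cells with majority
#' area inside the plaque disk are tallied separately
#' (`cells_inside_plaque`), not in the first annulus; cells with majority
#' area beyond the final ring are not counted.
#' @export
profile_plaque <- function(cells, plaque, neighbours = NULL, field,
                           step = 20, max_radius = 200,
                           background_tolerance = 0.1) {
  if (background_tolerance < 0) {
    stop("invalid parameter: background_tolerance must be >= 0", call. = FALSE)
  }
  p <- plaque_xyr(plaque)
  pid <- if (!is.null(as.list(plaque)$id)) as.list(plaque)$id else NA
  ann <- build_annuli(plaque, neighbours, field, step, max_radius)
  reason <- attr(ann, "stop_reason")

  mg <- cells
  if (!is.null(mg) && NROW(mg) > 0 && "is_microglia" %in% names(mg)) {
    mg <- dplyr::filter(mg, .data$is_microglia == 1)
  }

  n_ann <- nrow(ann)
  counts <- integer(n_ann)
  inside_plaque <- 0L

  if (!is.null(mg) && NROW(mg) > 0 && n_ann >= 0) {
    bounds <- c(p$r, ann$outer_r)  # boundary circles, innermost first
    # cheap prefilter: only cells that can overlap the final circle
    reach <- max(bounds)
    d2 <- (mg$x_um - p$x)^2 + (mg$y_um - p$y)^2
    near <- d2 <= (reach + mg$radius_um)^2
    mgn <- mg[near, , drop = FALSE]
    if (nrow(mgn) > 0) {
      cum <- vapply(bounds, function(r) {
        disk_fraction_in_circle(mgn$x_um, mgn$y_um, mgn$radius_um, p$x, p$y, r)
      }, numeric(nrow(mgn)))
      cum <- matrix(cum, nrow = nrow(mgn))
      # first boundary circle holding at least half the cell; ties go inward
      idx <- rowSums(cum < 0.5) + 1L
      counted <- idx <= length(bounds)
      inside_plaque <- sum(counted & idx == 1L)
      if (n_ann > 0) {
        tab <- tabulate(idx[counted & idx > 1L] - 1L, nbins = n_ann)
        counts <- as.integer(tab)
      }
    }
  }

  area_mm2 <- (pi * (ann$outer_r^2 - ann$inner_r^2)) / 1e6
  density <- ifelse(area_mm2 > 0, counts / area_mm2, NA_real_)

  prof <- tibble::tibble(inner_r = ann$inner_r, outer_r = ann$outer_r,
                         cell_count = counts, area_mm2 = area_mm2,
                         density_per_mm2 = density)

  if (field$reference_density > 0 && nrow(prof) > 0) {
    thr <- field$reference_density * (1 + background_tolerance)
    hit <- which(prof$density_per_mm2 <= thr)
    if (length(hit) > 0) {
      prof <- prof[seq_len(hit[1]), , drop = FALSE]
      reason <- "background_reached"
    }
  }

  structure(prof,
            class = c("radial_profile", class(prof)),
            plaque_id = pid, step = step,
            cells_inside_plaque = as.integer(inside_plaque),
            stop_reason = reason)
}

#' Profile every plaque in a field
#'
#' Runs [profile_plaque()] for each plaque in turn, treating all other
#' plaques as neighbours (every plaque is analysed independently; a cell
#' may contribute to several profiles, with the neighbour-contact rule
#' limiting double counting).
#'
#' @inheritParams profile_plaque
#' @param plaques Data frame of plaques with columns `id`, `x_um`, `y_um`,
#'   `radius_um`.
#' @return A list of `radial_profile` objects, named by plaque id.
#' @export
profile_field <- function(cells, plaques, field, step = 20,
                          max_radius = 200, background_tolerance = 0.1) {
  stopifnot(NROW(plaques) > 0)
  out <- purrr::map(seq_len(nrow(plaques)), function(i) {
    profile_plaque(cells, plaques[i, , drop = FALSE],
                   neighbours = plaques[-i, , drop = FALSE],
                   field = field, step = step, max_radius = max_radius,
                   background_tolerance = background_tolerance)
  })
  names(out) <- as.character(plaques$id)
  out
}

#' Aggregate radial profiles across plaques
#'
#' Bins are aligned by distance from the plaque boundary (ring index times
#' the common step), so plaques of different radii are comparable. Each
#' bin's mean density and SEM are computed over the profiles that reached
#' that bin; profiles that stopped earlier contribute nothing there (no
#' zero-imputation).
#'
#' @param profiles A list of `radial_profile` objects sharing one step
#'   size (e.g. from [profile_field()]).
#' @return An `aggregate_profile` tibble with columns `bin`,
#'   `distance_um` (bin midpoint, distance from the plaque edge),
#'   `mean_density`, `sem`, `n_plaques`; attribute `step`. SEM is 0 where
#'   only one plaque contributes (`n_plaques` flags this).
#' @export
aggregate_profiles <- function(profiles) {
  if (inherits(profiles, "radial_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0)
  steps <- unique(purrr::map_dbl(profiles, ~ attr(.x, "step")))
  if (length(steps) != 1) {
    stop("incompatible profiles: mixed step sizes", call. = FALSE)
  }
  step <- steps[[1]]
  long <- purrr::map_dfr(profiles, function(pr) {
    if (nrow(pr) == 0) return(NULL)
    tibble::tibble(bin = seq_len(nrow(pr)), density = pr$density_per_mm2)
  })
  if (nrow(long) == 0) {
    return(structure(tibble::tibble(bin = integer(), distance_um = numeric(),
                                    mean_density = numeric(), sem = numeric(),
                                    n_plaques = integer()),
                     class = c("aggregate_profile", "tbl_df", "tbl", "data.frame"),
                     step = step))
  }
  agg <- long |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_density = mean(.data$density),
      sem = if (dplyr::n() > 1) stats::sd(.data$density) / sqrt(dplyr::n()) else 0,
      n_plaques = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(distance_um = (.data$bin - 0.5) * step) |>
    dplyr::select("bin", "distance_um", "mean_density", "sem", "n_plaques")
  structure(agg,
            class = c("aggregate_profile", class(agg)),
            step = step)
}

#' Estimate the enrichment decay length from an aggregate profile
#'
#' Fits the plateau-plus-exponential enrichment model
#' `density(d) = b + c * exp(-d / tau)`, with `d` the distance from the
#' plaque boundary, by weighted nonlinear least squares (bins weighted by
#' the number of contributing plaques). Estimating the plateau `b` from
#' the profile itself, rather than fixing it at a nominal background,
#' matters in plaque-dense fields: enrichment spilling over from
#' neighbouring plaques lifts the far-field level, and a fixed baseline
#' would inflate the apparent decay length.
#'
#' @param aggregate An `aggregate_profile` from [aggregate_profiles()].
#' @param tau_init Starting value for the decay length; defaults to twice
#'   the profile's step size.
#' @return A one-row tibble with `tau_um` (decay length), `amplitude`
#'   (edge enrichment as a multiple of the fitted plateau), `baseline`
#'   (fitted plateau density, cells/mm^2), and `n_bins` used.
#' @export
estimate_decay_length <- function(aggregate, tau_init = NULL) {
  df <- as.data.frame(aggregate)
  if (nrow(df) < 4) {
    stop("insufficient data: need at least 4 radial bins", call. = FALSE)
  }
  if (is.null(tau_init)) tau_init <- 2 * attr(aggregate, "step")
  b0 <- min(df$mean_density)
  c0 <- max(df$mean_density) - b0
  if (c0 <= 0) {
    stop("no decay: profile shows no radial enrichment", call. = FALSE)
  }
  fit <- stats::nls(mean_density ~ b + cc * exp(-distance_um / tau),
                    data = df,
                    start = list(b = b0, cc = c0, tau = tau_init),
                    weights = df$n_plaques,
                    control = stats::nls.control(warnOnly = TRUE))
  est <- stats::coef(fit)
  if (!is.finite(est[["tau"]]) || est[["tau"]] <= 0) {
    stop("no decay: exponential fit did not converge to a positive decay length",
         call. = FALSE)
  }
  tibble::tibble(tau_um = est[["tau"]],
                 amplitude = est[["cc"]] / est[["b"]],
                 baseline = est[["b"]],
                 n_bins = nrow(df))
}
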