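#' Configuration for the synthetic histology generator
#'
#' Bundles every generative parameter of [simulate_field()] with a seed,
#' so a configuration fully determines its output. Defaults describe a
#' cortical field of an amyloid-depositing mouse at the onset of plaque
#' pathology: plaques at 4.41/mm^2, a background microglial density of
#' 300 cells/mm^2 enriched several-fold at plaque edges with an
#' exponential falloff, proliferation labelling concentrated near
#' plaques, and a reporter intensity decaying with distance to the
#' nearest plaque centre.
#'
#' @param seed Integer RNG seed; identical configurations produce
#'   byte-identical tables.
#' @param width,height Field dimensions in microns.
#' @param plaque_intensity Plaque intensity in plaques/mm^2.
#' @param plaque_radius_mean,plaque_radius_sd Plaque radius distribution
#'   (microns; truncated below at 2).
#' @param min_plaque_separation Hard-core minimum centre-to-centre
#'   distance between plaques (microns).
#' @param background_density Far-field microglial density (cells/mm^2).
#' @param enrichment_amplitude Density multiple added at the plaque edge:
#'   the local rate is
#'   `background * (1 + amplitude * exp(-d_boundary / decay_length))`.
#' @param decay_length Enrichment decay length (microns), measured from
#'   the plaque boundary.
#' @param cell_radius Cell (soma) disk radius (microns).
#' @param pi_near,pi_far Proliferation-labelling probability at the
#'   plaque edge and in the far field; interpolated on the same
#'   exponential scale as the density enrichment.
#' @param intensity_I0 Reporter intensity at a plaque centre (arbitrary
#'   units).
#' @param intensity_decay Reporter intensity decay length (microns),
#'   measured from the plaque centre.
#' @param intensity_noise_sd Gaussian intensity noise (arbitrary units);
#'   intensities are clipped at 0.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              width = 2000, height = 2000,
                              plaque_intensity = 4.41,
                              plaque_radius_mean = 15,
                              plaque_radius_sd = 4,
                              min_plaque_separation = 60,
                              background_density = 300,
                              enrichment_amplitude = 3,
                              decay_length = 40,
                              cell_radius = 5,
                              pi_near = 0.05,
                              pi_far = 0.01,
                              intensity_I0 = 100,
                              intensity_decay = 50,
                              intensity_noise_sd = 10) {
  cfg <- list(seed = as.integer(seed), width = width, height = height,
              plaque_intensity = plaque_intensity,
              plaque_radius_mean = plaque_radius_mean,
              plaque_radius_sd = plaque_radius_sd,
              min_plaque_separation = min_plaque_separation,
              background_density = background_density,
              enrichment_amplitude = enrichment_amplitude,
              decay_length = decay_length,
              cell_radius = cell_radius,
              pi_near = pi_near, pi_far = pi_far,
              intensity_I0 = intensity_I0,
              intensity_decay = intensity_decay,
              intensity_noise_sd = intensity_noise_sd)
  lengths_ok <- all(vapply(cfg[-1], function(v) is.numeric(v) && v >= 0,
                           logical(1)))
  if (!lengths_ok) {
    stop("invalid config: all parameters must be non-negative numbers",
         call. = FALSE)
  }
  if (cfg$width <= 0 || cfg$height <= 0) {
    stop("invalid config: field dimensions must be positive", call. = FALSE)
  }
  if (cfg$pi_near > 1 || cfg$pi_far > 1) {
    stop("invalid config: labelling probabilities must be in [0, 1]",
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a synthetic histology field
#'
#' Generates a plaque table and a cell table with the spatial structure
#' the profiling analyses assume. Plaques follow a hard-core Poisson
#' process (uniform proposals, rejected within the minimum separation) at
#' the configured intensity; microglia follow an inhomogeneous Poisson
#' process whose rate is elevated near plaque boundaries and decays
#' exponentially to the background; each cell carries a
#' distance-dependent proliferation label and a reporter intensity
#' decaying with distance to the nearest plaque centre plus Gaussian
#' noise (clipped at 0).
#'
#' @param config A [simulation_config()].
#' @return A list with tibbles `plaques` (`id`, `x_um`, `y_um`,
#'   `radius_um`) and `cells` (`id`, `x_um`, `y_um`, `radius_um`,
#'   `is_microglia`, `is_proliferating`, `intensity`), matching the CSV
#'   schemas read by [read_plaque_table()] and [read_cell_table()].
#' @export
simulate_field <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_field_impl(config))
}

simulate_field_impl <- function(cfg) {
  area_mm2 <- cfg$width * cfg$height / 1e6

  # --- plaques: hard-core thinned Poisson process
  n_target <- stats::rpois(1, cfg$plaque_intensity * area_mm2)
  px <- py <- pr <- numeric(0)
  attempts <- 0
  max_attempts <- max(200, 200 * n_target)
  while (length(px) < n_target && attempts < max_attempts) {
    attempts <- attempts + 1
    x <- stats::runif(1, 0, cfg$width)
    y <- stats::runif(1, 0, cfg$height)
    if (length(px) == 0 ||
        all((px - x)^2 + (py - y)^2 >= cfg$min_plaque_separation^2)) {
      px <- c(px, x); py <- c(py, y)
      pr <- c(pr, max(2, stats::rnorm(1, cfg$plaque_radius_mean,
                                      cfg$plaque_radius_sd)))
    }
  }
  if (n_target > 0 && length(px) == 0) {
    warning("field too small for the requested plaque separation; ",
            "returning a plaque-free field")
  }
  plaques <- tibble::tibble(
    id = if (length(px)) paste0("P", seq_along(px)) else character(0),
    x_um = px, y_um = py, radius_um = pr)

  # --- microglia: inhomogeneous Poisson by thinning at the rate maximum
  lambda_max <- cfg$background_density * (1 + cfg$enrichment_amplitude)
  n_prop <- stats::rpois(1, lambda_max * area_mm2)
  cx <- stats::runif(n_prop, 0, cfg$width)
  cy <- stats::runif(n_prop, 0, cfg$height)
  db <- distance_to_nearest_plaque(cx, cy, plaques, "boundary")
  grad <- exp(-db / cfg$decay_length)          # 1 at the boundary, 0 far away
  lambda <- cfg$background_density * (1 + cfg$enrichment_amplitude * grad)
  keep <- stats::runif(n_prop) < lambda / lambda_max
  cx <- cx[keep]; cy <- cy[keep]; grad <- grad[keep]

  p_label <- cfg$pi_far + (cfg$pi_near - cfg$pi_far) * grad
  labelled <- stats::runif(length(cx)) < p_label

  dc <- distance_to_nearest_plaque(cx, cy, plaques, "centre")
  intensity <- pmax(0, cfg$intensity_I0 * exp(-dc / cfg$intensity_decay) +
                      stats::rnorm(length(cx), 0, cfg$intensity_noise_sd))

  cells <- tibble::tibble(
    id = if (length(cx)) paste0("C", seq_along(cx)) else character(0),
    x_um = cx, y_um = cy,
    radius_um = rep(cfg$cell_radius, length(cx)),
    is_microglia = rep(1L, length(cx)),
    is_proliferating = as.integer(labelled),
    intensity = intensity)

  list(plaques = plaques, cells = cells)
}

#' Simulate a long-format qPCR Ct table
#'
#' Generates housekeeping and target Ct values for a two-group design
#' with a known generative fold change, so the 2^-ddCt pipeline can be
#' checked end to end: housekeeping Cts are Normal around gene-specific
#' means, and the target Ct is shifted by `-log2(fold)` in the affected
#' group.
#'
#' @param seed Integer RNG seed.
#' @param n_per_group Samples per group.
#' @param groups Length-2 character vector; the second group carries the
#'   fold effect.
#' @param housekeeping Named numeric vector of housekeeping mean Cts.
#' @param target_gene Name of the target gene.
#' @param target_base_ct Target mean Ct in the control group.
#' @param fold Generative fold change in the affected group (> 0;
#'   fold 2 lowers the target Ct by one cycle).
#' @param sd Gaussian Ct noise (cycles) applied to every measurement;
#'   `0` gives exact fold recovery.
#' @return A long tibble with columns `sample_id`, `group`, `gene`, `ct`.
#' @export
simulate_ct_table <- function(seed = 1L, n_per_group = 6,
                              groups = c("control", "case"),
                              housekeeping = c(Gapdh = 18, Hprt = 22,
                                               Rn18s = 12, Gusb = 24),
                              target_gene = "Csf1r",
                              target_base_ct = 26,
                              fold = 2, sd = 0.3) {
  stopifnot(length(groups) == 2, n_per_group >= 1, fold > 0, sd >= 0,
            length(housekeeping) >= 1, !is.null(names(housekeeping)))
  withr::with_seed(as.integer(seed), {
    samples <- tibble::tibble(
      sample_id = paste0("S", seq_len(2 * n_per_group)),
      group = rep(groups, each = n_per_group))
    genes <- c(housekeeping, stats::setNames(target_base_ct, target_gene))
    long <- tidyr::expand_grid(samples, gene = names(genes)) |>
      dplyr::mutate(
        base = unname(genes[.data$gene]),
        shift = ifelse(.data$gene == target_gene & .data$group == groups[2],
                       -log2(fold), 0),
        ct = .data$base + .data$shift + stats::rnorm(dplyr::n(), 0, sd)) |>
      dplyr::select("sample_id", "group", "gene", "ct")
    long
  })
}
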