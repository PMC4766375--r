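make_field <- function(ref = 0) field_spec(1000, 1000, ref)
plaque_at <- function(x, y, r = 10, id = "A") {
  tibble::tibble(id = id, x_um = x, y_um = y, radius_um = r)
}
cells_at <- function(x, y, r = 5) {
  tibble::tibble(id = paste0("c", seq_along(x)), x_um = x, y_um = y,
                 radius_um = r, is_microglia = 1L, is_proliferating = 0L,
                 intensity = NA_real_)
}

test_that("annuli grow in fixed steps from the plaque boundary", {
  a <- build_annuli(plaque_at(500, 500), NULL, make_field(),
                    step = 20, max_radius = 110)
  expect_equal(a$inner_r, c(10, 30, 50, 70, 90))
  expect_equal(a$outer_r, c(30, 50, 70, 90, 110))
  expect_equal(attr(a, "stop_reason"), "max_radius")
})

test_that("a ring contacting a neighbouring plaque stops the profile", {
  # neighbour of radius 10 at 100 um: ring [70,90) has 90 + 10 >= 100
  nb <- plaque_at(600, 500, id = "B")
  a <- build_annuli(plaque_at(500, 500), nb, make_field(), 20, 200)
  expect_equal(a$outer_r, c(30, 50, 70))
  expect_equal(attr(a, "stop_reason"), "neighbour_contact")
})

test_that("a ring crossing the tissue border stops the profile", {
  # plaque centre 45 um from the field edge: ring [30,50) would cross
  a <- build_annuli(plaque_at(45, 500), NULL, make_field(), 20, 200)
  expect_equal(a$outer_r, 30)
  expect_equal(attr(a, "stop_reason"), "tissue_border")
})

test_that("degenerate geometry is rejected or yields empty profiles", {
  expect_error(build_annuli(plaque_at(-5, 500), NULL, make_field()),
               "outside field")
  expect_error(build_annuli(plaque_at(500, 500), NULL, make_field(),
                            step = 0), "step")
  # plaque 15 um from the edge: even the first ring crosses the border
  a <- build_annuli(plaque_at(15, 500), NULL, make_field(), 20, 200)
  expect_equal(nrow(a), 0)
  expect_equal(attr(a, "stop_reason"), "tissue_border")
})

test_that("cells are assigned to the ring holding the majority of their area", {
  f <- make_field()
  p <- plaque_at(500, 500)
  # fully contained in ring [10,30)
  pr <- profile_plaque(cells_at(525, 500), p, NULL, f, 20, 110)
  expect_equal(pr$cell_count, c(1, 0, 0, 0, 0))
  # centred exactly on the [10,30)/[30,50) boundary: the boundary circle is
  # curved, so the majority (pixel oracle: ~51.8%) lies in the outer ring
  inner_frac <- pixel_disk_fraction_in_annulus(530, 500, 5, 500, 500, 10, 30)
  expect_lt(inner_frac, 0.5)
  pr2 <- profile_plaque(cells_at(530, 500), p, NULL, f, 20, 110)
  expect_equal(pr2$cell_count, c(0, 1, 0, 0, 0))
  # nudged inward past the majority point, the inner ring wins
  pr3 <- profile_plaque(cells_at(529, 500), p, NULL, f, 20, 110)
  expect_equal(pr3$cell_count, c(1, 0, 0, 0, 0))
  # majority inside the plaque disk: tallied separately
  pr4 <- profile_plaque(cells_at(503, 500), p, NULL, f, 20, 110)
  expect_equal(sum(pr4$cell_count), 0)
  expect_equal(attr(pr4, "cells_inside_plaque"), 1L)
})

test_that("empty cell tables give zero-count profiles, not errors", {
  pr <- profile_plaque(cells_at(numeric(0), numeric(0)),
                       plaque_at(500, 500), NULL, make_field(), 20, 110)
  expect_equal(sum(pr$cell_count), 0)
  expect_equal(attr(pr, "cells_inside_plaque"), 0L)
  expect_error(
    profile_plaque(cells_at(525, 500), plaque_at(500, 500), NULL,
                   make_field(), background_tolerance = -0.1),
    "background_tolerance")
})

test_that("density returning to the reference level stops the profile", {
  # deterministic 20-um grid of cells ~ 2500 cells/mm^2 everywhere
  g <- expand.grid(x = seq(10, 990, by = 20), y = seq(10, 990, by = 20))
  cells <- cells_at(g$x, g$y)
  f <- field_spec(1000, 1000, reference_density = 2500)
  pr <- profile_plaque(cells, plaque_at(500, 500), NULL, f,
                       step = 20, max_radius = 200,
                       background_tolerance = 0.1)
  expect_equal(attr(pr, "stop_reason"), "background_reached")
  expect_equal(nrow(pr), 1)  # uniform density: rule fires at the first ring
  expect_lte(pr$density_per_mm2[nrow(pr)], 2500 * 1.1)
})

test_that("counts are conserved within the final circle", {
  for (seed in c(3, 17, 29)) {
    cfg <- simulation_config(seed = seed, width = 1000, height = 1000,
                             plaque_intensity = 3)
    sim <- simulate_field(cfg)
    expect_gt(nrow(sim$plaques), 0)
    f <- field_spec(1000, 1000, 0)
    profs <- profile_field(sim$cells, sim$plaques, f)
    for (i in seq_along(profs)) {
      pr <- profs[[i]]
      if (nrow(pr) == 0) next
      p <- sim$plaques[i, ]
      R <- max(pr$outer_r)
      # independent accounting: majority-area membership in the final circle
      d <- sqrt((sim$cells$x_um - p$x_um)^2 + (sim$cells$y_um - p$y_um)^2)
      cand <- sim$cells[d <= R + sim$cells$radius_um + 1, ]
      expected <- pixel_cells_within_circle(cand, p$x_um, p$y_um, R)
      expect_equal(sum(pr$cell_count) + attr(pr, "cells_inside_plaque"),
                   expected)
    }
  }
})

test_that("enlarging max_radius never changes the annuli emitted before the stop", {
  cfg <- simulation_config(seed = 5, width = 1000, height = 1000)
  sim <- simulate_field(cfg)
  f <- field_spec(1000, 1000, 0)
  p <- sim$plaques[1, ]
  nb <- sim$plaques[-1, ]
  short <- profile_plaque(sim$cells, p, nb, f, max_radius = 100)
  long <- profile_plaque(sim$cells, p, nb, f, max_radius = 200)
  k <- nrow(short)
  expect_equal(as.data.frame(short),
               as.data.frame(long)[seq_len(k), ],
               ignore_attr = TRUE)
})

test_that("aggregation computes per-bin mean, SEM and contributing plaques", {
  f <- make_field()
  mk <- function(dens) {
    pr <- tibble::tibble(inner_r = c(10, 30), outer_r = c(30, 50),
                         cell_count = c(0L, 0L), area_mm2 = c(1, 1),
                         density_per_mm2 = dens)
    structure(pr, class = c("radial_profile", class(pr)),
              plaque_id = "x", step = 20, cells_inside_plaque = 0L,
              stop_reason = "max_radius")
  }
  agg <- aggregate_profiles(list(mk(c(100, 50)), mk(c(200, 150))))
  expect_equal(agg$mean_density, c(150, 100))
  expect_equal(agg$sem, c(50, 50))
  expect_equal(agg$n_plaques, c(2L, 2L))
  # single profile: means are its densities, SEM 0 with n flagged as 1
  agg1 <- aggregate_profiles(list(mk(c(100, 50))))
  expect_equal(agg1$mean_density, c(100, 50))
  expect_equal(agg1$sem, c(0, 0))
  expect_equal(agg1$n_plaques, c(1L, 1L))
  # mixed steps are incompatible
  bad <- mk(c(1, 2)); attr(bad, "step") <- 10
  expect_error(aggregate_profiles(list(mk(c(1, 2)), bad)), "step")
})

test_that("profiles of enriched fields are elevated near the plaque", {
  # first ring denser than the last in fields simulated with enrichment
  hits <- 0; total <- 0
  for (seed in 1:10) {
    sim <- simulate_field(simulation_config(seed = seed, width = 1500,
                                            height = 1500))
    if (nrow(sim$plaques) == 0) next
    profs <- profile_field(sim$cells, sim$plaques, field_spec(1500, 1500, 0))
    for (pr in profs) {
      if (nrow(pr) < 3) next
      total <- total + 1
      if (pr$density_per_mm2[1] > pr$density_per_mm2[nrow(pr)]) hits <- hits + 1
    }
  }
  expect_gt(total, 20)
  expect_gt(hits / total, 0.8)
})

test_that("the aggregate profile recovers the generative decay length", {
  profs <- list(); n_plaques <- 0; seed <- 1000
  while (n_plaques < 150) {
    sim <- simulate_field(simulation_config(seed = seed, width = 2000,
                                            height = 2000))
    if (nrow(sim$plaques) > 0) {
      profs <- c(profs,
                 profile_field(sim$cells, sim$plaques,
                               field_spec(2000, 2000, 0),
                               max_radius = 300))
      n_plaques <- n_plaques + nrow(sim$plaques)
    }
    seed <- seed + 1
  }
  agg <- aggregate_profiles(profs)
  # enrichment near plaques: the aggregate decreases from ring 1 outward
  expect_gt(agg$mean_density[1], agg$mean_density[nrow(agg)])
  est <- estimate_decay_length(agg)
  expect_lt(abs(est$tau_um - 40) / 40, 0.25)
  expect_gt(est$amplitude, 1)      # several-fold edge enrichment recovered
  expect_gt(est$baseline, 250)     # plateau near the 300/mm^2 background
  expect_lt(est$baseline, 450)
})

test_that("uniform background fields show no radial structure", {
  # no enrichment: every ring's density is the background within Poisson error
  dens1 <- dens_last <- numeric(0)
  for (seed in 1:30) {
    cfg <- simulation_config(seed = seed, width = 1200, height = 1200,
                             plaque_intensity = 1, enrichment_amplitude = 0)
    sim <- simulate_field(cfg)
    if (nrow(sim$plaques) == 0) next
    profs <- profile_field(sim$cells, sim$plaques, field_spec(1200, 1200, 0))
    for (pr in profs) {
      if (nrow(pr) < 5) next
      dens1 <- c(dens1, pr$density_per_mm2[1])
      dens_last <- c(dens_last, pr$density_per_mm2[nrow(pr)])
    }
  }
  # means of first/last ring densities both near the 300/mm^2 background
  se1 <- stats::sd(dens1) / sqrt(length(dens1))
  se2 <- stats::sd(dens_last) / sqrt(length(dens_last))
  expect_lt(abs(mean(dens1) - 300), 3 * se1)
  expect_lt(abs(mean(dens_last) - 300), 3 * se2)
})
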