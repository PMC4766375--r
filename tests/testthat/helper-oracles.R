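# Independent oracles used to validate the analytic implementations.
# These deliberately avoid the package's own code paths.

# Monte-Carlo estimate of the fraction of a cell disk inside an annulus:
# sample points uniformly in the cell disk and classify by distance.
mc_disk_fraction_in_annulus <- function(cell_x, cell_y, cell_r,
                                        centre_x, centre_y,
                                        inner_r, outer_r, n = 1e5) {
  r <- cell_r * sqrt(stats::runif(n))
  th <- 2 * pi * stats::runif(n)
  d <- sqrt((cell_x + r * cos(th) - centre_x)^2 +
              (cell_y + r * sin(th) - centre_y)^2)
  mean(d >= inner_r & d < outer_r)
}

# Monte-Carlo lens area: sample in disk 1, count points inside disk 2.
mc_lens_area <- function(x1, y1, r1, x2, y2, r2, n = 1e6) {
  r <- r1 * sqrt(stats::runif(n))
  th <- 2 * pi * stats::runif(n)
  d2 <- (x1 + r * cos(th) - x2)^2 + (y1 + r * sin(th) - y2)^2
  mean(d2 <= r2^2) * pi * r1^2
}

# Pixel-sampling fraction oracle at fixed resolution (deterministic).
pixel_disk_fraction_in_annulus <- function(cell_x, cell_y, cell_r,
                                           centre_x, centre_y,
                                           inner_r, outer_r, res = 0.1) {
  xs <- seq(cell_x - cell_r, cell_x + cell_r, by = res)
  ys <- seq(cell_y - cell_r, cell_y + cell_r, by = res)
  g <- expand.grid(x = xs, y = ys)
  in_cell <- (g$x - cell_x)^2 + (g$y - cell_y)^2 <= cell_r^2
  d <- sqrt((g$x[in_cell] - centre_x)^2 + (g$y[in_cell] - centre_y)^2)
  mean(d >= inner_r & d < outer_r)
}

# Exhaustive pair-classification Kendall tau-b (explicit double loop).
brute_force_tau_b <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- txy <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) txy <- txy + 1
      else if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) nc <- nc + 1
      else nd <- nd + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tx - txy) * (n0 - ty - txy))
}

# Brute-force Pearson correlation from raw covariance sums.
brute_force_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Count cells whose majority disk area lies inside the circle of radius R
# about (px, py), using the exact lens area directly (ties count as inside,
# matching the inward tie convention).
disk_fraction_in_circle_count <- function(cells, px, py, R) {
  fr <- circle_circle_intersection_area(cells$x_um, cells$y_um,
                                        cells$radius_um, px, py, R) /
    (pi * cells$radius_um^2)
  as.integer(sum(fr >= 0.5))
}

# Count cells whose majority disk area lies inside the circle of radius R
# about (px, py), by pixel sampling (independent of the package geometry).
pixel_cells_within_circle <- function(cells, px, py, R, res = 0.25) {
  sum(vapply(seq_len(nrow(cells)), function(i) {
    cx <- cells$x_um[i]; cy <- cells$y_um[i]; cr <- cells$radius_um[i]
    xs <- seq(cx - cr, cx + cr, by = res)
    ys <- seq(cy - cr, cy + cr, by = res)
    g <- expand.grid(x = xs, y = ys)
    inc <- (g$x - cx)^2 + (g$y - cy)^2 <= cr^2
    mean((g$x[inc] - px)^2 + (g$y[inc] - py)^2 <= R^2) >= 0.5
  }, logical(1)))
}
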