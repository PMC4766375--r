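#' Exact area of intersection of two disks
#'
#' Computes the lens-shaped area shared by two disks in the plane, in the
#' same squared units as the input coordinates (square microns throughout
#' this package). The computation is closed-form and exact up to floating
#' point: the standard circular-segment decomposition of the lens.
#'
#' @param x1,y1,r1 Centre and radius of the first disk (microns).
#' @param x2,y2,r2 Centre and radius of the second disk (microns).
#'
#' @return Intersection area in square microns. Vectorised over all
#'   arguments.
#'
#' @details
#' Degenerate containment (one disk entirely inside the other) returns the
#' area of the smaller disk; disjoint disks return 0. Radii must be
#' strictly positive and all inputs finite.
#'
#' @examples
#' circle_circle_intersection_area(0, 0, 1, 1, 0, 1) # two unit circles, d = 1
#' circle_circle_intersection_area(0, 0, 2, 5, 0, 2) # disjoint -> 0
#' @export
circle_circle_intersection_area <- function(x1, y1, r1, x2, y2, r2) {
  n <- max(length(x1), length(y1), length(r1), length(x2), length(y2), length(r2))
  x1 <- rep_len(x1, n); y1 <- rep_len(y1, n); r1 <- rep_len(r1, n)
  x2 <- rep_len(x2, n); y2 <- rep_len(y2, n); r2 <- rep_len(r2, n)
  if (!all(is.finite(c(x1, y1, r1, x2, y2, r2)))) {
    stop("invalid geometry: all coordinates and radii must be finite", call. = FALSE)
  }
  if (any(r1 <= 0) || any(r2 <= 0)) {
    stop("invalid geometry: radii must be strictly positive", call. = FALSE)
  }
  d <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  area <- numeric(n)

  disjoint <- d >= r1 + r2
  contained <- d <= abs(r1 - r2)
  area[contained] <- pi * pmin(r1[contained], r2[contained])^2

  lens <- !disjoint & !contained
  if (any(lens)) {
    dd <- d[lens]; a <- r1[lens]; b <- r2[lens]
    # clamp acos arguments: roundoff can push them infinitesimally past [-1, 1]
    ca <- pmin(1, pmax(-1, (dd^2 + a^2 - b^2) / (2 * dd * a)))
    cb <- pmin(1, pmax(-1, (dd^2 + b^2 - a^2) / (2 * dd * b)))
    k <- (-dd + a + b) * (dd + a - b) * (dd - a + b) * (dd + a + b)
    area[lens] <- a^2 * acos(ca) + b^2 * acos(cb) - 0.5 * sqrt(pmax(0, k))
  }
  area
}

#' Fraction of a cell disk lying inside an annulus
#'
#' Given a cell modelled as a disk and an annulus (ring) between two
#' concentric circles around a reference centre, returns the fraction of
#' the cell's area that falls inside the annulus. This is the quantity the
#' majority-area assignment rule of [profile_plaque()] is built on: a cell
#' straddling a ring boundary is attributed to the ring holding more than
#' half of its area.
#'
#' @param cell_x,cell_y,cell_r Centre and radius of the cell disk (microns).
#' @param centre_x,centre_y Annulus centre (typically a plaque centre).
#' @param inner_r,outer_r Annulus radii; must satisfy
#'   `0 <= inner_r < outer_r`. `inner_r = 0` degenerates to a full disk.
#'
#' @return Fraction in \[0, 1\]. Vectorised.
#' @examples
#' # cell of radius 5 fully inside the ring [10, 30)
#' disk_fraction_in_annulus(20, 0, 5, 0, 0, 10, 30)
#' @export
disk_fraction_in_annulus <- function(cell_x, cell_y, cell_r,
                                     centre_x, centre_y,
                                     inner_r, outer_r) {
  if (any(inner_r < 0) || any(inner_r >= outer_r)) {
    stop("invalid annulus: need 0 <= inner_r < outer_r", call. = FALSE)
  }
  outer <- circle_circle_intersection_area(cell_x, cell_y, cell_r,
                                           centre_x, centre_y, outer_r)
  inner <- ifelse(rep_len(inner_r, length(outer)) > 0,
                  circle_circle_intersection_area(
                    cell_x, cell_y, cell_r, centre_x, centre_y,
                    pmax(inner_r, .Machine$double.eps)),
                  0)
  frac <- (outer - inner) / (pi * cell_r^2)
  pmin(1, pmax(0, frac))
}

# Cumulative fraction of a cell disk inside the circle of radius r about
# (cx, cy); r = 0 allowed (returns 0). Internal helper for assignment.
disk_fraction_in_circle <- function(cell_x, cell_y, cell_r, cx, cy, r) {
  n <- max(length(cell_x), length(r))
  r <- rep_len(r, n)
  out <- numeric(n)
  pos <- r > 0
  if (any(pos)) {
    out[pos] <- circle_circle_intersection_area(
      rep_len(cell_x, n)[pos], rep_len(cell_y, n)[pos], rep_len(cell_r, n)[pos],
      cx, cy, r[pos]) / (pi * rep_len(cell_r, n)[pos]^2)
  }
  pmin(1, pmax(0, out))
}
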