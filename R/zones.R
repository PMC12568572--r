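## Peripapillary zone geometry: annuli at 0.5-PD steps from the disc
## border and S/N/I/T quadrants of the 0.5–2.5 PD band.
##
## Distances are measured from the disc *border*, with the border radius
## defined by the circle of equal area when the disc fit is elliptical.
## Quadrants split the plane along the two 45-degree diagonals through the
## disc center; nasal/temporal depend on eye laterality (nasal is toward
## the nose: +x in OD images, -x in OS images under the top-left-origin,
## x-rightward convention).

.annulus_bounds <- list(c(0.5, 1.0), c(1.0, 1.5), c(1.5, 2.0), c(2.0, 2.5))
.annulus_labels <- c("0.5–1.0 PD", "1.0–1.5 PD",
                     "1.5–2.0 PD", "2.0–2.5 PD")
.quadrant_labels <- c("Superior", "Nasal", "Inferior", "Temporal")

## Accept either a disc_spec or a fitted ellipse.
.disc_geom <- function(disc) {
  if (inherits(disc, "disc_spec")) {
    list(cx = disc$center[1], cy = disc$center[2], r_eq = disc$disc_radius)
  } else {
    list(cx = disc$cx, cy = disc$cy, r_eq = sqrt(disc$a * disc$b))
  }
}

#' Disc diameter (PD) of a fitted disc ellipse
#'
#' The diameter of the circle with the same area as the ellipse,
#' `2 * sqrt(a * b)`; the unit of peripapillary distances.
#' @param disc_ellipse Ellipse `list(cx, cy, a, b, theta)` (semi-axes px)
#'   or a [disc_spec()].
#' @return PD in px.
#' @export
disc_diameter_pd <- function(disc_ellipse) {
  g <- .disc_geom(disc_ellipse)
  2 * g$r_eq
}

#' Peripapillary annulus region
#'
#' Pixels whose distance from the disc border (radial distance from the
#' disc center minus the equal-area border radius) lies in
#' `[inner_pd * PD, outer_pd * PD)`.
#'
#' @param disc Disc ellipse or [disc_spec()].
#' @param inner_pd,outer_pd Bounds in PD units, `0 <= inner < outer`.
#' @param dim Raster `c(height, width)`.
#' @return Logical region matrix; a warning is issued if it is empty
#'   (annulus fully outside the frame).
#' @export
annulus_region <- function(disc, inner_pd, outer_pd, dim) {
  if (!(inner_pd >= 0 && inner_pd < outer_pd)) {
    stopf("annulus_region: need 0 <= inner < outer")
  }
  g <- .disc_geom(disc)
  pd <- 2 * g$r_eq
  d <- radial_dist(dim[1], dim[2], g$cx, g$cy) - g$r_eq
  reg <- d >= inner_pd * pd & d < outer_pd * pd
  if (!any(reg)) warnf("annulus %.2g-%.2g PD lies outside the frame",
                       inner_pd, outer_pd)
  reg
}

#' Peripapillary quadrant region
#'
#' The plane is split along the two 45-degree diagonals through the disc
#' center; `Superior` opens upward, `Inferior` downward, `Nasal` toward
#' the nose (+x in OD, -x in OS) and `Temporal` opposite. The region is
#' restricted to the peripapillary band (default 0.5–2.5 PD from the disc
#' border). Boundary pixels are assigned by half-open angular intervals so
#' the four quadrants partition the band exactly.
#'
#' @param disc Disc ellipse or [disc_spec()].
#' @param quadrant One of `"Superior"`, `"Nasal"`, `"Inferior"`,
#'   `"Temporal"`.
#' @param eye `"OD"` or `"OS"`.
#' @param dim Raster `c(height, width)`.
#' @param band Annulus bounds (PD units) of the peripapillary band.
#' @return Logical region matrix.
#' @export
quadrant_region <- function(disc, quadrant, eye, dim, band = c(0.5, 2.5)) {
  quadrant <- match.arg(quadrant, .quadrant_labels)
  if (!eye %in% c("OD", "OS")) {
    stopf("quadrant_region: unknown eye laterality '%s'", eye)
  }
  g <- .disc_geom(disc)
  gr <- coord_grid(dim[1], dim[2])
  dx <- gr$x - g$cx; dy <- gr$y - g$cy
  phi <- atan2(dy, dx)                    # y downward: positive = below
  right <- phi >= -pi / 4 & phi < pi / 4
  down <- phi >= pi / 4 & phi < 3 * pi / 4
  up <- phi >= -3 * pi / 4 & phi < -pi / 4
  left <- !(right | down | up)
  sel <- switch(quadrant,
    Superior = up,
    Inferior = down,
    Nasal = if (eye == "OD") right else left,
    Temporal = if (eye == "OD") left else right
  )
  sel & annulus_region(disc, band[1], band[2], dim)
}

#' Default peripapillary zones for one eye
#'
#' The four 0.5-PD annuli (labels `"0.5–1.0 PD"` … `"2.0–2.5 PD"`) and the
#' four quadrants of the 0.5–2.5 PD band.
#' @param disc Disc ellipse or [disc_spec()].
#' @param eye `"OD"` or `"OS"`.
#' @param dim Raster `c(height, width)`.
#' @return Named list of logical region matrices.
#' @export
peripapillary_zones <- function(disc, eye, dim) {
  zones <- list()
  for (i in seq_along(.annulus_bounds)) {
    b <- .annulus_bounds[[i]]
    zones[[.annulus_labels[i]]] <-
      suppressWarnings(annulus_region(disc, b[1], b[2], dim))
  }
  for (q in .quadrant_labels) {
    zones[[q]] <- quadrant_region(disc, q, eye, dim)
  }
  zones
}
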