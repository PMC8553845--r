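#' Hexagonal facet-lattice geometry
#'
#' The ommatidial mosaic of an apposition compound eye is a (locally)
#' hexagonal lattice.  Positions on the eye surface are expressed in
#' *facet-row coordinates* `(u, v)`: `u` counts facets along the first row
#' axis, `v` along the second, with the two axes at 60 degrees.  Integer
#' `(u, v)` denote facet centres; fractional values denote sub-facet
#' positions such as a pseudopupil centre.  Internally all distances are in
#' facet units (centre-to-centre pitch = 1); micrometres enter only through
#' a [lattice_frame()] used for image registration.
#'
#' The working orthogonal basis puts the u-axis horizontal and the v-axis
#' at +60 degrees, so `x` is horizontal and `y` vertical in the visual
#' field.  The orientation of the real facet rows in an image is absorbed
#' into `lattice_frame$orientation_deg`, not into this convention.
#'
#' @param u,v Numeric vectors (recycled) of facet-row coordinates.
#' @return `lattice_coord()` returns a data.frame with columns `u`, `v`.
#' @examples
#' lattice_to_cart(lattice_coord(0, 1))   # (0.5, sqrt(3)/2)
#' @export
lattice_coord <- function(u, v) {
  if (!is.numeric(u) || !is.numeric(v)) {
    stop("lattice coordinates must be numeric", call. = FALSE)
  }
  data.frame(u = as.numeric(u), v = as.numeric(v))
}

#' @rdname lattice_coord
#' @param x,y Numeric vectors, planar coordinates in facet units.
#' @return `planar_point()` returns a data.frame with columns `x`, `y`.
#' @export
planar_point <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("planar coordinates must be numeric", call. = FALSE)
  }
  data.frame(x = as.numeric(x), y = as.numeric(y))
}

check_finite <- function(x, what) {
  if (!all(is.finite(unlist(x)))) {
    stop("non-finite ", what, call. = FALSE)
  }
}

#' Convert facet-row coordinates to the planar working basis
#'
#' Linear axial-coordinate embedding with axes at 60 degrees:
#' `x = u + v/2`, `y = v * sqrt(3)/2`.  Exactly invertible by
#' [cart_to_lattice()].
#'
#' @param coord Data frame with columns `u`, `v` (see [lattice_coord()]).
#' @return Data frame with columns `x`, `y` in facet units.
#' @export
lattice_to_cart <- function(coord) {
  check_finite(coord[c("u", "v")], "lattice coordinate")
  planar_point(coord$u + coord$v / 2, coord$v * sqrt(3) / 2)
}

#' @rdname lattice_to_cart
#' @param point Data frame with columns `x`, `y` (see [planar_point()]).
#' @export
cart_to_lattice <- function(point) {
  check_finite(point[c("x", "y")], "planar point")
  v <- point$y * 2 / sqrt(3)
  lattice_coord(point$x - v / 2, v)
}

#' The three hexagonal row axes
#'
#' Unit steps along the three hexagonally oriented facet rows: `(1, 0)`,
#' `(0, 1)` and `(1, -1)` in facet-row coordinates.  Each maps to a planar
#' vector of length one, and the pairwise planar angles are 60/120 degrees.
#' Local interommatidial angles are averaged over these three axes.
#'
#' @return A `lattice_coord` data.frame with three rows.
#' @export
hex_axes <- function() {
  lattice_coord(c(1, 0, 1), c(0, 1, -1))
}

#' Snap a fractional lattice position to the nearest facet centre
#'
#' Returns the integer lattice point minimising planar distance.  Ties
#' (points equidistant from several facet centres) are broken by the
#' smallest `u`, then the smallest `v`.
#'
#' @param coord Fractional `lattice_coord` data.frame (vectorised).
#' @return Integer-valued `lattice_coord` data.frame.
#' @export
nearest_facet <- function(coord) {
  check_finite(coord[c("u", "v")], "lattice coordinate")
  p <- lattice_to_cart(coord)
  u0 <- floor(coord$u)
  v0 <- floor(coord$v)
  best_u <- u0
  best_v <- v0
  best_d <- rep(Inf, length(u0))
  # candidate integer points around the fractional position; the nearest
  # facet centre always lies within the floor cell's 2x2 corner set plus
  # the adjacent ring (hex Voronoi cells can cross the (u,v) unit cell)
  for (du in -1:2) {
    for (dv in -1:2) {
      cu <- u0 + du
      cv <- v0 + dv
      dx <- (cu + cv / 2) - p$x
      dy <- cv * sqrt(3) / 2 - p$y
      d <- dx * dx + dy * dy
      better <- d < best_d - 1e-12 |
        (abs(d - best_d) <= 1e-12 &
           (cu < best_u | (cu == best_u & cv < best_v)))
      best_u[better] <- cu[better]
      best_v[better] <- cv[better]
      best_d[better] <- d[better]
    }
  }
  lattice_coord(best_u, best_v)
}

#' Registration metadata tying image pixels to the facet lattice
#'
#' A similarity transform between pixel coordinates `(row, col)` and the
#' planar lattice basis: `pitch_px` pixels per facet, a rotation of the
#' u-axis relative to the image horizontal, and the pixel position of the
#' lattice origin.  Solved from landmark correspondences by
#' [solve_lattice_frame()].
#'
#' @param pitch_px Pixels per facet pitch (> 0).
#' @param orientation_deg Angle (degrees) of the u-axis relative to the
#'   image column direction, measured counter-clockwise on the displayed
#'   image (i.e. with the row axis pointing down).
#' @param origin_px Numeric length-2 `(row, col)` of the lattice origin.
#' @param pitch_um Optional physical facet pitch in micrometres.
#' @return An object of class `"lattice_frame"`.
#' @export
lattice_frame <- function(pitch_px, orientation_deg = 0,
                          origin_px = c(0, 0), pitch_um = NA_real_) {
  if (!is.numeric(pitch_px) || length(pitch_px) != 1 ||
      !is.finite(pitch_px) || pitch_px <= 0) {
    stop("pitch_px must be a single positive number", call. = FALSE)
  }
  if (length(origin_px) != 2 || !all(is.finite(origin_px))) {
    stop("origin_px must be finite (row, col)", call. = FALSE)
  }
  structure(
    list(pitch_px = pitch_px,
         orientation_deg = as.numeric(orientation_deg),
         origin_px = as.numeric(origin_px),
         pitch_um = as.numeric(pitch_um)),
    class = "lattice_frame"
  )
}

#' @export
print.lattice_frame <- function(x, ...) {
  cat(sprintf(
    "<lattice_frame> pitch %.4g px/facet, orientation %.3g deg, origin (%.4g, %.4g) px\n",
    x$pitch_px, x$orientation_deg, x$origin_px[1], x$origin_px[2]))
  invisible(x)
}
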