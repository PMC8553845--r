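#' Parametric acuity field of a compound eye
#'
#' Ground-truth interommatidial angle as a function of visual-field
#' position.  The field is flat (at its minimum) on a square plateau of
#' half-width `plateau_halfwidth_deg` around the frontal axis and rises
#' linearly outside it, with separate slopes for azimuth, the dorsal and
#' the ventral visual field:
#'
#' \deqn{\Delta\varphi(a, e) = \Delta\varphi_{min}
#'   + s_{az} \max(|a| - w, 0)
#'   + s_{d} \max(e - w, 0)
#'   + s_{v} \max(-e - w, 0)}
#'
#' This piecewise-linear form is continuous, everywhere at least
#' `dphi_min_deg`, and separable in azimuth and elevation, which lets the
#' gaze field of a synthetic eye be integrated in closed form
#' (see [build_eye()]).
#'
#' @param dphi_min_deg Minimum interommatidial angle, degrees (> 0).
#' @param plateau_halfwidth_deg Half-width of the flat acute-zone plateau,
#'   degrees (>= 0).
#' @param slope_az Rise per degree of |azimuth| beyond the plateau (>= 0).
#' @param slope_dorsal Rise per degree of elevation above the plateau (>= 0).
#' @param slope_ventral Rise per degree below the plateau (>= 0).
#' @return An object of class `"acuity_field"`.
#' @seealso [honeybee_field()], [uniform_field()], [eval_acuity()]
#' @export
acuity_field <- function(dphi_min_deg,
                         plateau_halfwidth_deg = 0,
                         slope_az = 0,
                         slope_dorsal = 0,
                         slope_ventral = 0) {
  stopifnot(is.numeric(dphi_min_deg), length(dphi_min_deg) == 1)
  if (!is.finite(dphi_min_deg) || dphi_min_deg <= 0) {
    stop("dphi_min_deg must be positive", call. = FALSE)
  }
  if (plateau_halfwidth_deg < 0 || slope_az < 0 ||
      slope_dorsal < 0 || slope_ventral < 0) {
    stop("plateau half-width and slopes must be non-negative", call. = FALSE)
  }
  structure(
    list(dphi_min_deg = dphi_min_deg,
         plateau_halfwidth_deg = plateau_halfwidth_deg,
         slope_az = slope_az,
         slope_dorsal = slope_dorsal,
         slope_ventral = slope_ventral),
    class = "acuity_field"
  )
}

#' Honeybee-forager acute-zone preset
#'
#' Derived constants for a synthetic honeybee forager eye: a 1.30 degree
#' minimum on a 10 degree plateau around the frontal axis, a shallow
#' azimuthal rise (0.00875 deg/deg), a steep dorsal rise (0.10 deg/deg)
#' and a gentle ventral rise (0.015 deg/deg).  The numbers are constructed
#' so that a 10-degree-step goniometer scan processed by [build_map()]
#' recovers a frontal minimum of 1.3 degrees, equatorial values at or
#' below 1.7 degrees out to 40 degrees azimuth, ventral values at or below
#' 1.9 degrees down to -30 degrees elevation, and dorsal values at or
#' above 2 degrees by +20 degrees elevation.  Because a 10-degree step
#' harmonically averages the local field, the plateau is required for the
#' recovered minimum to equal the field minimum exactly.
#'
#' @return An `"acuity_field"` object.
#' @export
honeybee_field <- function() {
  acuity_field(dphi_min_deg = 1.30,
               plateau_halfwidth_deg = 10,
               slope_az = 0.00875,
               slope_dorsal = 0.10,
               slope_ventral = 0.015)
}

#' @rdname honeybee_field
#' @param g_deg Constant interommatidial angle in degrees.
#' @export
uniform_field <- function(g_deg) {
  acuity_field(dphi_min_deg = g_deg)
}

#' Evaluate an acuity field
#'
#' @param field An [acuity_field()].
#' @param az_deg,el_deg Azimuth and elevation in degrees (vectorised).
#' @return Interommatidial angle(s) in degrees.
#' @examples
#' eval_acuity(honeybee_field(), 0, 0)    # 1.30
#' eval_acuity(honeybee_field(), 0, 20)   # 2.30
#' @export
eval_acuity <- function(field, az_deg, el_deg) {
  stopifnot(inherits(field, "acuity_field"))
  check_finite(list(az_deg, el_deg), "angle")
  w <- field$plateau_halfwidth_deg
  field$dphi_min_deg +
    field$slope_az * pmax(abs(az_deg) - w, 0) +
    field$slope_dorsal * pmax(el_deg - w, 0) +
    field$slope_ventral * pmax(-el_deg - w, 0)
}

#' @export
print.acuity_field <- function(x, ...) {
  cat(sprintf(
    paste0("<acuity_field> min %.4g deg, plateau half-width %.4g deg,\n",
           "  slopes az %.4g, dorsal %.4g, ventral %.4g deg/deg\n"),
    x$dphi_min_deg, x$plateau_halfwidth_deg,
    x$slope_az, x$slope_dorsal, x$slope_ventral))
  invisible(x)
}
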