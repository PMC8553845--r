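#' Locate the pseudopupil centre in a frame
#'
#' Thresholds the frame at `min + threshold_frac * (max - min)`, labels
#' the connected pixel set (4-connectivity) containing the global
#' maximum, and returns the intensity-weighted centroid of that set with
#' the threshold level subtracted as background.  For `mode = "dark"`
#' (a dark principal pseudopupil on a pale eye) the identical procedure
#' runs on the inverted frame.  The estimator is invariant to affine
#' rescaling of the intensities.
#'
#' @param frame An `"image_frame"`.
#' @param threshold_frac Relative threshold in (0, 1).
#' @param mode `"bright"` for a fluorescent pseudopupil, `"dark"` for a
#'   principal (dark) pseudopupil.
#' @return A list of class `"detection_result"`: `centre_px` (row, col,
#'   sub-pixel), `n_pixels`, `peak_value` (original intensity at the
#'   extremum).
#' @export
detect_centre <- function(frame, threshold_frac = 0.5,
                          mode = c("bright", "dark")) {
  stopifnot(inherits(frame, "image_frame"))
  mode <- match.arg(mode)
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop("threshold_frac must be in (0, 1)", call. = FALSE)
  }
  m <- frame$intensities
  peak_value <- if (mode == "dark") min(m) else max(m)
  if (mode == "dark") m <- max(m) - m
  lo <- min(m)
  hi <- max(m)
  if (hi - lo <= 0) {
    stop("flat frame: no pseudopupil signal", call. = FALSE)
  }
  thr <- lo + threshold_frac * (hi - lo)
  mask <- m >= thr
  labels <- EBImage::bwlabel(mask)
  imax <- which.max(m)
  comp <- labels == labels[imax]
  w <- m[comp] - thr
  rows <- row(m)[comp]
  cols <- col(m)[comp]
  if (sum(w) <= 0) {  # single-pixel component exactly at threshold
    ctr <- c(rows[1], cols[1])
  } else {
    ctr <- c(sum(rows * w), sum(cols * w)) / sum(w)
  }
  structure(list(centre_px = ctr, n_pixels = sum(comp),
                 peak_value = peak_value),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> centre (%.3f, %.3f) px, %d px, peak %.4g\n",
              x$centre_px[1], x$centre_px[2], x$n_pixels, x$peak_value))
  invisible(x)
}

# bilinear interpolation of a matrix at fractional (row, col)
bilinear <- function(m, r, c) {
  r0 <- pmin(pmax(floor(r), 1), nrow(m) - 1)
  c0 <- pmin(pmax(floor(c), 1), ncol(m) - 1)
  fr <- r - r0
  fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Relative-intensity profile along a line
#'
#' Samples the frame by bilinear interpolation at `n_samples` equispaced
#' points from `p0_px` to `p1_px` and min-max normalises the values to
#' [0, 1] ("relative pixel values").  Positions are path length in
#' micrometres via the frame's pixel scale.
#'
#' @param frame An `"image_frame"`.
#' @param p0_px,p1_px Numeric `(row, col)` endpoints, inside the frame.
#' @param n_samples Number of samples (>= 3).
#' @return A list of class `"intensity_profile"`: `positions` (um),
#'   `values` in [0, 1], `unit`, and `flat` (TRUE when the raw line had
#'   zero range, in which case values are all 0).
#' @export
line_profile <- function(frame, p0_px, p1_px, n_samples = 200) {
  stopifnot(inherits(frame, "image_frame"))
  if (n_samples < 3) stop("n_samples must be >= 3", call. = FALSE)
  m <- frame$intensities
  ends <- rbind(p0_px, p1_px)
  if (any(ends[, 1] < 1 | ends[, 1] > nrow(m) |
            ends[, 2] < 1 | ends[, 2] > ncol(m))) {
    stop("profile endpoints outside the frame", call. = FALSE)
  }
  tt <- seq(0, 1, length.out = n_samples)
  r <- p0_px[1] + tt * (p1_px[1] - p0_px[1])
  c <- p0_px[2] + tt * (p1_px[2] - p0_px[2])
  vals <- bilinear(m, r, c)
  len_um <- sqrt(sum((p1_px - p0_px)^2)) * frame$pixel_scale_um
  rng <- max(vals) - min(vals)
  flat <- rng <= 0
  vals <- if (flat) rep(0, n_samples) else (vals - min(vals)) / rng
  structure(list(positions = tt * len_um, values = vals,
                 unit = "um", flat = flat),
            class = "intensity_profile")
}

#' Position of a profile's maximum
#'
#' Returns the position of the maximum sample value; ties (plateaus) are
#' broken by the smallest position.  Callers analysing a dark pseudopupil
#' pass an inverted profile.
#'
#' @param profile An `"intensity_profile"` (or any list with `positions`
#'   and `values`).
#' @return Position of the maximum, in the profile's unit.
#' @export
profile_peak <- function(profile) {
  v <- profile$values
  if (isTRUE(profile$flat) || max(v) - min(v) <= 0) {
    stop("flat profile: no peak", call. = FALSE)
  }
  profile$positions[which.max(v)]
}

#' Full width at half maximum of a profile
#'
#' Distance between the two half-maximum crossings nearest the peak,
#' linearly interpolated between samples.  Half maximum is
#' `(min + max) / 2` of the profile values.
#'
#' @param profile An `"intensity_profile"`.
#' @return Width in the profile's position unit.
#' @export
profile_fwhm <- function(profile) {
  v <- profile$values
  p <- profile$positions
  if (isTRUE(profile$flat) || max(v) - min(v) <= 0) {
    stop("flat profile: no width", call. = FALSE)
  }
  half <- (max(v) + min(v)) / 2
  ipk <- which.max(v)
  cross <- function(idx) {
    # linear interpolation of the half-max crossing between idx, idx + 1
    p[idx] + (half - v[idx]) / (v[idx + 1] - v[idx]) * (p[idx + 1] - p[idx])
  }
  left <- NA_real_
  if (ipk > 1) {
    for (i in (ipk - 1):1) {
      if (v[i] <= half && v[i + 1] >= half) {
        left <- cross(i)
        break
      }
    }
  }
  right <- NA_real_
  if (ipk < length(v)) {
    for (i in ipk:(length(v) - 1)) {
      if (v[i] >= half && v[i + 1] <= half) {
        right <- cross(i)
        break
      }
    }
  }
  if (!is.finite(left) || !is.finite(right)) {
    stop("profile does not cross half maximum on both sides of the peak",
         call. = FALSE)
  }
  right - left
}

#' Physical distance between two detected centres
#'
#' @param r1,r2 `"detection_result"` objects from the same frame geometry.
#' @param pixel_scale_um Micrometres per pixel.
#' @return Euclidean distance in micrometres.
#' @export
centre_offset <- function(r1, r2, pixel_scale_um) {
  sqrt(sum((r1$centre_px - r2$centre_px)^2)) * pixel_scale_um
}

#' Convert a pixel position to facet-row coordinates
#'
#' Applies the inverse of the frame's similarity transform: translate to
#' the lattice origin, rotate by `-orientation_deg`, scale by the pitch in
#' pixels per facet, then [cart_to_lattice()].
#'
#' @param centre_px Numeric `(row, col)`.
#' @param frame_ref A [lattice_frame()].
#' @return One-row `lattice_coord` data.frame.
#' @export
pixel_to_lattice <- function(centre_px, frame_ref) {
  stopifnot(inherits(frame_ref, "lattice_frame"))
  if (frame_ref$pitch_px <= 0) {
    stop("lattice frame has non-positive pitch", call. = FALSE)
  }
  th <- frame_ref$orientation_deg * pi / 180
  xr <- (centre_px[2] - frame_ref$origin_px[2]) / frame_ref$pitch_px
  yr <- -(centre_px[1] - frame_ref$origin_px[1]) / frame_ref$pitch_px
  cart_to_lattice(planar_point(cos(th) * xr + sin(th) * yr,
                               -sin(th) * xr + cos(th) * yr))
}

#' Solve the pixel-to-lattice registration from landmarks
#'
#' Least-squares similarity transform (rotation + uniform scale +
#' translation) mapping integer landmark lattice coordinates to their
#' pixel positions, as marked by fluorescent crystals on the cornea.
#' Solved in closed form as a complex linear regression.
#'
#' @param landmark_px Two-column matrix or data.frame of `(row, col)`
#'   pixel positions (>= 2 rows).
#' @param landmark_lattice `lattice_coord` data.frame of the
#'   corresponding integer facet coordinates.
#' @return A [lattice_frame()] with attribute `residual_rms_px`.
#' @export
solve_lattice_frame <- function(landmark_px, landmark_lattice) {
  landmark_px <- as.matrix(landmark_px)
  if (nrow(landmark_px) < 2 || nrow(landmark_lattice) < 2) {
    stop("registration needs at least 2 landmark correspondences",
         call. = FALSE)
  }
  if (nrow(landmark_px) != nrow(landmark_lattice)) {
    stop("landmark lists differ in length", call. = FALSE)
  }
  q <- lattice_to_cart(landmark_lattice)
  zq <- complex(real = q$x, imaginary = q$y)
  # image row axis points down: flip to a right-handed basis
  zp <- complex(real = landmark_px[, 2], imaginary = -landmark_px[, 1])
  vq <- zq - mean(zq)
  vp <- zp - mean(zp)
  denom <- sum(Conj(vq) * vq)
  if (Mod(denom) < 1e-12) {
    stop("degenerate landmark set: all lattice positions coincide",
         call. = FALSE)
  }
  a <- sum(Conj(vq) * vp) / denom
  if (Mod(a) < 1e-12) {
    stop("degenerate landmark set: zero scale", call. = FALSE)
  }
  b <- mean(zp) - a * mean(zq)
  resid <- Mod(zp - (a * zq + b))
  fr <- lattice_frame(pitch_px = Mod(a),
                      orientation_deg = Arg(a) * 180 / pi,
                      origin_px = c(-Im(b), Re(b)))
  attr(fr, "residual_rms_px") <- sqrt(mean(resid^2))
  fr
}

#' Facet diameter from a line across several facets
#'
#' The standard manual measurement: a straight line drawn through
#' `n_facets` ommatidia in focus, divided by the count.  Lines through
#' fewer than 5 or more than 8 facets are allowed but warned about.
#'
#' @param p0_px,p1_px Numeric `(row, col)` line endpoints.
#' @param n_facets Number of facets the line crosses (>= 2).
#' @param pixel_scale_um Micrometres per pixel.
#' @return Mean facet diameter in micrometres.
#' @export
facet_diameter_line <- function(p0_px, p1_px, n_facets, pixel_scale_um) {
  if (n_facets < 2) stop("n_facets must be >= 2", call. = FALSE)
  len <- sqrt(sum((p1_px - p0_px)^2))
  if (len <= 0) stop("zero-length measurement line", call. = FALSE)
  if (n_facets < 5 || n_facets > 8) {
    warning("facet-diameter lines are usually drawn through 5-8 ommatidia",
            call. = FALSE)
  }
  len * pixel_scale_um / n_facets
}
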