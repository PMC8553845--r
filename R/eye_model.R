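#' @keywords internal
#' @name gaze-integration
#' @details
#' The gaze field of a synthetic eye is obtained by integrating the
#' reciprocal acuity field along facet rows.  For the piecewise-linear
#' [acuity_field()] the cumulative integrals have closed form: linear
#' inside the plateau and logarithmic outside it, and are therefore exact
#' and exactly invertible (no numerical quadrature is involved).
NULL

# planar position reached after integrating 1/f from 0 to angle t, where
# f(t) = c + s_pos*max(t - w, 0) + s_neg*max(-t - w, 0)
angpos_1d <- function(t, c, s_pos, s_neg, w) {
  a <- abs(t)
  s <- ifelse(t >= 0, s_pos, s_neg)
  inside <- pmin(a, w) / c
  excess <- pmax(a - w, 0)
  outside <- ifelse(s > 0, log1p(s * excess / c) / s, excess / c)
  sign(t) * (inside + outside)
}

# inverse of angpos_1d: the angle whose integrated planar position is p
anginv_1d <- function(p, c, s_pos, s_neg, w) {
  q <- abs(p)
  s <- ifelse(p >= 0, s_pos, s_neg)
  pw <- w / c
  inside <- pmin(q, pw) * c
  excess <- pmax(q - pw, 0)
  outside <- ifelse(s > 0, c * expm1(s * excess) / s, c * excess)
  sign(p) * (inside + outside)
}

# elevation <-> planar y along the frontal meridian
elev_to_y <- function(field, el_deg) {
  angpos_1d(el_deg, field$dphi_min_deg, field$slope_dorsal,
            field$slope_ventral, field$plateau_halfwidth_deg)
}

y_to_elev <- function(field, y) {
  anginv_1d(y, field$dphi_min_deg, field$slope_dorsal,
            field$slope_ventral, field$plateau_halfwidth_deg)
}

# transverse angle <-> planar x along the row at elevation el
alpha_to_x <- function(field, alpha_deg, el_deg) {
  angpos_1d(alpha_deg, eval_acuity(field, 0, el_deg), field$slope_az,
            field$slope_az, field$plateau_halfwidth_deg)
}

x_to_alpha <- function(field, x, el_deg) {
  anginv_1d(x, eval_acuity(field, 0, el_deg), field$slope_az,
            field$slope_az, field$plateau_halfwidth_deg)
}

#' Build a synthetic ground-truth eye model
#'
#' Assigns every facet of a hexagonal lattice a gaze direction so that the
#' angular divergence between neighbouring facets follows an
#' [acuity_field()].  Elevation is assigned along the central column by
#' (closed-form) cumulative integration of the field at azimuth 0 per unit
#' planar `y`; azimuth is then assigned along each row by cumulative
#' integration of the field at the row's elevation per unit planar `x`.
#' The origin facet gazes along the frontal axis: `gaze(0, 0) = (0, 0)`.
#'
#' Goniometer longitude is a rotation about the vertical head axis, so at
#' latitude `lat` one degree of longitude moves the gaze by `cos(lat)`
#' degrees along the row; the model accounts for this foreshortening when
#' mapping poses to facets (see [observe()]).
#'
#' @param field An [acuity_field()].
#' @param extent List with integer ranges `u = c(min, max)`,
#'   `v = c(min, max)` of facet-row coordinates, or `NULL` to size the
#'   lattice automatically to cover `scan_lat_range` x `scan_lon_range`
#'   with a two-facet margin.
#' @param pitch_um Facet pitch in micrometres (> 0); the honeybee default
#'   is 20.
#' @param seed Integer seed stored with the model; all stochastic draws of
#'   scans and renderings derive from it.
#' @param scan_lat_range,scan_lon_range Latitude/longitude ranges
#'   (degrees) the eye must be able to serve.
#' @return An object of class `"eye_model"`.
#' @export
build_eye <- function(field, extent = NULL, pitch_um = 20, seed = 1L,
                      scan_lat_range = c(-40, 40),
                      scan_lon_range = c(-10, 60)) {
  stopifnot(inherits(field, "acuity_field"))
  if (!is.numeric(pitch_um) || pitch_um <= 0) {
    stop("pitch_um must be positive", call. = FALSE)
  }
  need <- scan_footprint(field, scan_lat_range, scan_lon_range)
  if (is.null(extent)) {
    extent <- list(u = c(floor(min(need$u)) - 2L, ceiling(max(need$u)) + 2L),
                   v = c(floor(min(need$v)) - 2L, ceiling(max(need$v)) + 2L))
  } else {
    ok <- all(need$u >= extent$u[1] & need$u <= extent$u[2] &
                need$v >= extent$v[1] & need$v <= extent$v[2])
    if (!ok) {
      stop(sprintf(
        paste0("extent too small for scan latitude [%g, %g], ",
               "longitude [%g, %g]: needs u in [%.1f, %.1f], ",
               "v in [%.1f, %.1f]"),
        scan_lat_range[1], scan_lat_range[2],
        scan_lon_range[1], scan_lon_range[2],
        min(need$u), max(need$u), min(need$v), max(need$v)),
        call. = FALSE)
    }
  }
  structure(
    list(field = field, extent = extent, pitch_um = pitch_um,
         seed = as.integer(seed),
         scan_lat_range = scan_lat_range, scan_lon_range = scan_lon_range),
    class = "eye_model"
  )
}

# lattice coordinates swept by a scan, sampled on a fine pose grid
scan_footprint <- function(field, lat_range, lon_range) {
  lat <- seq(lat_range[1], lat_range[2], length.out = 33)
  lon <- seq(lon_range[1], lon_range[2], length.out = 33)
  g <- expand.grid(lat = lat, lon = lon)
  p <- pose_to_planar(field, g$lat, g$lon)
  cart_to_lattice(p)
}

# noiseless planar position of the pseudopupil centre for a pose
pose_to_planar <- function(field, lat_deg, lon_deg) {
  y <- elev_to_y(field, lat_deg)
  alpha <- lon_deg * cos(lat_deg * pi / 180)
  x <- alpha_to_x(field, alpha, lat_deg)
  planar_point(x, y)
}

#' Gaze direction of lattice positions
#'
#' Evaluates the model's gaze field at (possibly fractional) facet-row
#' coordinates, returning goniometer coordinates: the pose at which the
#' pseudopupil would be centred on that position.
#'
#' @param model An [build_eye()] model.
#' @param coord `lattice_coord` data.frame (vectorised).
#' @return Data frame with columns `azimuth_deg` (longitude) and
#'   `elevation_deg` (latitude).
#' @export
gaze <- function(model, coord) {
  stopifnot(inherits(model, "eye_model"))
  p <- lattice_to_cart(coord)
  el <- y_to_elev(model$field, p$y)
  alpha <- x_to_alpha(model$field, p$x, el)
  data.frame(azimuth_deg = alpha / cos(el * pi / 180), elevation_deg = el)
}

in_extent <- function(model, coord) {
  coord$u >= model$extent$u[1] & coord$u <= model$extent$u[2] &
    coord$v >= model$extent$v[1] & coord$v <= model$extent$v[2]
}

#' Observe the pseudopupil centre at one goniometer pose
#'
#' Inverts the gaze field (exactly, via the closed-form integrals) to the
#' fractional facet-row coordinate whose gaze equals the pose, then adds
#' independent zero-mean Gaussian localisation noise of standard deviation
#' `noise_sd_facets` to each planar component.  Noise is drawn from R's
#' global RNG stream; seed it (or use [scan_eye()]) for reproducibility.
#'
#' @param model An [build_eye()] model.
#' @param latitude_deg,longitude_deg Goniometer pose in degrees.
#' @param noise_sd_facets Centre-localisation noise, facet units (>= 0).
#' @return One-row data.frame: `latitude_deg`, `longitude_deg`,
#'   `u_facets`, `v_facets`, `facet_diameter_um`.
#' @export
observe <- function(model, latitude_deg, longitude_deg,
                    noise_sd_facets = 0) {
  stopifnot(inherits(model, "eye_model"))
  check_finite(list(latitude_deg, longitude_deg), "pose")
  p <- pose_to_planar(model$field, latitude_deg, longitude_deg)
  centre <- cart_to_lattice(p)
  if (!all(in_extent(model, centre))) {
    stop(sprintf(
      "pose (latitude %g, longitude %g) outside the eye's gaze range",
      latitude_deg, longitude_deg), call. = FALSE)
  }
  if (noise_sd_facets > 0) {
    p$x <- p$x + stats::rnorm(nrow(p), 0, noise_sd_facets)
    p$y <- p$y + stats::rnorm(nrow(p), 0, noise_sd_facets)
    centre <- cart_to_lattice(p)
  }
  data.frame(latitude_deg = latitude_deg, longitude_deg = longitude_deg,
             u_facets = centre$u, v_facets = centre$v,
             facet_diameter_um = model$pitch_um)
}

#' Scan an eye over a goniometer grid
#'
#' One [observe()] per grid node, row-major (latitude outer, longitude
#' inner, both ascending).  The default grid matches the standard protocol
#' for the frontal honeybee eye: latitude -40..+40 degrees, longitude
#' -10..+60 degrees, 10 degree steps (72 observations).
#'
#' @inheritParams observe
#' @param lat_range,lon_range Length-2 numeric ranges in degrees.
#' @param step_deg Grid step in degrees (> 0).
#' @param seed Integer seed for the localisation noise; defaults to the
#'   model's stored seed.  Ignored (no RNG use) when `noise_sd_facets` is 0.
#' @return Data frame of observations (one row per node).
#' @export
scan_eye <- function(model, lat_range = c(-40, 40), lon_range = c(-10, 60),
                 step_deg = 10, noise_sd_facets = 0, seed = model$seed) {
  stopifnot(inherits(model, "eye_model"))
  if (!is.numeric(step_deg) || step_deg <= 0) {
    stop("step_deg must be positive", call. = FALSE)
  }
  lats <- seq(lat_range[1], lat_range[2], by = step_deg)
  lons <- seq(lon_range[1], lon_range[2], by = step_deg)
  run <- function() {
    rows <- lapply(lats, function(lat) {
      do.call(rbind, lapply(lons, function(lon) {
        observe(model, lat, lon, noise_sd_facets = noise_sd_facets)
      }))
    })
    do.call(rbind, rows)
  }
  if (noise_sd_facets > 0) {
    obs <- local_seed(seed, run())
  } else {
    obs <- run()
  }
  rownames(obs) <- NULL
  obs
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf(
    paste0("<eye_model> pitch %.4g um, extent u [%d, %d], v [%d, %d], ",
           "seed %d\n"),
    x$pitch_um, x$extent$u[1], x$extent$u[2],
    x$extent$v[1], x$extent$v[2], x$seed))
  print(x$field)
  invisible(x)
}
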