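#' Optical parameters for pseudopupil rendering
#'
#' Phenomenological optics of the observation path.  The apparent angular
#' width of the pseudopupil is set by the numerical aperture of the
#' objective: the fluorescent envelope is Gaussian with
#' `sigma = pupil_sigma_deg_per_na * na` degrees, and the dark (principal)
#' pseudopupil is an inverted envelope broader by `dark_width_factor`
#' (off-axis light is absorbed by screening pigment over a wider angle
#' than it excites fluorescence).
#'
#' @param na Numerical aperture of the objective, in (0, 1).
#' @param pupil_sigma_deg_per_na Envelope width per unit NA (deg, > 0).
#' @param dark_width_factor Width ratio dark/fluorescent (> 1).
#' @param landmark_count Number of saturated landmark facets (>= 0),
#'   emulating fluorescent crystals sprinkled on the cornea.
#' @param noise_sd Additive Gaussian pixel noise, intensity units (>= 0).
#' @param pixel_scale_um Physical size of one pixel (um, > 0).
#' @param image_size_px Integer `(rows, cols)` of the rendered frame.
#' @return An object of class `"optics_params"`.
#' @export
optics_params <- function(na = 0.15,
                          pupil_sigma_deg_per_na = 20,
                          dark_width_factor = 1.8,
                          landmark_count = 6L,
                          noise_sd = 0,
                          pixel_scale_um = 2.5,
                          image_size_px = c(256L, 256L)) {
  if (!is.numeric(na) || na <= 0 || na >= 1) {
    stop("na must be in (0, 1)", call. = FALSE)
  }
  if (pupil_sigma_deg_per_na <= 0 || dark_width_factor <= 1 ||
      landmark_count < 0 || noise_sd < 0 || pixel_scale_um <= 0) {
    stop("invalid optics parameter", call. = FALSE)
  }
  if (length(image_size_px) != 2 || any(image_size_px < 8)) {
    stop("image_size_px must be two integers >= 8", call. = FALSE)
  }
  structure(
    list(na = na, pupil_sigma_deg_per_na = pupil_sigma_deg_per_na,
         dark_width_factor = dark_width_factor,
         landmark_count = as.integer(landmark_count),
         noise_sd = noise_sd, pixel_scale_um = pixel_scale_um,
         image_size_px = as.integer(image_size_px)),
    class = "optics_params"
  )
}

#' An image frame with physical pixel scale
#'
#' @param intensities Numeric matrix (rows x cols), non-negative.
#' @param pixel_scale_um Micrometres per pixel (> 0).
#' @param ... Extra metadata stored alongside (e.g. the generating pose,
#'   lattice frame, landmark table).
#' @return An object of class `"image_frame"`.
#' @export
image_frame <- function(intensities, pixel_scale_um, ...) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("intensities must be a numeric matrix", call. = FALSE)
  }
  if (nrow(intensities) < 8 || ncol(intensities) < 8) {
    stop("frame must be at least 8x8 pixels", call. = FALSE)
  }
  if (!all(is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_scale_um) || pixel_scale_um <= 0) {
    stop("pixel_scale_um must be positive", call. = FALSE)
  }
  structure(c(list(intensities = intensities,
                   pixel_scale_um = pixel_scale_um), list(...)),
            class = "image_frame")
}

# map planar facet-unit coordinates to pixel (row, col) under a frame
planar_to_px <- function(frame_ref, x, y) {
  th <- frame_ref$orientation_deg * pi / 180
  s <- frame_ref$pitch_px
  list(row = frame_ref$origin_px[1] - s * (sin(th) * x + cos(th) * y),
       col = frame_ref$origin_px[2] + s * (cos(th) * x - sin(th) * y))
}

#' Render a synthetic pseudopupil image frame
#'
#' Draws the facet mosaic as discs on the hexagonal lattice and shades
#' each pixel by the pupil envelope at its own gaze direction: for the
#' fluorescent mode `exp(-theta^2 / (2 sigma^2))` where `theta` is the
#' angular distance between the local gaze and the goniometer pose and
#' `sigma = pupil_sigma_deg_per_na * na`; for the dark mode an inverted
#' envelope `B0 * (1 - c * exp(-theta^2 / (2 (k sigma)^2)))` with
#' `k = dark_width_factor`.  The interstices between discs take the
#' background level, landmark facets are saturated to 1, Gaussian pixel
#' noise of sd `noise_sd` is added, and values are clipped to [0, 1].
#'
#' Landmark facets are drawn at random from the facets inside the frame
#' (reproducibly from `seed`), and their pixel/lattice positions are
#' returned in the frame's `landmarks` table for registration tests.
#'
#' @param model An [build_eye()] model.
#' @param latitude_deg,longitude_deg Goniometer pose (degrees).
#' @param optics An [optics_params()].
#' @param mode `"fluorescent"` or `"dark"`.
#' @param orientation_deg Rotation of the facet rows in the image
#'   (degrees).
#' @param seed Integer seed for landmark placement and pixel noise.
#' @return An `"image_frame"` whose metadata includes the true pupil
#'   centre (`centre_px`, `centre_lattice`), the generating
#'   `lattice_frame`, the `landmarks` table, the pose and the mode.
#' @export
render_frame <- function(model, latitude_deg, longitude_deg,
                         optics = optics_params(),
                         mode = c("fluorescent", "dark"),
                         orientation_deg = 0, seed = model$seed) {
  stopifnot(inherits(model, "eye_model"), inherits(optics, "optics_params"))
  mode <- match.arg(mode)
  nr <- optics$image_size_px[1]
  nc <- optics$image_size_px[2]
  pitch_px <- model$pitch_um / optics$pixel_scale_um
  if (min(nr, nc) < 7 * pitch_px) {
    stop(sprintf(
      "image size %dx%d px too small: needs at least 7 facet pitches (%.1f px)",
      nr, nc, 7 * pitch_px), call. = FALSE)
  }
  centre <- pose_to_planar(model$field, latitude_deg, longitude_deg)
  # place the lattice so the true pupil centre sits at the image centre
  th <- orientation_deg * pi / 180
  origin <- c((nr + 1) / 2 + pitch_px * (sin(th) * centre$x + cos(th) * centre$y),
              (nc + 1) / 2 - pitch_px * (cos(th) * centre$x - sin(th) * centre$y))
  fr <- lattice_frame(pitch_px, orientation_deg, origin,
                      pitch_um = model$pitch_um)

  # planar coordinates of every pixel centre
  px <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  xr <- (px$col - origin[2]) / pitch_px
  yr <- -(px$row - origin[1]) / pitch_px
  x <- cos(th) * xr + sin(th) * yr
  y <- -sin(th) * xr + cos(th) * yr

  # nearest facet and the disc mask (radius 0.52 pitch: discs just touch)
  nf <- nearest_facet(lattice_coord(x - y / sqrt(3), y * 2 / sqrt(3)))
  fx <- nf$u + nf$v / 2
  fy <- nf$v * sqrt(3) / 2
  on_disc <- (x - fx)^2 + (y - fy)^2 <= 0.52^2

  # angular distance between each pixel's gaze and the pose
  el <- y_to_elev(model$field, y)
  alpha <- x_to_alpha(model$field, x, el)
  alpha0 <- longitude_deg * cos(latitude_deg * pi / 180)
  theta2 <- (alpha - alpha0)^2 + (el - latitude_deg)^2

  sigma <- optics$pupil_sigma_deg_per_na * optics$na
  if (mode == "fluorescent") {
    envelope <- exp(-theta2 / (2 * sigma^2))
    background <- 0.02
  } else {
    ks <- optics$dark_width_factor * sigma
    envelope <- 0.9 * (1 - 0.85 * exp(-theta2 / (2 * ks^2)))
    background <- 0.9
  }
  img <- ifelse(on_disc, envelope, background)

  # landmark facets: saturated discs, chosen reproducibly from the facets
  # fully inside the frame
  landmarks <- NULL
  if (optics$landmark_count > 0) {
    inside <- which(on_disc)
    keys <- unique(data.frame(u = nf$u[inside], v = nf$v[inside]))
    lp <- planar_to_px(fr, keys$u + keys$v / 2, keys$v * sqrt(3) / 2)
    margin <- 0.6 * pitch_px
    ok <- lp$row > margin & lp$row < nr - margin &
      lp$col > margin & lp$col < nc - margin
    keys <- keys[ok, , drop = FALSE]
    n_lm <- min(optics$landmark_count, nrow(keys))
    pick <- local_seed(seed, sample.int(nrow(keys), n_lm))
    lm <- keys[pick, , drop = FALSE]
    is_lm <- paste(nf$u, nf$v) %in% paste(lm$u, lm$v) & on_disc
    img[is_lm] <- 1
    lmp <- planar_to_px(fr, lm$u + lm$v / 2, lm$v * sqrt(3) / 2)
    landmarks <- data.frame(u = lm$u, v = lm$v,
                            row_px = lmp$row, col_px = lmp$col)
    rownames(landmarks) <- NULL
  }

  if (optics$noise_sd > 0) {
    img <- img + local_seed(seed + 1L, stats::rnorm(length(img), 0,
                                                    optics$noise_sd))
  }
  img <- pmin(pmax(img, 0), 1)
  m <- matrix(img, nrow = nr, ncol = nc)

  image_frame(m, optics$pixel_scale_um,
              lattice_frame = fr,
              landmarks = landmarks,
              centre_px = c((nr + 1) / 2, (nc + 1) / 2),
              centre_lattice = cart_to_lattice(centre),
              pose = c(latitude_deg = latitude_deg,
                       longitude_deg = longitude_deg),
              mode = mode)
}

#' Read and write image frames
#'
#' Frames are written as 16-bit grayscale TIFF (or PNG, by file
#' extension).  Intensities are clipped to [0, 1] and quantised on write.
#'
#' @param frame An `"image_frame"`.
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_scale_um Pixel scale to attach on read (um/px).
#' @return `read_frame()` returns an `"image_frame"`; `write_frame()`
#'   returns `path` invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "image_frame"))
  m <- pmin(pmax(frame$intensities, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else {
    stop("unsupported frame format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path, pixel_scale_um) {
  if (!file.exists(path)) {
    stop("frame file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported frame format: ", ext, call. = FALSE)
  }
  if (length(dim(m)) == 3) m <- m[, , 1]  # grayscale from first channel
  image_frame(m, pixel_scale_um)
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %.3g um/px, range [%.3g, %.3g]\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_scale_um,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}
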