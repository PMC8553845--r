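test_that("detect_centre finds single pixels, sub-pixel Gaussians, and errors on flat frames", {
  m <- matrix(0, 32, 32)
  m[10, 20] <- 1
  expect_equal(detect_centre(image_frame(m, 1))$centre_px, c(10, 20))
  # sub-pixel accuracy on an analytic Gaussian spot
  fr <- gaussian_frame(centre = c(24.3, 31.7), sigma_px = 5)
  det <- detect_centre(fr)
  expect_lt(max(abs(det$centre_px - c(24.3, 31.7))), 0.1)
  # affine intensity rescaling leaves the centre unchanged
  fr2 <- image_frame(0.2 + 3 * fr$intensities, fr$pixel_scale_um)
  expect_equal(detect_centre(fr2)$centre_px, det$centre_px, tolerance = 1e-12)
  # dark mode = identical estimate on the inverted frame
  frd <- image_frame(max(fr$intensities) - fr$intensities + 0.01,
                     fr$pixel_scale_um)
  expect_equal(detect_centre(frd, mode = "dark")$centre_px, det$centre_px,
               tolerance = 1e-9)
  expect_error(detect_centre(image_frame(matrix(0.4, 16, 16), 1)), "flat")
  expect_error(detect_centre(fr, threshold_frac = 1.5), "threshold_frac")
})

test_that("line profiles sample bilinearly and normalise to relative values", {
  rf <- ramp_frame(32)
  pr <- line_profile(rf, c(16, 2), c(16, 30), n_samples = 29)
  expect_equal(pr$values, seq(0, 1, length.out = 29), tolerance = 1e-9)
  expect_equal(max(pr$positions), 28 * rf$pixel_scale_um)
  flat <- line_profile(image_frame(matrix(0.7, 16, 16), 1),
                       c(8, 2), c(8, 14))
  expect_true(flat$flat)
  expect_true(all(flat$values == 0))
  expect_error(line_profile(rf, c(0, 0), c(16, 30)), "outside")
  # profile through a rendered pupil peaks at the detected centre
  fr <- gaussian_frame()
  det <- detect_centre(fr)
  pr <- line_profile(fr, c(det$centre_px[1], 2), c(det$centre_px[1], 62),
                     n_samples = 121)
  step <- diff(pr$positions)[1]
  expect_lt(abs(profile_peak(pr) - (det$centre_px[2] - 2) * 2), step + 1e-9)
})

test_that("profile_peak returns the maximum with first-position tie-breaking", {
  expect_equal(profile_peak(list(positions = c(0, 5, 10),
                                 values = c(0, 1, 0))), 5)
  expect_equal(profile_peak(list(positions = c(0, 5, 10, 15),
                                 values = c(0, 1, 1, 0))), 5)
  x <- seq(0, 20, by = 0.1)
  g <- exp(-(x - 7.3)^2 / 8)
  expect_lt(abs(profile_peak(list(positions = x, values = g)) - 7.3), 0.05 + 1e-9)
  expect_error(profile_peak(list(positions = 1:3, values = rep(1, 3))), "flat")
})

test_that("profile_fwhm interpolates half-maximum crossings", {
  # triangle of half-width 4 per side: FWHM 4
  x <- seq(-6, 6)
  tri <- pmax(1 - abs(x) / 4, 0)
  expect_equal(profile_fwhm(list(positions = x, values = tri)), 4)
  # sampled Gaussian, sigma = 3: analytic 2*sqrt(2 log 2)*3
  xs <- seq(-15, 15, by = 0.05)
  g <- exp(-xs^2 / 18)
  expect_equal(profile_fwhm(list(positions = xs, values = g)),
               2 * sqrt(2 * log(2)) * 3, tolerance = 0.02)
  expect_error(profile_fwhm(list(positions = 1:10, values = (1:10) / 10)),
               "half maximum")
})

test_that("centre offsets convert pixel distance to micrometres", {
  r1 <- structure(list(centre_px = c(0, 0)), class = "detection_result")
  r2 <- structure(list(centre_px = c(3, 4)), class = "detection_result")
  expect_equal(centre_offset(r1, r1, 2), 0)
  expect_equal(centre_offset(r1, r2, 2), 10)
})

test_that("pixel/lattice registration round-trips and solves from landmarks", {
  fr <- lattice_frame(pitch_px = 7.3, orientation_deg = 23,
                      origin_px = c(40, 60))
  set.seed(8)
  coords <- lattice_coord(runif(50, -8, 8), runif(50, -8, 8))
  p <- lattice_to_cart(coords)
  th <- 23 * pi / 180
  px_row <- 40 - 7.3 * (sin(th) * p$x + cos(th) * p$y)
  px_col <- 60 + 7.3 * (cos(th) * p$x - sin(th) * p$y)
  for (i in seq_len(50)) {
    back <- pixel_to_lattice(c(px_row[i], px_col[i]), fr)
    expect_equal(c(back$u, back$v), c(coords$u[i], coords$v[i]),
                 tolerance = 1e-9)
  }
  expect_equal(unlist(pixel_to_lattice(c(40, 60), fr)), c(u = 0, v = 0))
  one_pitch <- c(40 - 7.3 * sin(th) * 1, 60 + 7.3 * cos(th) * 1)
  expect_equal(unlist(pixel_to_lattice(one_pitch, fr)), c(u = 1, v = 0),
               tolerance = 1e-9)
  # two exact correspondences give a zero-residual solution
  solved <- solve_lattice_frame(cbind(px_row[1:2], px_col[1:2]),
                                lattice_coord(coords$u[1:2], coords$v[1:2]))
  expect_equal(attr(solved, "residual_rms_px"), 0, tolerance = 1e-9)
  expect_equal(solved$pitch_px, 7.3, tolerance = 1e-9)
  expect_error(solve_lattice_frame(cbind(px_row[1], px_col[1]),
                                   lattice_coord(coords$u[1], coords$v[1])),
               "at least 2")
})

test_that("registration recovers the generator's frame from rendered landmarks", {
  m <- honeybee_model()
  fr <- render_frame(m, 0, 20, optics_params(landmark_count = 8L),
                     orientation_deg = 17, seed = 2)
  solved <- solve_lattice_frame(fr$landmarks[c("row_px", "col_px")],
                                lattice_coord(fr$landmarks$u, fr$landmarks$v))
  truth <- fr$lattice_frame
  expect_lt(abs(solved$pitch_px - truth$pitch_px) / truth$pitch_px, 0.01)
  expect_lt(abs(solved$orientation_deg - truth$orientation_deg), 0.5)
  back <- pixel_to_lattice(fr$centre_px, solved)
  expect_equal(c(back$u, back$v),
               c(fr$centre_lattice$u, fr$centre_lattice$v), tolerance = 1e-6)
})

test_that("facet diameters follow the line-over-count rule", {
  expect_equal(facet_diameter_line(c(0, 0), c(0, 150), 6, 1), 25)
  expect_equal(facet_diameter_line(c(0, 0), c(120, 0), 6, 0.5), 10)
  expect_warning(facet_diameter_line(c(0, 0), c(0, 30), 3, 1), "5-8")
  expect_error(facet_diameter_line(c(1, 1), c(1, 1), 6, 1), "zero-length")
  # six facet pitches measured on a rendered frame with pitch 20 um
  m <- honeybee_model()
  op <- optics_params(landmark_count = 0L)
  fr <- render_frame(m, 0, 0, op)
  ref <- fr$lattice_frame
  c0 <- fr$centre_lattice
  p <- lattice_to_cart(lattice_coord(c0$u + c(0, 6), c0$v))
  th <- ref$orientation_deg * pi / 180
  rowc <- ref$origin_px[1] - ref$pitch_px * (sin(th) * p$x + cos(th) * p$y)
  colc <- ref$origin_px[2] + ref$pitch_px * (cos(th) * p$x - sin(th) * p$y)
  d <- facet_diameter_line(c(rowc[1], colc[1]), c(rowc[2], colc[2]), 6,
                           fr$pixel_scale_um)
  expect_equal(d, 20, tolerance = 0.025)
})

test_that("fluorescent pupils are sharper than dark ones with a shared centre", {
  m <- honeybee_model()
  op <- optics_params(landmark_count = 0L)
  fb <- render_frame(m, 0, 20, op, mode = "fluorescent")
  fd <- render_frame(m, 0, 20, op, mode = "dark")
  db <- detect_centre(fb, mode = "bright")
  dd <- detect_centre(fd, mode = "dark")
  pitch <- fb$lattice_frame$pitch_px
  expect_lt(centre_offset(db, dd, 1) / pitch, 0.2)
  line0 <- c(db$centre_px[1], 6)
  line1 <- c(db$centre_px[1], ncol(fb$intensities) - 5)
  pb <- line_profile(fb, line0, line1, 301)
  pd <- line_profile(fd, line0, line1, 301)
  pd$values <- 1 - pd$values   # invert the dark profile
  expect_lt(profile_fwhm(pb), profile_fwhm(pd))
  step <- diff(pb$positions)[1]
  expect_lt(abs(profile_peak(pb) - profile_peak(pd)), step + 1e-9)
})

test_that("pupil width scales with numerical aperture, centre does not move", {
  m <- honeybee_model()
  nas <- c(0.075, 0.1, 0.15)
  fw <- numeric(3)
  pk <- numeric(3)
  for (i in seq_along(nas)) {
    fr <- render_frame(m, 0, 0, optics_params(na = nas[i],
                                              landmark_count = 0L))
    det <- detect_centre(fr)
    pr <- line_profile(fr, c(det$centre_px[1], 6),
                       c(det$centre_px[1], ncol(fr$intensities) - 5), 301)
    fw[i] <- profile_fwhm(pr)
    pk[i] <- profile_peak(pr)
  }
  expect_true(all(diff(fw) > 0))             # strictly increasing with NA
  expect_equal(fw[3] / fw[1], 2, tolerance = 0.05)
  step <- 245 * 2.5 / 300
  expect_lt(max(pk) - min(pk), step + 1e-9)  # peak position unchanged
})
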