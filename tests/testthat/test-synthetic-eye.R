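test_that("the acuity field evaluates the plateau-plus-slopes form", {
  f <- honeybee_field()
  expect_equal(eval_acuity(f, 0, 0), 1.30)
  expect_equal(eval_acuity(f, 0, 20), 2.30)      # 1.30 + 0.10 * 10
  expect_equal(eval_acuity(f, 40, 0), 1.5625)    # 1.30 + 0.00875 * 30
  expect_equal(eval_acuity(f, -40, 0), eval_acuity(f, 40, 0))  # az symmetry
  expect_equal(eval_acuity(f, 0, -20), 1.30 + 0.015 * 10)
  # everywhere at least the minimum
  g <- expand.grid(az = seq(-60, 60, 7), el = seq(-50, 50, 7))
  expect_true(all(eval_acuity(f, g$az, g$el) >= 1.30))
  expect_error(acuity_field(-1), "positive")
})

test_that("gaze integration is uniform-exact and anchored at the origin", {
  m <- uniform_eye(2)
  expect_equal(gaze(m, lattice_coord(0, 0)),
               data.frame(azimuth_deg = 0, elevation_deg = 0))
  g10 <- gaze(m, cart_to_lattice(planar_point(1, 0)))
  expect_equal(g10$azimuth_deg, 2.0)
  expect_equal(g10$elevation_deg, 0)
  g01 <- gaze(m, cart_to_lattice(planar_point(0, 1)))
  expect_equal(g01$azimuth_deg, 0)
  expect_equal(g01$elevation_deg, 2.0)
  # honeybee plateau: 5 planar steps of 1.30 degrees
  hb <- honeybee_model()
  g5 <- gaze(hb, cart_to_lattice(planar_point(5, 0)))
  expect_equal(g5$azimuth_deg, 6.5)
  expect_equal(g5$elevation_deg, 0)
})

test_that("angular steps between adjacent facets follow the field", {
  m <- uniform_eye(2)
  # uniform field: every planar-adjacent pair is exactly g apart
  at <- expand.grid(x = -5:5, y = -3:3)
  g0 <- gaze(m, cart_to_lattice(planar_point(at$x, at$y)))
  gx <- gaze(m, cart_to_lattice(planar_point(at$x + 1, at$y)))
  gy <- gaze(m, cart_to_lattice(planar_point(at$x, at$y + 1)))
  # horizontal neighbours: one arc-degree step along the parallel is the
  # longitude step scaled by cos(latitude)
  arc_x <- (gx$azimuth_deg - g0$azimuth_deg) *
    cos(g0$elevation_deg * pi / 180)
  expect_equal(arc_x, rep(2, nrow(at)), tolerance = 1e-6)
  expect_equal(gy$elevation_deg - g0$elevation_deg, rep(2, nrow(at)),
               tolerance = 1e-6)
  # monotone along rows and columns for the honeybee field
  hb <- honeybee_model()
  row <- gaze(hb, cart_to_lattice(planar_point(-15:40, rep(2.5, 56))))
  col <- gaze(hb, cart_to_lattice(planar_point(rep(-3, 61), -30:30)))
  expect_true(all(diff(row$azimuth_deg) > 0))
  expect_true(all(diff(col$elevation_deg) > 0))
})

test_that("observe inverts the gaze field and respects the eye extent", {
  m <- uniform_eye(2)
  o <- observe(m, 0, 0)
  expect_equal(c(o$u_facets, o$v_facets), c(0, 0))
  o <- observe(m, 0, 10)
  p <- lattice_to_cart(lattice_coord(o$u_facets, o$v_facets))
  expect_equal(c(p$x, p$y), c(5, 0), tolerance = 1e-9)
  # inversion round trip on random in-range poses
  hb <- honeybee_model()
  set.seed(3)
  lat <- runif(20, -35, 35)
  lon <- runif(20, -5, 55)
  for (i in seq_len(20)) {
    oo <- observe(hb, lat[i], lon[i])
    gz <- gaze(hb, lattice_coord(oo$u_facets, oo$v_facets))
    expect_equal(gz$elevation_deg, lat[i], tolerance = 1e-5)
    expect_equal(gz$azimuth_deg, lon[i], tolerance = 1e-5)
  }
  expect_error(observe(m, 0, 500), "outside the eye's gaze range")
  small <- build_eye(uniform_field(2), extent = list(u = c(-5, 5), v = c(-5, 5)),
                     scan_lat_range = c(-5, 5), scan_lon_range = c(-5, 5))
  expect_error(observe(small, 0, 30), "outside")
  expect_error(build_eye(uniform_field(2),
                         extent = list(u = c(-5, 5), v = c(-5, 5))),
               "extent too small")
})

test_that("scans cover the requested grid deterministically", {
  m <- uniform_eye(2)
  obs <- scan_eye(m)
  expect_equal(nrow(obs), 72)   # 9 latitudes x 8 longitudes
  expect_equal(length(unique(obs$latitude_deg)), 9)
  expect_equal(length(unique(obs$longitude_deg)), 8)
  # row-major: latitude outer, longitude inner
  expect_equal(obs$latitude_deg[1:8], rep(-40, 8))
  expect_equal(obs$longitude_deg[1:8], seq(-10, 60, 10))
  obs20 <- scan_eye(m, c(-40, 40), c(-10, 50), step_deg = 20)
  expect_equal(nrow(obs20), 20)
  expect_identical(scan_eye(m), scan_eye(m))  # noiseless is deterministic
  n1 <- scan_eye(m, noise_sd_facets = 0.1, seed = 9)
  n2 <- scan_eye(m, noise_sd_facets = 0.1, seed = 9)
  n3 <- scan_eye(m, noise_sd_facets = 0.1, seed = 10)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  expect_equal(unique(obs$facet_diameter_um), 20)
})
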