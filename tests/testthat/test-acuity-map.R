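test_that("displacement matrices recover facets-per-degree on a uniform eye", {
  obs <- scan_eye(uniform_eye(2))
  dm <- displacement_matrix(obs, 0, 20)
  expect_equal(dm$M, matrix(c(0.5, 0, 0, 0.5), 2, 2,
                            dimnames = list(c("x", "y"), c("lon", "lat"))))
  expect_false(dm$edge)
  # corner nodes fall back to one-sided differences; same value on a
  # linear gaze field
  corner <- displacement_matrix(obs, -40, -10)
  expect_true(corner$edge)
  expect_equal(unname(corner$M[1, 1]), 0.5, tolerance = 1e-9)
  expect_equal(unname(corner$M[2, 2]), 0.5, tolerance = 1e-9)
  # an unusable neighbour observation invalidates dependent nodes only
  obs_na <- obs
  obs_na$u_facets[obs_na$latitude_deg == 10 & obs_na$longitude_deg == 20] <- NA
  map_na <- build_map(obs_na)
  nd <- map_na$nodes
  expect_false(nd$valid[nd$elevation_deg == 0 & nd$azimuth_deg == 20])
  expect_false(nd$valid[nd$elevation_deg == 20 & nd$azimuth_deg == 20])
  expect_true(nd$valid[nd$elevation_deg == 0 & nd$azimuth_deg == 40])
})

test_that("local_jacobian inverts well-conditioned matrices and rejects singular ones", {
  expect_equal(local_jacobian(diag(c(0.5, 0.5))), diag(c(2, 2)))
  set.seed(21)
  for (i in 1:100) {
    M <- matrix(rnorm(4), 2, 2)
    while (abs(det(M)) < 0.1) M <- matrix(rnorm(4), 2, 2)
    expect_lt(max(abs(M %*% local_jacobian(M) - diag(2))), 1e-9)
  }
  expect_error(local_jacobian(matrix(c(1, 2, 2, 4), 2, 2)), "singular")
})

test_that("delta-phi components and the three-axis average follow the Jacobian", {
  expect_equal(dphi_components(diag(c(2, 2.5))),
               c(dphi_h_deg = 2, dphi_v_deg = 2.5, dphi_mean_deg = 2.25))
  expect_equal(unname(dphi_components(3 * diag(2))), c(3, 3, 3))
  expect_equal(dphi_three_axis(3 * diag(2)), 3)
  expect_equal(dphi_three_axis(diag(c(2, 0))), 4 / 3)  # mean of 2, 1, 1
  set.seed(13)
  ax <- lattice_to_cart(hex_axes())
  for (i in 1:25) {
    J <- matrix(rnorm(4), 2, 2)
    comp <- dphi_components(J)
    expect_equal(unname(comp["dphi_h_deg"]), sqrt(sum((J %*% c(1, 0))^2)),
                 tolerance = 1e-12)
    expect_equal(unname(comp["dphi_v_deg"]), sqrt(sum((J %*% c(0, 1))^2)),
                 tolerance = 1e-12)
    three <- mean(vapply(1:3, function(k) {
      sqrt(sum((J %*% c(ax$x[k], ax$y[k]))^2))
    }, numeric(1)))
    expect_equal(dphi_three_axis(J), three, tolerance = 1e-12)
    # axis-norm bounds
    norms <- vapply(1:3, function(k) sqrt(sum((J %*% c(ax$x[k], ax$y[k]))^2)),
                    numeric(1))
    expect_gte(dphi_three_axis(J), min(norms) - 1e-12)
    expect_lte(dphi_three_axis(J), max(norms) + 1e-12)
  }
})

test_that("hex_combine applies the quadrature lattice allowance", {
  expect_equal(hex_combine(1.3, 1.0), sqrt(1.3^2 + 1), tolerance = 1e-12)
  expect_equal(round(hex_combine(1.3, 1.0), 2), 1.64)
  expect_equal(hex_combine(0, 5), 5)
  expect_equal(hex_combine(3, 4), 5)
  expect_gte(hex_combine(1.2, 0.8), 1.2)   # never below either component
  expect_error(hex_combine(-1, 1), "non-negative")
})

test_that("uniform scans recover the field exactly at every node", {
  g <- 2
  map <- build_map(scan_eye(uniform_eye(g)))
  nd <- map$nodes
  expect_equal(nrow(nd), 72)
  expect_true(all(nd$valid))
  expect_equal(nd$dphi_h_deg, rep(g, 72), tolerance = 1e-6)
  expect_equal(nd$dphi_v_deg, rep(g, 72), tolerance = 1e-6)
  expect_equal(nd$dphi_3axis_deg, rep(g, 72), tolerance = 1e-6)
  # cos-latitude correction compensates foreshortened longitude steps
  hi_lat <- nd$dphi_h_deg[nd$elevation_deg == 40]
  eq <- nd$dphi_h_deg[nd$elevation_deg == 0]
  expect_equal(hi_lat, eq, tolerance = 1e-6)
})

test_that("the honeybee scan recovers the acute zone of the preset", {
  map <- honeybee_map()
  sm <- summarize_map(map)
  expect_equal(sm$dphi_min_deg, 1.30, tolerance = 0.05)
  nd <- map$nodes
  frontal <- nd$dphi_mean_deg[nd$azimuth_deg == 0 & nd$elevation_deg == 0]
  expect_equal(frontal, sm$dphi_min_deg, tolerance = 1e-9)
  expect_equal(sm$equator_extent_deg, 70)
  expect_equal(sm$argmin[["elevation_deg"]], 0)
  # recovered J agrees with the generator's own finite differences
  obs <- honeybee_scan()
  p0 <- lattice_to_cart(lattice_coord(
    obs$u_facets[obs$latitude_deg == 0 & obs$longitude_deg == 10],
    obs$v_facets[obs$latitude_deg == 0 & obs$longitude_deg == 10]))
  dm <- displacement_matrix(obs, 0, 10)
  J <- local_jacobian(dm$M)
  fd <- (lattice_to_cart(lattice_coord(
    obs$u_facets[obs$latitude_deg == 0 & obs$longitude_deg == 20],
    obs$v_facets[obs$latitude_deg == 0 & obs$longitude_deg == 20]))$x -
      lattice_to_cart(lattice_coord(
        obs$u_facets[obs$latitude_deg == 0 & obs$longitude_deg == 0],
        obs$v_facets[obs$latitude_deg == 0 & obs$longitude_deg == 0]))$x) / 20
  expect_equal(unname(dm$M[1, 1]), fd, tolerance = 1e-9)
  expect_gt(det(J), 0)
})

test_that("non-rectangular grids and empty maps raise informative errors", {
  obs <- scan_eye(uniform_eye(2), c(-10, 10), c(0, 20), 10)
  expect_error(build_map(obs[-3, ]), "missing nodes")
  expect_error(build_map(rbind(obs, obs[1, ])), "duplicate")
  map <- build_map(obs)
  map$nodes$valid <- FALSE
  expect_error(summarize_map(map), "no valid nodes")
  expect_error(summarize_map(build_map(obs), threshold_deg = -1), "positive")
})

test_that("maps are deterministic and the median filter preserves uniform fields", {
  obs <- scan_eye(uniform_eye(1.5), c(-20, 20), c(-10, 30), 10)
  expect_identical(build_map(obs), build_map(obs))
  filtered <- map_median_filter(build_map(obs))
  expect_equal(filtered$nodes$dphi_mean_deg,
               build_map(obs)$nodes$dphi_mean_deg, tolerance = 1e-9)
})
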