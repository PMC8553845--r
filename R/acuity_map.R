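#' Local pseudopupil displacement per degree of gaze rotation
#'
#' At a goniometer grid node, the 2x2 matrix `M` of the planar facet
#' displacement of the pseudopupil centre per degree of *effective* gaze
#' rotation.  Goniometer steps are first differenced on the grid (central
#' differences at interior nodes, one-sided at edges) and then normalised
#' by the pose-to-gaze-arc Jacobian computed with the same differencing
#' scheme: a longitude turn at latitude `lat` sweeps the gaze only
#' `cos(lat)` degrees of arc per degree (foreshortening), and a latitude
#' step at non-zero longitude also drags the gaze sideways along the
#' parallel by `lon * d cos(lat)` (meridian convergence).  Without the
#' first factor, off-equator horizontal components are biased by
#' `1/cos(lat)`; without the second, vertical components acquire a shear
#' off the frontal meridian.  Both vanish on the equator and the frontal
#' meridian.  Units: facets per degree of arc.
#'
#' @param obs Observation data.frame (see [scan_eye()] /
#'   [read_observations()]) forming a rectangular goniometer grid.
#' @param latitude_deg,longitude_deg Node coordinates (must be grid
#'   nodes).
#' @return List with `M` (2x2 matrix, possibly containing NA when a
#'   neighbour is missing), `edge` (logical: any one-sided difference).
#' @export
displacement_matrix <- function(obs, latitude_deg, longitude_deg) {
  g <- obs_grid(obs)
  node_diff <- function(axis) {
    # finite difference along one grid axis; NULL if no usable neighbour
    if (axis == "lon") {
      vals <- sort(unique(obs$longitude_deg))
      at <- longitude_deg
    } else {
      vals <- sort(unique(obs$latitude_deg))
      at <- latitude_deg
    }
    i <- match(at, vals)
    if (is.na(i)) stop("not a grid node", call. = FALSE)
    lo <- if (i > 1) vals[i - 1] else at
    hi <- if (i < length(vals)) vals[i + 1] else at
    if (lo == hi) return(NULL)
    p_lo <- node_planar(g, latitude_deg, longitude_deg, axis, lo)
    p_hi <- node_planar(g, latitude_deg, longitude_deg, axis, hi)
    if (is.null(p_lo) || is.null(p_hi)) return(NULL)
    list(d = (p_hi - p_lo) / (hi - lo), lo = lo, hi = hi,
         edge = (i == 1 || i == length(vals)))
  }
  dl <- node_diff("lon")
  dt <- node_diff("lat")
  if (is.null(dl) || is.null(dt)) {
    return(list(M = matrix(NA_real_, 2, 2), edge = TRUE))
  }
  # pose -> gaze-arc Jacobian, same differencing scheme as the data:
  # arc xi = lon * cos(lat) along the parallel, eta = lat along the
  # meridian
  dcos <- (cos(dt$hi * pi / 180) - cos(dt$lo * pi / 180)) / (dt$hi - dt$lo)
  P <- matrix(c(cos(latitude_deg * pi / 180), 0,
                longitude_deg * dcos, 1), 2, 2)
  D <- cbind(dl$d, dt$d)
  M <- D %*% solve(P)
  dimnames(M) <- list(c("x", "y"), c("lon", "lat"))
  list(M = M, edge = dl$edge || dt$edge)
}

# planar centre at the node obtained by moving `axis` to `value`
node_planar <- function(g, lat, lon, axis, value) {
  if (axis == "lon") lon <- value else lat <- value
  i <- which(g$latitude_deg == lat & g$longitude_deg == lon)
  if (length(i) != 1 || !is.finite(g$x[i]) || !is.finite(g$y[i])) {
    return(NULL)
  }
  c(g$x[i], g$y[i])
}

# observation table with planar centre coordinates, checked rectangular
obs_grid <- function(obs) {
  need <- c("latitude_deg", "longitude_deg", "u_facets", "v_facets")
  if (!all(need %in% names(obs))) {
    stop("observations must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  lats <- sort(unique(obs$latitude_deg))
  lons <- sort(unique(obs$longitude_deg))
  full <- expand.grid(latitude_deg = lats, longitude_deg = lons)
  key <- paste(obs$latitude_deg, obs$longitude_deg)
  miss <- !(paste(full$latitude_deg, full$longitude_deg) %in% key)
  if (any(miss)) {
    stop("observations do not form a rectangular grid; missing nodes: ",
         paste(sprintf("(%g, %g)", full$latitude_deg[miss],
                       full$longitude_deg[miss]), collapse = " "),
         call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop("duplicate observations at ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  # NA centres (failed detections) propagate to invalid nodes downstream
  cbind(obs, x = obs$u_facets + obs$v_facets / 2,
        y = obs$v_facets * sqrt(3) / 2)
}

#' Local angular magnification (degrees per facet)
#'
#' Inverts a [displacement_matrix()] to the local Jacobian `J = M^-1`,
#' the degrees of gaze rotation per unit planar facet step.  Its
#' directional magnitudes are the local interommatidial-angle components.
#'
#' @param M 2x2 displacement matrix, facets/degree.
#' @return 2x2 matrix, degrees/facet.
#' @export
local_jacobian <- function(M) {
  if (!is.matrix(M) || any(dim(M) != 2) || !all(is.finite(M))) {
    stop("M must be a finite 2x2 matrix", call. = FALSE)
  }
  if (abs(det(M)) <= 1e-9) {
    stop("degenerate node: displacement matrix is singular", call. = FALSE)
  }
  solve(M)
}

#' Horizontal/vertical interommatidial-angle components
#'
#' `dphi_h` and `dphi_v` are the angular magnitudes of unit planar facet
#' steps along the horizontal and vertical directions, `|J e_x|` and
#' `|J e_y|`; `dphi_mean` is their arithmetic mean (the map value of the
#' h/v-average convention).
#'
#' @param J Local Jacobian (degrees/facet), see [local_jacobian()].
#' @return Named numeric: `dphi_h_deg`, `dphi_v_deg`, `dphi_mean_deg`.
#' @export
dphi_components <- function(J) {
  h <- sqrt(sum(J[, 1]^2))
  v <- sqrt(sum(J[, 2]^2))
  c(dphi_h_deg = h, dphi_v_deg = v, dphi_mean_deg = (h + v) / 2)
}

#' Three-axis interommatidial angle
#'
#' The average of the angles subtended by nearest-neighbour ommatidia
#' along the three hexagonally oriented facet rows: the mean of
#' `|J p_k|` over the planar unit vectors `p_k` of the [hex_axes()].
#'
#' @inheritParams dphi_components
#' @return Interommatidial angle in degrees.
#' @export
dphi_three_axis <- function(J) {
  ax <- lattice_to_cart(hex_axes())
  mean(sqrt((J[1, 1] * ax$x + J[1, 2] * ax$y)^2 +
              (J[2, 1] * ax$x + J[2, 2] * ax$y)^2))
}

#' Combine orthogonal interommatidial-angle components
#'
#' The hexagonal-lattice allowance combining a horizontal and a vertical
#' component in quadrature: `sqrt(dphi_h^2 + dphi_v^2)`.  Note the
#' classical worked example takes `dphi_h` as *half* the horizontal row
#' separation (rows are offset by half a facet vertically, so the
#' horizontal neighbour spacing per row is twice the column spacing);
#' that halving is the caller's responsibility.
#'
#' @param dphi_h,dphi_v Components in degrees (>= 0).
#' @return Combined interommatidial angle in degrees.
#' @examples
#' hex_combine(1.3, 1.0)  # 1.64
#' @export
hex_combine <- function(dphi_h, dphi_v) {
  if (any(dphi_h < 0) || any(dphi_v < 0)) {
    stop("components must be non-negative", call. = FALSE)
  }
  sqrt(dphi_h^2 + dphi_v^2)
}

#' Assemble an acuity map from goniometer observations
#'
#' Per grid node: [displacement_matrix()] -> [local_jacobian()] ->
#' [dphi_components()] and [dphi_three_axis()]; the facet diameter is
#' carried over per node.  Map azimuth is the goniometer longitude and
#' map elevation the latitude.  Nodes with a missing neighbour or a
#' near-singular displacement matrix are flagged invalid (never silently
#' interpolated); one-sided (edge) nodes are flagged lower-confidence.
#'
#' @param obs Observation data.frame over a rectangular goniometer grid.
#' @return An object of class `"acuity_map"`: a list with `nodes` (one
#'   data.frame row per grid node: `azimuth_deg`, `elevation_deg`,
#'   `dphi_h_deg`, `dphi_v_deg`, `dphi_mean_deg`, `dphi_3axis_deg`,
#'   `facet_diameter_um`, `valid`, `edge_flag`) and `meta` (grid ranges
#'   and step).
#' @export
build_map <- function(obs) {
  g <- obs_grid(obs)
  lats <- sort(unique(obs$latitude_deg))
  lons <- sort(unique(obs$longitude_deg))
  nodes <- expand.grid(elevation_deg = lats, azimuth_deg = lons)
  out <- lapply(seq_len(nrow(nodes)), function(i) {
    lat <- nodes$elevation_deg[i]
    lon <- nodes$azimuth_deg[i]
    dm <- displacement_matrix(obs, lat, lon)
    row <- data.frame(azimuth_deg = lon, elevation_deg = lat,
                      dphi_h_deg = NA_real_, dphi_v_deg = NA_real_,
                      dphi_mean_deg = NA_real_, dphi_3axis_deg = NA_real_,
                      facet_diameter_um = NA_real_,
                      valid = FALSE, edge_flag = dm$edge)
    k <- which(g$latitude_deg == lat & g$longitude_deg == lon)
    if ("facet_diameter_um" %in% names(g)) {
      row$facet_diameter_um <- mean(g$facet_diameter_um[k])
    }
    if (all(is.finite(dm$M)) && abs(det(dm$M)) > 1e-9) {
      J <- local_jacobian(dm$M)
      comp <- dphi_components(J)
      row$dphi_h_deg <- comp[["dphi_h_deg"]]
      row$dphi_v_deg <- comp[["dphi_v_deg"]]
      row$dphi_mean_deg <- comp[["dphi_mean_deg"]]
      row$dphi_3axis_deg <- dphi_three_axis(J)
      row$valid <- TRUE
    }
    row
  })
  nodes <- do.call(rbind, out)
  # column-major over (elevation, azimuth): order rows by azimuth within
  # elevation for a stable, documented layout
  nodes <- nodes[order(nodes$elevation_deg, nodes$azimuth_deg), ]
  rownames(nodes) <- NULL
  structure(
    list(nodes = nodes,
         meta = list(lat_range = range(lats), lon_range = range(lons),
                     step_deg = if (length(lats) > 1) diff(lats)[1] else NA,
                     n_lat = length(lats), n_lon = length(lons))),
    class = "acuity_map"
  )
}

#' Summary statistics of an acuity map
#'
#' The acute-zone summary: minimum `dphi_mean` over valid nodes with its
#' grid-node location (ties broken by smallest elevation, then smallest
#' azimuth); the azimuth span between the outermost equatorial
#' (elevation 0) nodes at or below `threshold_deg` (+ 0.05 tolerance);
#' the elevation span of qualifying frontal-meridian (azimuth 0) nodes
#' under the same rule; and the count of valid nodes at or below the
#' threshold.
#'
#' @param map An `"acuity_map"`.
#' @param threshold_deg Acute-zone threshold in degrees (> 0).
#' @return A list of class `"map_summary"`.
#' @export
summarize_map <- function(map, threshold_deg = 2.0) {
  stopifnot(inherits(map, "acuity_map"))
  if (threshold_deg <= 0) stop("threshold_deg must be positive", call. = FALSE)
  nd <- map$nodes[map$nodes$valid, , drop = FALSE]
  if (nrow(nd) == 0) stop("empty map: no valid nodes", call. = FALSE)
  nd <- nd[order(nd$dphi_mean_deg, nd$elevation_deg, nd$azimuth_deg), ]
  thr <- threshold_deg + 0.05
  eq <- nd[nd$elevation_deg == 0 & nd$dphi_mean_deg <= thr, , drop = FALSE]
  fm <- nd[nd$azimuth_deg == 0 & nd$dphi_mean_deg <= thr, , drop = FALSE]
  structure(
    list(dphi_min_deg = nd$dphi_mean_deg[1],
         argmin = c(azimuth_deg = nd$azimuth_deg[1],
                    elevation_deg = nd$elevation_deg[1]),
         threshold_deg = threshold_deg,
         equator_extent_deg =
           if (nrow(eq)) diff(range(eq$azimuth_deg)) else 0,
         frontal_meridian_extent_deg =
           if (nrow(fm)) diff(range(fm$elevation_deg)) else 0,
         region_node_count = sum(nd$dphi_mean_deg <= thr)),
    class = "map_summary"
  )
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<map_summary> min dphi %.4g deg at (az %g, el %g);\n",
           "  <= %.3g deg: equator span %g deg, frontal meridian span %g deg,",
           " %d nodes\n"),
    x$dphi_min_deg, x$argmin[["azimuth_deg"]], x$argmin[["elevation_deg"]],
    x$threshold_deg, x$equator_extent_deg, x$frontal_meridian_extent_deg,
    x$region_node_count))
  invisible(x)
}

#' @export
print.acuity_map <- function(x, ...) {
  cat(sprintf(
    "<acuity_map> %d x %d nodes, elevation [%g, %g], azimuth [%g, %g]\n",
    x$meta$n_lat, x$meta$n_lon, x$meta$lat_range[1], x$meta$lat_range[2],
    x$meta$lon_range[1], x$meta$lon_range[2]))
  ok <- x$nodes$valid
  if (any(ok)) {
    cat(sprintf("  dphi_mean range [%.4g, %.4g] deg over %d valid nodes\n",
                min(x$nodes$dphi_mean_deg[ok]),
                max(x$nodes$dphi_mean_deg[ok]), sum(ok)))
  }
  invisible(x)
}

#' @export
summary.acuity_map <- function(object, threshold_deg = 2.0, ...) {
  summarize_map(object, threshold_deg = threshold_deg)
}

#' Median-filter an acuity map
#'
#' Optional 3x3 node median smoothing of the delta-phi fields (all of
#' `dphi_h_deg`, `dphi_v_deg`, `dphi_mean_deg`, `dphi_3axis_deg`),
#' ignoring invalid neighbours.  Off by default in every pipeline; the
#' finite-difference estimate over a 10-degree step already averages over
#' roughly a 5 x 5 facet rhomboid.
#'
#' @param map An `"acuity_map"`.
#' @return A filtered `"acuity_map"`.
#' @export
map_median_filter <- function(map) {
  stopifnot(inherits(map, "acuity_map"))
  nd <- map$nodes
  lats <- sort(unique(nd$elevation_deg))
  lons <- sort(unique(nd$azimuth_deg))
  fields <- c("dphi_h_deg", "dphi_v_deg", "dphi_mean_deg", "dphi_3axis_deg")
  out <- nd
  for (i in seq_len(nrow(nd))) {
    if (!nd$valid[i]) next
    li <- match(nd$elevation_deg[i], lats)
    ci <- match(nd$azimuth_deg[i], lons)
    nb_l <- lats[max(1, li - 1):min(length(lats), li + 1)]
    nb_c <- lons[max(1, ci - 1):min(length(lons), ci + 1)]
    sel <- nd$elevation_deg %in% nb_l & nd$azimuth_deg %in% nb_c & nd$valid
    for (f in fields) out[[f]][i] <- stats::median(nd[[f]][sel])
  }
  map$nodes <- out
  map
}
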