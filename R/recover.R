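#' Run configuration for the end-to-end recovery harness
#'
#' Validates a configuration list (or JSON/YAML file) for
#' [run_recover()].  Unknown keys are rejected; angles are degrees and
#' lengths micrometres throughout.
#'
#' @param config A named list, or a path to a JSON (or YAML) file.
#' @return A validated configuration list of class `"run_config"`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(
    preset = "honeybee",      # "honeybee", "uniform", or "custom"
    uniform_g_deg = 2.0,      # field value for preset "uniform"
    field = NULL,             # acuity_field parameter list for "custom"
    pitch_um = 20,
    lat_range = c(-40, 40),
    lon_range = c(-10, 60),
    step_deg = 10,
    noise_sd_facets = 0,
    use_frames = FALSE,       # render + detect instead of direct centres
    optics = NULL,            # optics_params arguments when use_frames
    threshold_deg = 2.0,
    seed = 1L,
    claims = NULL             # NULL = preset default claim checks
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (cfg$step_deg <= 0) stop("step_deg must be > 0", call. = FALSE)
  if (cfg$threshold_deg <= 0) stop("threshold_deg must be > 0", call. = FALSE)
  if (cfg$noise_sd_facets < 0) stop("noise_sd_facets must be >= 0",
                                    call. = FALSE)
  structure(cfg, class = "run_config")
}

config_field <- function(cfg) {
  switch(cfg$preset,
         honeybee = honeybee_field(),
         uniform = uniform_field(cfg$uniform_g_deg),
         custom = do.call(acuity_field, cfg$field),
         stop("unknown preset: ", cfg$preset, call. = FALSE))
}

# the printed acute-zone claims the honeybee preset is built to satisfy
honeybee_claims <- function() {
  list(
    list(name = "frontal minimum 1.3 deg, attained at the frontal axis",
         check = function(map, sm) {
           nd <- map$nodes
           at0 <- nd$valid & nd$azimuth_deg == 0 & nd$elevation_deg == 0
           abs(sm$dphi_min_deg - 1.3) <= 0.05 && any(at0) &&
             nd$dphi_mean_deg[at0] <= sm$dphi_min_deg + 1e-9
         }),
    list(name = "equatorial span at or below 2.0 deg covers >= 40 deg azimuth",
         check = function(map, sm) sm$equator_extent_deg >= 40),
    list(name = "equatorial dphi_mean <= 1.7 deg for azimuth 0..40",
         check = function(map, sm) {
           nd <- map$nodes
           sel <- nd$valid & nd$elevation_deg == 0 &
             nd$azimuth_deg >= 0 & nd$azimuth_deg <= 40
           all(nd$dphi_mean_deg[sel] <= 1.7)
         }),
    list(name = "frontal-meridian dphi_mean <= 1.9 deg for elevation 0..-30",
         check = function(map, sm) {
           nd <- map$nodes
           sel <- nd$valid & nd$azimuth_deg == 0 &
             nd$elevation_deg <= 0 & nd$elevation_deg >= -30
           all(nd$dphi_mean_deg[sel] <= 1.9)
         }),
    list(name = "frontal-meridian dphi_mean >= 2.0 deg at elevation +20",
         check = function(map, sm) {
           nd <- map$nodes
           sel <- nd$valid & nd$azimuth_deg == 0 & nd$elevation_deg == 20
           any(sel) && all(nd$dphi_mean_deg[sel] >= 2.0)
         })
  )
}

#' End-to-end parameter recovery on a synthetic eye
#'
#' Builds the configured eye, scans it over the goniometer grid
#' (optionally rendering frames and detecting pseudopupil centres instead
#' of using the generator's centres directly), assembles the acuity map,
#' and compares the recovered delta-phi field against the generator's own
#' finite-difference truth (a noiseless scan of the same eye through the
#' same estimator) and against the configured acute-zone claim checks.
#'
#' @param config A [run_config()], a plain list, or a config file path.
#' @return A list of class `"recovery_report"`: the recovered `map`, its
#'   `summary`, the `truth_map`, a per-node comparison table `nodes`
#'   (truth vs recovered `dphi_mean`), `rmse_deg` and `max_abs_err_deg`
#'   over valid interior nodes, the claim-check results `claims`, and
#'   `pass` (all claims passed).
#' @export
run_recover <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  field <- config_field(cfg)
  model <- build_eye(field, pitch_um = cfg$pitch_um, seed = cfg$seed,
                     scan_lat_range = cfg$lat_range,
                     scan_lon_range = cfg$lon_range)
  truth_obs <- scan_eye(model, cfg$lat_range, cfg$lon_range, cfg$step_deg,
                        noise_sd_facets = 0)
  obs <- if (cfg$use_frames) {
    scan_frames(model, cfg)
  } else if (cfg$noise_sd_facets > 0) {
    scan_eye(model, cfg$lat_range, cfg$lon_range, cfg$step_deg,
             noise_sd_facets = cfg$noise_sd_facets, seed = cfg$seed)
  } else {
    truth_obs
  }
  map <- build_map(obs)
  truth_map <- build_map(truth_obs)
  sm <- summarize_map(map, threshold_deg = cfg$threshold_deg)

  cmp <- merge(
    truth_map$nodes[c("azimuth_deg", "elevation_deg", "dphi_mean_deg",
                      "valid", "edge_flag")],
    map$nodes[c("azimuth_deg", "elevation_deg", "dphi_mean_deg", "valid")],
    by = c("azimuth_deg", "elevation_deg"),
    suffixes = c("_truth", "_recovered"))
  ok <- cmp$valid_truth & cmp$valid_recovered & !cmp$edge_flag
  err <- cmp$dphi_mean_deg_recovered[ok] - cmp$dphi_mean_deg_truth[ok]

  claims <- cfg$claims
  if (is.null(claims) && cfg$preset == "honeybee") claims <- honeybee_claims()
  claim_results <- lapply(claims, function(cl) {
    list(name = cl$name, pass = isTRUE(cl$check(map, sm)))
  })

  structure(
    list(config = cfg, map = map, truth_map = truth_map, summary = sm,
         nodes = cmp,
         rmse_deg = if (any(ok)) sqrt(mean(err^2)) else NA_real_,
         max_abs_err_deg = if (any(ok)) max(abs(err)) else NA_real_,
         n_interior = sum(ok),
         claims = claim_results,
         pass = all(vapply(claim_results, `[[`, logical(1), "pass"))),
    class = "recovery_report"
  )
}

# frame-based observation path: render each pose, detect the centre,
# register via the rendered landmarks
scan_frames <- function(model, cfg) {
  optics <- do.call(optics_params, as.list(cfg$optics))
  lats <- seq(cfg$lat_range[1], cfg$lat_range[2], by = cfg$step_deg)
  lons <- seq(cfg$lon_range[1], cfg$lon_range[2], by = cfg$step_deg)
  rows <- list()
  k <- 0L
  for (lat in lats) {
    for (lon in lons) {
      k <- k + 1L
      # saturated landmark crystals would outshine the pupil peak, so
      # detection runs on a landmark-free render of the same pose while
      # registration is solved from the landmark render
      op_det <- optics
      op_det$landmark_count <- 0L
      fr <- render_frame(model, lat, lon, op_det, mode = "fluorescent",
                         seed = model$seed + k)
      det <- detect_centre(fr, mode = "bright")
      ref <- if (optics$landmark_count >= 2) {
        frl <- render_frame(model, lat, lon, optics, mode = "fluorescent",
                            seed = model$seed + k)
        solve_lattice_frame(frl$landmarks[c("row_px", "col_px")],
                            lattice_coord(frl$landmarks$u, frl$landmarks$v))
      } else {
        fr$lattice_frame
      }
      centre <- pixel_to_lattice(det$centre_px, ref)
      rows[[k]] <- data.frame(latitude_deg = lat, longitude_deg = lon,
                              u_facets = centre$u, v_facets = centre$v,
                              facet_diameter_um = model$pitch_um)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> preset '%s', %d interior nodes, RMSE %.4g deg, max |err| %.4g deg\n",
    x$config$preset, x$n_interior, x$rmse_deg, x$max_abs_err_deg))
  print(x$summary)
  for (cl in x$claims) {
    cat(sprintf("  [%s] %s\n", if (cl$pass) "PASS" else "FAIL", cl$name))
  }
  invisible(x)
}
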