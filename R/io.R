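#' Read and write goniometer observation tables
#'
#' Observations travel as tab-separated text with the fixed header
#' `latitude_deg longitude_deg u_facets v_facets facet_diameter_um`
#' (degrees and micrometres; decimal point only).
#' Blank lines are ignored; any missing column or non-numeric cell is a
#' parse error reporting the line number.
#'
#' @param path File path.
#' @param obs Observation data.frame (see [scan_eye()]).
#' @return `read_observations()` returns the observation data.frame;
#'   `write_observations()` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  cols <- c("latitude_deg", "longitude_deg", "u_facets", "v_facets",
            "facet_diameter_um")
  read_numeric_table(path, cols, sep = "\t")
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  cols <- c("latitude_deg", "longitude_deg", "u_facets", "v_facets",
            "facet_diameter_um")
  if (!all(cols %in% names(obs))) {
    stop("observations must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  write_numeric_table(obs[cols], path, sep = "\t")
  invisible(path)
}

MAP_COLS <- c("azimuth_deg", "elevation_deg", "dphi_h_deg", "dphi_v_deg",
              "dphi_mean_deg", "dphi_3axis_deg", "facet_diameter_um",
              "valid", "edge_flag")

#' Read and write acuity maps
#'
#' Maps travel as comma-separated text with the fixed header
#' `azimuth_deg, elevation_deg, dphi_h_deg, dphi_v_deg, dphi_mean_deg,
#' dphi_3axis_deg, facet_diameter_um, valid, edge_flag`.  Invalid nodes
#' carry `valid = 0` and empty delta-phi cells.  Finite values round-trip
#' losslessly to better than 1e-9.
#'
#' @param map An `"acuity_map"`.
#' @param path File path.
#' @return `read_map()` returns an `"acuity_map"`; `write_map()` returns
#'   `path` invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "acuity_map"))
  nd <- map$nodes[MAP_COLS]
  nd$valid <- as.integer(nd$valid)
  nd$edge_flag <- as.integer(nd$edge_flag)
  write_numeric_table(nd, path, sep = ",")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  nd <- read_numeric_table(path, MAP_COLS, sep = ",", allow_empty = TRUE)
  nd$valid <- nd$valid != 0
  nd$edge_flag <- nd$edge_flag != 0
  lats <- sort(unique(nd$elevation_deg))
  lons <- sort(unique(nd$azimuth_deg))
  nd <- nd[order(nd$elevation_deg, nd$azimuth_deg), ]
  rownames(nd) <- NULL
  structure(
    list(nodes = nd,
         meta = list(lat_range = range(lats), lon_range = range(lons),
                     step_deg = if (length(lats) > 1) diff(lats)[1] else NA,
                     n_lat = length(lats), n_lon = length(lons))),
    class = "acuity_map"
  )
}

#' Write a map summary as JSON
#'
#' @param summary A `"map_summary"` (see [summarize_map()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "map_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# --- plain-text numeric table plumbing -----------------------------------

NUM_RE <- "^[-+]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][-+]?[0-9]+)?$"

read_numeric_table <- function(path, cols, sep, allow_empty = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty table: ", path, call. = FALSE)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  header <- trimws(header)
  if (!identical(header, cols)) {
    missing <- setdiff(cols, header)
    if (length(missing)) {
      stop("missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    stop("header must be exactly: ", paste(cols, collapse = sep),
         call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) == 0) stop("table has no data rows", call. = FALSE)
  parsed <- lapply(seq_along(body), function(i) {
    cells <- trimws(strsplit(body[i], sep, fixed = TRUE)[[1]])
    length(cells) <- length(cols)  # pad trailing empties
    cells[is.na(cells)] <- ""
    empty <- cells == ""
    bad <- !empty & !grepl(NUM_RE, cells)
    if (any(bad)) {
      stop(sprintf("line %d: non-numeric value '%s' in column %s",
                   lineno[-1][i], cells[bad][1], cols[bad][1]),
           call. = FALSE)
    }
    if (any(empty) && !allow_empty) {
      stop(sprintf("line %d: empty cell in column %s",
                   lineno[-1][i], cols[empty][1]), call. = FALSE)
    }
    out <- suppressWarnings(as.numeric(cells))
    out
  })
  df <- as.data.frame(do.call(rbind, parsed))
  names(df) <- cols
  df
}

write_numeric_table <- function(df, path, sep) {
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (!is.finite(v)) "" else sprintf("%.12g", v)
    }, character(1))
    out
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  lines <- c(paste(names(df), collapse = sep),
             apply(cells, 1, paste, collapse = sep))
  writeLines(lines, path)
}
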