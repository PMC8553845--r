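# Shared fixtures, all built in code at test time.

# frame containing an analytic Gaussian spot at a known sub-pixel centre
gaussian_frame <- function(centre = c(24.3, 31.7), sigma_px = 5,
                           size = 64, pixel_scale_um = 2,
                           background = 0) {
  r <- matrix(seq_len(size), size, size)
  c <- t(r)
  m <- background + (1 - background) *
    exp(-((r - centre[1])^2 + (c - centre[2])^2) / (2 * sigma_px^2))
  image_frame(m, pixel_scale_um)
}

# linear-ramp frame (values proportional to column index)
ramp_frame <- function(size = 32) {
  image_frame(matrix(rep(seq_len(size), each = size) / size,
                     size, size, byrow = FALSE),
              pixel_scale_um = 1)
}

# small uniform-field eye for cheap scans
uniform_eye <- function(g = 2, ...) {
  build_eye(uniform_field(g), ...)
}

# default honeybee model + noiseless default-grid scan, computed once
honeybee_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_eye(honeybee_field())
    cache
  }
})

honeybee_scan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- scan_eye(honeybee_model())
    cache
  }
})

honeybee_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_map(honeybee_scan())
    cache
  }
})
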