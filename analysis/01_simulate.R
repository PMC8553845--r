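#!/usr/bin/env Rscript
# Stage 1 — simulate the study data.
#
# Builds the honeybee-forager synthetic eye (1.30 deg frontal minimum on
# a 10 deg plateau, shallow azimuthal and ventral rises, steep dorsal
# rise), scans it over the standard goniometer grid (latitude -40..+40,
# longitude -10..+60, 10 deg steps) both noiselessly and with 0.2-facet
# centre-localisation noise, and renders example fluorescent/dark frame
# pairs.  Outputs go under results/.

suppressPackageStartupMessages(library(facetmap))

dir.create("results/frames", recursive = TRUE, showWarnings = FALSE)

model <- build_eye(honeybee_field(), seed = 1L)
print(model)

obs <- scan_eye(model)
write_observations(obs, "results/observations_noiseless.tsv")
cat(sprintf("noiseless scan: %d observations, pupil centre spans u [%.1f, %.1f], v [%.1f, %.1f]\n",
            nrow(obs), min(obs$u_facets), max(obs$u_facets),
            min(obs$v_facets), max(obs$v_facets)))

obs_noisy <- scan_eye(model, noise_sd_facets = 0.2, seed = 42L)
write_observations(obs_noisy, "results/observations_noisy.tsv")
cat(sprintf("noisy scan (sd 0.2 facets, seed 42): per-component shift sd %.3f facets\n",
            sd(obs_noisy$u_facets - obs$u_facets)))

# example frames at the frontal axis and 20 deg azimuth
op <- optics_params(na = 0.15, landmark_count = 6L, noise_sd = 0.01)
for (pose in list(c(0, 0), c(0, 20))) {
  for (mode in c("fluorescent", "dark")) {
    fr <- render_frame(model, pose[1], pose[2], op, mode = mode)
    path <- sprintf("results/frames/%s_lat%+03d_lon%+03d.tif",
                    mode, pose[1], pose[2])
    write_frame(fr, path)
    cat("wrote", path, "\n")
  }
}
cat("done\n")
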