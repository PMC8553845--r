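#!/usr/bin/env Rscript
# Stage 3 — build the acuity map.
#
# Reads the stage-1 observation tables, converts pseudopupil-centre
# displacements per goniometer step into local interommatidial angles,
# writes the map (CSV) and its acute-zone summary (JSON), and draws an
# equirectangular contour figure.

suppressPackageStartupMessages(library(facetmap))

obs <- read_observations("results/observations_noiseless.tsv")
map <- build_map(obs)
print(map)
write_map(map, "results/acuity_map.csv")

sm <- summarize_map(map, threshold_deg = 2.0)
print(sm)
write_summary(sm, "results/acuity_summary.json")

nd <- map$nodes
cat(sprintf("equator (el 0), az 0..40:  max dphi_mean %.4f deg\n",
            max(nd$dphi_mean_deg[nd$elevation_deg == 0 &
                                   nd$azimuth_deg >= 0 & nd$azimuth_deg <= 40])))
cat(sprintf("frontal meridian, el 0..-30: max dphi_mean %.4f deg\n",
            max(nd$dphi_mean_deg[nd$azimuth_deg == 0 &
                                   nd$elevation_deg <= 0 & nd$elevation_deg >= -30])))
cat(sprintf("frontal meridian, el +20:    dphi_mean %.4f deg\n",
            nd$dphi_mean_deg[nd$azimuth_deg == 0 & nd$elevation_deg == 20]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  p <- plot_map(map)
  ggplot2::ggsave("results/acuity_map.png", p, width = 7, height = 6, dpi = 150)
  cat("wrote results/acuity_map.png\n")
}
cat("wrote results/acuity_map.csv and results/acuity_summary.json\n")
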