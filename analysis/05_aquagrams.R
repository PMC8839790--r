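#!/usr/bin/env Rscript
# Wavelength voting and classic aquagrams: pool the top-20 wavelengths from
# PCA loadings, PCA-LDA weights, PLSR regression vectors and the
# MSC / 2nd-derivative subtraction spectra, bucket them into the 12 WAMACs,
# and compute the 24 aquagrams (8 per honey type). This driver runs the
# whole replay through run_study() on a compact pretreatment grid and
# renders the radar charts.
#
# Run from the repository root:  Rscript analysis/05_aquagrams.R [seed]

library(aquaheat)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cfg <- run_config(
  seed = seed, out_dir = "results/study",
  grid_codes = c("raw", "snv", "msc", "deTr_msc", "sgol@2-21-0_snv",
                 "sgol@2-21-0_msc", "sgol@2-13-0_sgol@2-13-2"),
  pc_candidates = 2:10, max_lvs = 10, render_figures = TRUE)
report <- run_study(cfg)
print(report)

for (ty in names(report$per_type)) {
  ag <- report$per_type[[ty]]$aquagrams
  coords <- sort(unique(unlist(lapply(ag, function(a)
    a$coordinates$wavelength))))
  message(sprintf("%-15s aquagrams: %d, WAMAC coordinates in use: %s",
                  ty, length(ag), paste(coords, collapse = " ")))
}
message("aquagram CSVs + radar PNGs and model summary in results/study/")
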