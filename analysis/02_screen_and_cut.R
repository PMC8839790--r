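#!/usr/bin/env Rscript
# Outlier screening (Hotelling T2 + Q residuals per honey type, on the raw
# full-range spectra) and cutting to the 1300-1600 nm working range.
# Writes the outlier audit under results/.
#
# Run from the repository root:  Rscript analysis/02_screen_and_cut.R [seed]

library(aquaheat)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

spectra <- if (file.exists("results/data/spectra.csv")) {
  message("reading results/data/spectra.csv")
  read_spectra_csv("results/data/spectra.csv")
} else {
  generate_spectra(generate_design(), default_synth_params(seed))
}

screened <- screen_outliers(spectra, alpha = 0.999)
for (ty in names(screened$reports)) {
  r <- screened$reports[[ty]]
  message(sprintf("%-15s kept %d / %d spectra (n_pcs = %d)",
                  ty, sum(r$keep_mask), length(r$keep_mask), r$n_pcs))
  write_outlier_report(r, spectra$meta[spectra$meta$honey_type == ty, ],
                       sprintf("results/outliers_%s.csv", ty))
}

work <- cut_range(screened$spectra, 1300, 1600)
message(sprintf("working range %g-%g nm: %d wavelengths",
                min(work$wavelengths), max(work$wavelengths),
                length(work$wavelengths)))
write_spectra_csv(work, "results/data/spectra_1300_1600.csv")
message("wrote results/outliers_*.csv and results/data/spectra_1300_1600.csv")
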