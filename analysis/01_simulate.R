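#!/usr/bin/env Rscript
# Simulate the heat-treatment study: 3 honey types x 17 levels x 3 replicate
# bottles, 3 fills x 5 scans per sample, plus the HMF table. Writes the
# data bundle under results/data/.
#
# Run from the repository root:  Rscript analysis/01_simulate.R [seed]

library(aquaheat)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

params <- default_synth_params(seed)
design <- generate_design()
spectra <- generate_spectra(design, params)
hmf <- generate_hmf(design, params)

message(sprintf("design: %d samples (%d per type, %d treatment levels/type)",
                nrow(design), 51, 17))
message(sprintf("spectra: %d scans x %d wavelengths (%.0f-%.0f nm)",
                nrow(spectra$absorbance), length(spectra$wavelengths),
                min(spectra$wavelengths), max(spectra$wavelengths)))
lvl <- table(paste(spectra$meta$honey_type, spectra$meta$temperature_C,
                   spectra$meta$time_min))
message(sprintf("spectra per treatment level per type: %d (expected 45)",
                unique(lvl)))

write_spectra_csv(spectra, "results/data/spectra.csv")
utils::write.csv(hmf, "results/data/hmf.csv", row.names = FALSE)
# record the generator settings used (reproducibility manifest)
flat <- params[!(names(params) %in% "archetypes")]
manifest <- c(
  lapply(flat, function(x) paste(format(x, digits = 12), collapse = ",")),
  list(archetypes = paste(names(params$archetypes), collapse = ",")))
writeLines(paste(names(manifest), unlist(manifest), sep = ": "),
           "results/data/params.yml")
message("wrote results/data/{spectra.csv, hmf.csv, params.yml}")
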