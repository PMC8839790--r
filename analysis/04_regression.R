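#!/usr/bin/env Rscript
# PLS regression of temperature and holding time with replicate-blocked CV:
# two general models plus eight detailed models per honey type, optimized
# over the full 41-spec pretreatment grid by best cross-validated R2.
#
# Run from the repository root:  Rscript analysis/04_regression.R [seed]

library(aquaheat)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

work <- if (file.exists("results/data/spectra_1300_1600.csv")) {
  read_spectra_csv("results/data/spectra_1300_1600.csv")
} else {
  cut_range(generate_spectra(generate_design(), default_synth_params(seed)),
            1300, 1600)
}

grid <- enumerate_grid()
tasks <- function(ty) {
  c(list(general_temperature = model_task("general_temperature", ty),
         general_time = model_task("general_time", ty)),
    stats::setNames(lapply(c(60L, 120L, 180L, 240L), function(tm)
      model_task("detailed_temperature", ty, tm)),
      sprintf("temp_within_%dmin", c(60, 120, 180, 240))),
    stats::setNames(lapply(c("40", "60", "80", "100"), function(tc)
      model_task("detailed_time", ty, tc)),
      sprintf("time_within_%sC", c("40", "60", "80", "100"))))
}

rows <- list()
for (ty in c("sunflower", "bastard_indigo", "acacia")) {
  for (key in names(tasks(ty))) {
    opt <- optimize_pretreatment(work, tasks(ty)[[key]], grid, "R2CV")
    b <- opt$best
    rows[[paste(ty, key)]] <- data.frame(
      honey_type = ty, model = key, pretreatment = opt$best_spec,
      n_lvs = b$n_lvs, R2C = b$R2C, R2CV = b$R2CV,
      RMSEC = b$RMSEC, RMSECV = b$RMSECV, RPDC = b$RPDC, RPDCV = b$RPDCV)
  }
  g <- rows[[paste(ty, "general_temperature")]]
  message(sprintf("%-15s general temperature: R2CV %.2f RMSECV %.1f C (%s)",
                  ty, g$R2CV, g$RMSECV, g$pretreatment))
}

out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
utils::write.csv(out, "results/plsr_models.csv", row.names = FALSE)
message("wrote results/plsr_models.csv (", nrow(out), " models)")
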