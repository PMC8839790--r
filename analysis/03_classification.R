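#!/usr/bin/env Rscript
# PCA-LDA classification with leave-one-replicate-out CV: the general
# temperature/time models and the eight detailed models per honey type,
# each optimized over the pretreatment grid. The full 41-spec grid over all
# 30 classification tasks is expensive; this driver optimizes the general
# models over the full grid and the detailed models over the grid's
# 11-member window-21 + scatter/baseline subset, which contains every kind
# of step combination. Writes per-task winners to results/.
#
# Run from the repository root:  Rscript analysis/03_classification.R [seed]

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

full_grid <- enumerate_grid()
codes <- vapply(full_grid, format, character(1))
small_grid <- full_grid[codes == "raw" | !grepl("sgol@2-1[37]", codes)]

rows <- list()
for (ty in c("sunflower", "bastard_indigo", "acacia")) {
  for (fam in c("general_temperature", "general_time")) {
    opt <- optimize_pretreatment(work, model_task(fam, ty), full_grid,
                                 "validation_accuracy")
    b <- opt$best
    rows[[paste(ty, fam)]] <- data.frame(
      honey_type = ty, model = fam, pretreatment = opt$best_spec,
      n_pcs = b$n_pcs, training = b$training_accuracy,
      validation = b$validation_accuracy, control = b$control_accuracy)
    message(sprintf("%-15s %-20s %-24s train %5.1f%% val %5.1f%%",
                    ty, fam, opt$best_spec, b$training_accuracy,
                    b$validation_accuracy))
  }
  for (tm in c(60L, 120L, 180L, 240L)) {
    opt <- optimize_pretreatment(work,
                                 model_task("detailed_temperature", ty, tm),
                                 small_grid, "validation_accuracy")
    b <- opt$best
    key <- sprintf("temp_within_%dmin", tm)
    rows[[paste(ty, key)]] <- data.frame(
      honey_type = ty, model = key, pretreatment = opt$best_spec,
      n_pcs = b$n_pcs, training = b$training_accuracy,
      validation = b$validation_accuracy, control = b$control_accuracy)
  }
  for (tc in c("40", "60", "80", "100")) {
    opt <- optimize_pretreatment(work, model_task("detailed_time", ty, tc),
                                 small_grid, "validation_accuracy")
    b <- opt$best
    key <- sprintf("time_within_%sC", tc)
    rows[[paste(ty, key)]] <- data.frame(
      honey_type = ty, model = key, pretreatment = opt$best_spec,
      n_pcs = b$n_pcs, training = b$training_accuracy,
      validation = b$validation_accuracy, control = b$control_accuracy)
  }
  message(sprintf("%s: 8 detailed models done", ty))
}

out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
utils::write.csv(out, "results/pcalda_models.csv", row.names = FALSE)
message("wrote results/pcalda_models.csv (", nrow(out), " models)")
message(sprintf("mean detailed validation: sunflower %.1f%%, acacia %.1f%%",
                mean(out$validation[out$honey_type == "sunflower" &
                                      grepl("within", out$model)]),
                mean(out$validation[out$honey_type == "acacia" &
                                      grepl("within", out$model)])))
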