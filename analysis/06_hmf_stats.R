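#!/usr/bin/env Rscript
# HMF statistics: assumption checks, two-way ANOVA on the synthetic HMF
# table, control-comparison stars, and the summary-statistics post hoc
# verification against the published per-level means/SDs (Games-Howell
# computable from mean, SD and n alone).
#
# Run from the repository root:  Rscript analysis/06_hmf_stats.R [seed]

library(aquaheat)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

hmf <- if (file.exists("results/data/hmf.csv")) {
  utils::read.csv("results/data/hmf.csv",
                  colClasses = c(temperature_C = "character"))
} else {
  generate_hmf(generate_design(), default_synth_params(seed))
}

## synthetic table: effects and stars per type
eff_rows <- list(); star_rows <- list()
for (ty in unique(hmf$honey_type)) {
  h <- hmf[hmf$honey_type == ty, ]
  eff <- two_way_anova(h)
  eff$honey_type <- ty
  eff_rows[[ty]] <- eff
  st <- control_comparison(h)
  st$honey_type <- ty
  star_rows[[ty]] <- st
  message(sprintf(
    "%-15s two-way ANOVA p: temperature %.2g, time %.2g, interaction %.2g; %d/16 levels differ from control",
    ty, eff$p[1], eff$p[2], eff$p[3], sum(st$star)))
}
utils::write.csv(do.call(rbind, c(eff_rows, list(make.row.names = FALSE))),
                 "results/hmf_anova.csv", row.names = FALSE)
utils::write.csv(do.call(rbind, c(star_rows, list(make.row.names = FALSE))),
                 "results/hmf_stars.csv", row.names = FALSE)

## published summaries: within-row (capital) and within-column (lowercase)
## letter displays from Games-Howell on (mean, sd, n)
ref <- hmf_reference_summary()
letter_rows <- list()
for (ty in unique(ref$honey_type)) {
  rt <- ref[ref$honey_type == ty & ref$temperature_C != "CONTROL", ]
  for (tm in unique(rt$time_min)) {
    row <- rt[rt$time_min == tm, ]
    ph <- posthoc(data.frame(group = row$temperature_C, mean = row$mean,
                             sd = row$sd, n = row$n), homogeneous = FALSE)
    lt <- letter_display(ph, c("40", "60", "80", "100"),
                         letters_pool = LETTERS)
    letter_rows[[paste(ty, tm)]] <- data.frame(
      honey_type = ty, time_min = tm, temperature_C = names(lt),
      letters = unname(lt))
  }
}
letters_df <- do.call(rbind, c(letter_rows, list(make.row.names = FALSE)))
utils::write.csv(letters_df, "results/hmf_reference_letters.csv",
                 row.names = FALSE)
sun240 <- letters_df[letters_df$honey_type == "sunflower" &
                       letters_df$time_min == 240, ]
message("sunflower 240 min row letters: ",
        paste(sun240$temperature_C, sun240$letters, collapse = ", "))
message("wrote results/hmf_{anova,stars,reference_letters}.csv")
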