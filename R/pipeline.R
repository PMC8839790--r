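## Full study replay: simulate/load -> outlier screen -> range cut ->
## general PCA-LDA optimization -> PCA display models -> detailed PCA-LDA ->
## PLSR -> subtraction spectra -> wavelength votes -> aquagrams -> HMF stats.

#' Default run configuration
#'
#' All settings of a study replay in one list: generator parameters, the
#' working spectral range (1300-1600 nm), the pretreatment grid, candidate
#' model dimensions, vote count, and the output directory. `grid_codes`
#' defaults to the full 41-combination grid; a smaller grid replays the
#' identical pipeline structure faster (the methods vignette discusses the
#' problem sizes used by the bundled scripts and tests).
#'
#' @param seed integer seed driving the synthetic generator.
#' @param out_dir output directory (created if missing); NULL disables
#'   file output.
#' @param grid_codes character vector of pretreatment codec strings.
#' @param honey_types honey types to run.
#' @param pc_candidates candidate PC numbers for PCA-LDA.
#' @param max_lvs maximum PLSR latent variables.
#' @param top_k votes per source for WAMAC selection.
#' @param n_fills,n_scans fills per sample / scans per fill to simulate.
#' @param render_figures write radar PNGs (default FALSE).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL,
                       grid_codes = vapply(enumerate_grid(), format,
                                           character(1)),
                       honey_types = c("sunflower", "bastard_indigo",
                                       "acacia"),
                       pc_candidates = 2:15, max_lvs = 12, top_k = 20,
                       n_fills = 3L, n_scans = 5L,
                       render_figures = FALSE) {
  for (code in grid_codes) parse_pretreatment(code)  # validate early
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 grid_codes = grid_codes, honey_types = honey_types,
                 pc_candidates = pc_candidates, max_lvs = max_lvs,
                 top_k = top_k, n_fills = as.integer(n_fills),
                 n_scans = as.integer(n_scans),
                 range_nm = c(1300, 1600),
                 render_figures = render_figures),
            class = "run_config")
}

#' Replay the whole study on synthetic data
#'
#' Executes the full analysis sequence for every honey type in the
#' configuration: simulate spectra and HMF, screen outliers per type on the
#' raw full-range spectra, cut to 1300-1600 nm, optimize the general
#' temperature and time PCA-LDA models over the pretreatment grid, build
#' PCA display models reusing the general winners' pretreatments, fit the
#' eight detailed PCA-LDA and eight PLSR models per type plus the two
#' general PLSR models, compute subtraction spectra, pool wavelength votes,
#' select WAMAC coordinates, compute the eight aquagrams per type
#' (4 temperature-pattern + 4 time-pattern), and run the HMF statistics.
#' Deterministic for a fixed seed.
#'
#' @param config run_config.
#' @return list of class `study_report`; see its `summary` element for the
#'   headline tables.
#' @export
run_study <- function(config = run_config()) {
  params <- default_synth_params(config$seed)
  design <- generate_design()
  design <- design[design$honey_type %in% config$honey_types, , drop = FALSE]
  spectra <- generate_spectra(design, params, config$n_fills, config$n_scans)
  hmf <- generate_hmf(design, params)
  screened <- screen_outliers(spectra)
  work <- cut_range(screened$spectra, config$range_nm[1], config$range_nm[2])
  grid <- lapply(config$grid_codes, parse_pretreatment)

  report <- list(config = config, outliers = screened$reports,
                 n_spectra = nrow(work$absorbance))
  per_type <- list()
  for (ty in config$honey_types) {
    ty_res <- list()
    ## general PCA-LDA models (temperature, time), optimized over the grid
    for (fam in c("general_temperature", "general_time")) {
      task <- model_task(fam, ty)
      opt <- optimize_pretreatment(work, task, grid,
                                   metric = "validation_accuracy",
                                   pc_candidates = config$pc_candidates)
      ty_res$general[[fam]] <- opt
    }
    ## PCA display models reuse the general winners' pretreatments
    ty_idx <- which(work$meta$honey_type == ty)
    ty_set <- subset_spectra(work, ty_idx)
    ty_res$pca <- lapply(c("general_temperature", "general_time"),
                         function(fam) {
      pre <- apply_pretreatment(ty_res$general[[fam]]$best_spec,
                                ty_set$absorbance,
                                wavelengths = ty_set$wavelengths)
      fit_pca(pre$train, 2)
    })
    names(ty_res$pca) <- c("temperature", "time")

    ## detailed PCA-LDA models: 4 temperature-in-time + 4 time-in-temperature
    detailed <- list()
    for (tm in c(60L, 120L, 180L, 240L)) {
      task <- model_task("detailed_temperature", ty, tm)
      detailed[[paste0("temp_within_", tm, "min")]] <-
        optimize_pretreatment(work, task, grid,
                              metric = "validation_accuracy",
                              pc_candidates = config$pc_candidates)
    }
    for (tc in c("40", "60", "80", "100")) {
      task <- model_task("detailed_time", ty, tc)
      detailed[[paste0("time_within_", tc, "C")]] <-
        optimize_pretreatment(work, task, grid,
                              metric = "validation_accuracy",
                              pc_candidates = config$pc_candidates)
    }
    ty_res$detailed <- detailed

    ## PLSR: 2 general + 8 detailed
    plsr <- list()
    for (fam in c("general_temperature", "general_time")) {
      task <- model_task(fam, ty)
      plsr[[fam]] <- optimize_pretreatment(work, task, grid,
                                           metric = "R2CV",
                                           max_lvs = config$max_lvs)
    }
    for (tm in c(60L, 120L, 180L, 240L)) {
      task <- model_task("detailed_temperature", ty, tm)
      plsr[[paste0("temp_within_", tm, "min")]] <-
        optimize_pretreatment(work, task, grid, metric = "R2CV",
                              max_lvs = config$max_lvs)
    }
    for (tc in c("40", "60", "80", "100")) {
      task <- model_task("detailed_time", ty, tc)
      plsr[[paste0("time_within_", tc, "C")]] <-
        optimize_pretreatment(work, task, grid, metric = "R2CV",
                              max_lvs = config$max_lvs)
    }
    ty_res$plsr <- plsr

    ## subtraction spectra + votes + aquagram coordinates, per comparison
    aquagrams <- list()
    for (tm in c(60L, 120L, 180L, 240L)) {
      key <- paste0("temp_within_", tm, "min")
      task <- model_task("detailed_temperature", ty, tm)
      cmp <- subset_spectra(work, task_subset(task, work$meta))
      diffs <- subtraction_spectra(cmp, "temperature_C")
      sources <- c(
        stats::setNames(lapply(seq_along(diffs$groups)[-1], function(i)
          diffs$msc[i, ]), paste0("diff_msc_", diffs$groups[-1])),
        stats::setNames(lapply(seq_along(diffs$groups)[-1], function(i)
          diffs$sgol2d[i, ]), paste0("diff_sg2d_", diffs$groups[-1])),
        list(pca = ty_res$pca$temperature,
             plsr = plsr[[key]]$best),
        list(pcalda = refit_pcalda(cmp, task, detailed[[key]])))
      votes <- collect_votes(sources, cmp$wavelengths, config$top_k)
      coords <- select_coordinates(votes)
      aquagrams[[key]] <- classic_aquagram(cmp, coords, "temperature_C")
    }
    for (tc in c("40", "60", "80", "100")) {
      key <- paste0("time_within_", tc, "C")
      task <- model_task("detailed_time", ty, tc)
      cmp <- subset_spectra(work, task_subset(task, work$meta))
      diffs <- subtraction_spectra(cmp, "time_min")
      grouping <- ifelse(cmp$meta$temperature_C == "CONTROL", "CONTROL",
                         as.character(cmp$meta$time_min))
      sources <- c(
        stats::setNames(lapply(seq_along(diffs$groups)[-1], function(i)
          diffs$msc[i, ]), paste0("diff_msc_", diffs$groups[-1])),
        stats::setNames(lapply(seq_along(diffs$groups)[-1], function(i)
          diffs$sgol2d[i, ]), paste0("diff_sg2d_", diffs$groups[-1])),
        list(pca = ty_res$pca$time,
             plsr = plsr[[key]]$best),
        list(pcalda = refit_pcalda(cmp, task, detailed[[key]])))
      votes <- collect_votes(sources, cmp$wavelengths, config$top_k)
      coords <- select_coordinates(votes)
      aquagrams[[key]] <- classic_aquagram(cmp, coords, grouping)
    }
    ty_res$aquagrams <- aquagrams

    ## HMF statistics for this type
    hmf_ty <- hmf[hmf$honey_type == ty, , drop = FALSE]
    ty_res$hmf <- list(anova = two_way_anova(hmf_ty),
                       stars = control_comparison(hmf_ty))
    per_type[[ty]] <- ty_res
  }
  report$per_type <- per_type
  report$hmf_table <- hmf
  report$summary <- summarize_study(report)

  if (!is.null(config$out_dir)) write_study_outputs(report, config)
  structure(report, class = "study_report")
}

## internal: refit the winning PCA-LDA on the full comparison set so its
## wavelength weights can vote
refit_pcalda <- function(cmp, task, opt) {
  pre <- apply_pretreatment(opt$best_spec, cmp$absorbance,
                            wavelengths = cmp$wavelengths)
  fit_pca_lda(pre$train, task_labels(task, cmp$meta), opt$best$n_pcs)
}

## internal: headline tables of a study report
summarize_study <- function(report) {
  rows <- list()
  for (ty in names(report$per_type)) {
    tr <- report$per_type[[ty]]
    for (key in names(tr$detailed)) {
      b <- tr$detailed[[key]]$best
      rows[[paste(ty, key)]] <- data.frame(
        honey_type = ty, model = key, kind = "pcalda",
        pretreatment = tr$detailed[[key]]$best_spec,
        n_components = b$n_pcs,
        training = b$training_accuracy, validation = b$validation_accuracy,
        control = b$control_accuracy, stringsAsFactors = FALSE)
    }
    for (key in names(tr$plsr)) {
      b <- tr$plsr[[key]]$best
      rows[[paste(ty, "plsr", key)]] <- data.frame(
        honey_type = ty, model = key, kind = "plsr",
        pretreatment = tr$plsr[[key]]$best_spec,
        n_components = b$n_lvs,
        training = b$R2C, validation = b$R2CV,
        control = NA_real_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## internal: CSV/PNG bundle for a study report
write_study_outputs <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary,
                   file.path(config$out_dir, "model_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$hmf_table,
                   file.path(config$out_dir, "hmf_table.csv"),
                   row.names = FALSE)
  for (ty in names(report$per_type)) {
    tr <- report$per_type[[ty]]
    for (key in names(tr$aquagrams)) {
      a <- tr$aquagrams[[key]]
      vals <- as.data.frame(a$values)
      vals <- cbind(group = a$groups, vals)
      utils::write.csv(vals,
                       file.path(config$out_dir,
                                 sprintf("aquagram_%s_%s.csv", ty, key)),
                       row.names = FALSE)
      if (isTRUE(config$render_figures))
        render_radar(a, file.path(config$out_dir,
                                  sprintf("aquagram_%s_%s.png", ty, key)),
                     main = sprintf("%s: %s", ty, key))
    }
    utils::write.csv(tr$hmf$stars,
                     file.path(config$out_dir,
                               sprintf("hmf_stars_%s.csv", ty)),
                     row.names = FALSE)
  }
  invisible(config$out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d honey types, %d spectra after screening\n",
              length(x$per_type), x$n_spectra))
  cat(sprintf("  detailed PCA-LDA models: %d, PLSR models: %d, aquagrams: %d\n",
              sum(vapply(x$per_type, function(t) length(t$detailed),
                         integer(1))),
              sum(vapply(x$per_type, function(t)
                length(t$plsr) - 2L, integer(1))),
              sum(vapply(x$per_type, function(t) length(t$aquagrams),
                         integer(1)))))
  invisible(x)
}

#' Build quick fixture bundles
#'
#' `tiny`: one honey type, 2 replicates, 2 fills x 2 scans — enough design
#' structure for fast end-to-end checks. `default`: the full 153-sample
#' design at 3 fills x 5 scans. Seed-stable.
#'
#' @param scale "tiny" or "default".
#' @param seed generator seed.
#' @return list `spectra` (spectra_set), `hmf` (data.frame),
#'   `params` (synth_params).
#' @export
make_fixtures <- function(scale = c("tiny", "default"), seed = 1L) {
  scale <- match.arg(scale)
  params <- default_synth_params(seed)
  design <- generate_design()
  if (scale == "tiny") {
    design <- design[design$honey_type == "sunflower" &
                       design$replicate %in% c("R1", "R2"), , drop = FALSE]
    spectra <- generate_spectra(design, params, n_fills = 2L, n_scans = 2L)
  } else {
    spectra <- generate_spectra(design, params)
  }
  list(spectra = spectra, hmf = generate_hmf(design, params),
       params = params)
}
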