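## Replicate-blocked cross-validation, model tasks, and the pretreatment /
## PC-number optimization loops.

#' Define a modelling task
#'
#' A task names the classification or regression target and the subset of
#' the study it runs on. Families:
#' \describe{
#'   \item{botanical}{classify honey type (control spectra of all types).}
#'   \item{general_temperature / general_time}{classify temperature level or
#'     holding time across the full design of one honey type.}
#'   \item{detailed_temperature}{classify temperature within one holding
#'     time (`group`, min), control included.}
#'   \item{detailed_time}{classify holding time within one temperature
#'     (`group`, degrees C), control included.}
#' }
#' For regression (PLSR) the same task yields a numeric target: temperature
#' in degrees C with the control coded `control_temperature` (default 25,
#' i.e. ambient; set `NA` to exclude control), or time in minutes with
#' control = 0.
#'
#' @param family task family string (see above).
#' @param honey_type honey type the task is scoped to (ignored for
#'   botanical).
#' @param group time (min) for detailed_temperature, temperature label for
#'   detailed_time.
#' @param control_temperature numeric coding of the control for temperature
#'   regression (default 25; NA drops control rows from regression).
#' @return list of class `model_task`.
#' @export
model_task <- function(family, honey_type = NULL, group = NULL,
                       control_temperature = 25) {
  family <- match.arg(family, c("botanical", "general_temperature",
                                "general_time", "detailed_temperature",
                                "detailed_time"))
  if (family %in% c("detailed_temperature", "detailed_time") &&
      is.null(group))
    stop("detailed tasks need a `group`")
  structure(list(family = family, honey_type = honey_type, group = group,
                 control_temperature = control_temperature),
            class = "model_task")
}

#' Row subset of a spectra_set that a task runs on
#' @param task model_task.
#' @param meta spectra metadata.
#' @return integer row indices.
#' @export
task_subset <- function(task, meta) {
  is_ctrl <- meta$temperature_C == "CONTROL"
  sel <- switch(task$family,
    botanical = is_ctrl & meta$honey_type %in% honey_types(),
    general_temperature = ,
    general_time = meta$honey_type == task$honey_type,
    detailed_temperature = meta$honey_type == task$honey_type &
      (meta$time_min == task$group | is_ctrl),
    detailed_time = meta$honey_type == task$honey_type &
      (meta$temperature_C == task$group | is_ctrl))
  which(sel)
}

#' Class labels of a task
#' @param task model_task.
#' @param meta metadata rows of the task subset.
#' @return character labels.
#' @export
task_labels <- function(task, meta) {
  switch(task$family,
    botanical = meta$honey_type,
    general_temperature = ,
    detailed_temperature = meta$temperature_C,
    general_time = ,
    detailed_time = as.character(meta$time_min))
}

#' Numeric regression target of a task
#' @param task model_task.
#' @param meta metadata rows of the task subset.
#' @return numeric target; NA for rows to exclude.
#' @export
task_numeric <- function(task, meta) {
  if (task$family %in% c("general_temperature", "detailed_temperature")) {
    y <- suppressWarnings(as.numeric(meta$temperature_C))
    y[meta$temperature_C == "CONTROL"] <- task$control_temperature
    y
  } else if (task$family %in% c("general_time", "detailed_time")) {
    as.numeric(meta$time_min)
  } else stop("botanical task has no numeric target")
}

#' Control class label of a task (or NA if none)
#' @param task model_task.
#' @return character.
#' @export
task_control_label <- function(task) {
  switch(task$family,
    botanical = NA_character_,
    general_temperature = ,
    detailed_temperature = "CONTROL",
    general_time = ,
    detailed_time = "0")
}

## Folds -----------------------------------------------------------------------

#' Leave-one-replicate-out folds
#'
#' One fold per replicate bottle: the validation set of a fold is every
#' spectrum (all fills and scans, all treatment levels) of that replicate;
#' the training set is everything else. All 15 scans of a sample always land
#' on the same side, so no sample leaks across the split.
#'
#' @param meta spectra metadata (the task subset).
#' @return list of folds, each `list(replicate, train, validation)` with
#'   integer indices into `meta`.
#' @export
loso_folds <- function(meta) {
  reps <- sort(unique(meta$replicate))
  if (length(reps) < 2)
    stop("leave-one-replicate-out needs >= 2 replicate ids")
  lapply(reps, function(r) {
    val <- which(meta$replicate == r)
    list(replicate = r, train = which(meta$replicate != r),
         validation = val)
  })
}

## internal: LDA on a ready-made score matrix (shared by fit_pca_lda logic)
lda_scores_fit <- function(S, y) {
  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2))
    stop("class-support error: class(es) with < 2 training spectra: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  p <- ncol(S)
  means <- t(vapply(classes, function(cl)
    colMeans(S[y == cl, , drop = FALSE]), numeric(p)))
  W <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    Sc <- sweep(S[y == classes[i], , drop = FALSE], 2, means[i, ])
    W <- W + crossprod(Sc)
  }
  W <- W / (nrow(S) - length(classes))
  W <- W + diag(1e-8 * sum(diag(W)) / p, p)
  Winv <- solve(W)
  priors <- as.numeric(counts) / length(y)
  disc_w <- Winv %*% t(means)
  disc_b <- -0.5 * colSums(t(means) * disc_w) + log(priors)
  list(classes = classes, disc_w = disc_w, disc_b = disc_b)
}

lda_scores_predict <- function(fit, S) {
  sc <- sweep(S %*% fit$disc_w, 2, fit$disc_b, "+")
  fit$classes[max.col(sc, ties.method = "first")]
}

## internal: pretreated fold data for a task
prepare_fold_data <- function(s, task, spec) {
  idx <- task_subset(task, s$meta)
  if (length(idx) == 0) stop("task subset is empty")
  sub <- subset_spectra(s, idx)
  folds <- loso_folds(sub$meta)
  lapply(folds, function(f) {
    pre <- apply_pretreatment(spec, sub$absorbance[f$train, , drop = FALSE],
                              sub$absorbance[f$validation, , drop = FALSE],
                              wavelengths = sub$wavelengths)
    list(replicate = f$replicate,
         Xt = pre$train, Xv = pre$apply,
         meta_t = sub$meta[f$train, , drop = FALSE],
         meta_v = sub$meta[f$validation, , drop = FALSE])
  })
}

## internal: evaluate PCA-LDA over folds for a set of candidate PC numbers.
## PCA is fitted once per fold at max(n_pcs_set); smaller models reuse the
## leading score columns (SVD components are nested).
pcalda_cv_eval <- function(fold_data, task, n_pcs_set) {
  n_pcs_set <- sort(unique(n_pcs_set))
  per_fold <- lapply(fold_data, function(f) {
    yt <- task_labels(task, f$meta_t)
    yv <- task_labels(task, f$meta_v)
    kmax <- min(max(n_pcs_set), nrow(f$Xt) - 1, ncol(f$Xt))
    pca <- fit_pca(f$Xt, kmax)
    St <- pca$scores
    Sv <- project_pca(pca, f$Xv)
    res <- list()
    for (k in n_pcs_set[n_pcs_set <= kmax]) {
      fit <- lda_scores_fit(St[, seq_len(k), drop = FALSE], yt)
      pt <- lda_scores_predict(fit, St[, seq_len(k), drop = FALSE])
      pv <- lda_scores_predict(fit, Sv[, seq_len(k), drop = FALSE])
      res[[as.character(k)]] <- list(
        train_acc = 100 * mean(pt == yt),
        val_pred = pv, val_true = yv)
    }
    res
  })
  lapply(stats::setNames(as.character(n_pcs_set), n_pcs_set), function(kk) {
    fr <- lapply(per_fold, `[[`, kk)
    if (any(vapply(fr, is.null, logical(1)))) return(NULL)
    all_classes <- sort(unique(c(unlist(lapply(fr, `[[`, "val_true")),
                                 unlist(lapply(fr, `[[`, "val_pred")))))
    confusion <- table(
      truth = factor(unlist(lapply(fr, `[[`, "val_true")), all_classes),
      predicted = factor(unlist(lapply(fr, `[[`, "val_pred")), all_classes))
    val_accs <- vapply(fr, function(x) 100 * mean(x$val_pred == x$val_true),
                       numeric(1))
    ctrl <- task_control_label(task)
    control_accuracy <- NA_real_
    if (!is.na(ctrl) && ctrl %in% rownames(confusion)) {
      ctrl_n <- sum(confusion[ctrl, ])
      control_accuracy <- 100 * confusion[ctrl, ctrl] / ctrl_n
    }
    structure(list(
      n_pcs = as.integer(kk),
      folds = lapply(seq_along(fr), function(i)
        list(replicate = fold_data[[i]]$replicate,
             confusion = table(truth = fr[[i]]$val_true,
                               predicted = fr[[i]]$val_pred))),
      confusion = confusion,
      training_accuracy = mean(vapply(fr, `[[`, numeric(1), "train_acc")),
      validation_accuracy = mean(val_accs),
      control_accuracy = control_accuracy), class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> n_pcs=%d training=%.2f%% validation=%.2f%% control=%s\n",
    x$n_pcs, x$training_accuracy, x$validation_accuracy,
    ifelse(is.na(x$control_accuracy), "NA",
           sprintf("%.2f%%", x$control_accuracy))))
  invisible(x)
}

#' Cross-validate a PCA-LDA task
#'
#' Per fold, the pretreatment (including the MSC reference) and the model
#' are fitted on the training replicates only and evaluated on the held-out
#' replicate. Training/validation accuracies are fold-averaged; the control
#' correct-classification rate comes from the pooled validation confusion
#' table.
#'
#' @param s spectra_set (full study or one honey type).
#' @param task model_task.
#' @param spec pretreatment spec or codec string.
#' @param n_pcs number of principal components.
#' @return `cv_result` with folds, confusion and the three accuracies.
#' @export
cross_validate <- function(s, task, spec, n_pcs) {
  fd <- prepare_fold_data(s, task, spec)
  res <- pcalda_cv_eval(fd, task, n_pcs)[[as.character(n_pcs)]]
  if (is.null(res)) stop("n_pcs too large for the task's folds")
  res$spec <- if (is.character(spec)) spec else format(spec)
  res
}

#' Choose the number of principal components
#'
#' Lexicographic rule: maximize validation accuracy; break ties by the
#' smallest (training - validation) gap; remaining ties go to the smallest
#' number of components.
#'
#' @param s spectra_set.
#' @param task model_task.
#' @param spec pretreatment spec or codec string.
#' @param candidates candidate PC numbers (default 2:15).
#' @return the selected `cv_result` (with `$n_pcs`).
#' @export
optimize_pcs <- function(s, task, spec, candidates = 2:15) {
  if (length(candidates) == 0) stop("empty candidate range")
  fd <- prepare_fold_data(s, task, spec)
  all_res <- pcalda_cv_eval(fd, task, candidates)
  all_res <- all_res[!vapply(all_res, is.null, logical(1))]
  if (length(all_res) == 0) stop("no candidate PC number is feasible")
  best <- select_best_pcs(all_res)
  best$spec <- if (is.character(spec)) spec else format(spec)
  best
}

## internal: the stated lexicographic selection rule
select_best_pcs <- function(results) {
  val <- vapply(results, `[[`, numeric(1), "validation_accuracy")
  gap <- vapply(results, function(r)
    r$training_accuracy - r$validation_accuracy, numeric(1))
  npc <- vapply(results, `[[`, integer(1), "n_pcs")
  ord <- order(-val, gap, npc)
  results[[ord[1]]]
}

#' Optimize the pretreatment over a grid
#'
#' Evaluates every pretreatment spec with [optimize_pcs()] (classification,
#' metric `validation_accuracy`) or [cv_plsr()] (regression, metric `R2CV`)
#' and returns the argmax plus the per-spec report. Ties break
#' deterministically by grid order.
#'
#' @param s spectra_set.
#' @param task model_task.
#' @param grid list of pretreatment specs (default [enumerate_grid()]).
#' @param metric "validation_accuracy" or "R2CV".
#' @param pc_candidates candidate PC numbers for classification.
#' @param max_lvs maximum latent variables for regression.
#' @return list `best` (the winning cv_result / plsr_report), `report`
#'   (data.frame over the grid).
#' @export
optimize_pretreatment <- function(s, task, grid = enumerate_grid(),
                                  metric = c("validation_accuracy", "R2CV"),
                                  pc_candidates = 2:15, max_lvs = 12) {
  metric <- match.arg(metric)
  if (length(grid) == 0) stop("empty pretreatment grid")
  results <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    results[[i]] <- if (metric == "validation_accuracy")
      optimize_pcs(s, task, grid[[i]], pc_candidates)
    else cv_plsr(s, task, grid[[i]], max_lvs)
  }
  score <- vapply(results, function(r)
    if (metric == "validation_accuracy") r$validation_accuracy else r$R2CV,
    numeric(1))
  best_i <- which.max(score)  # which.max returns the first maximum
  report <- data.frame(
    spec = vapply(grid, format, character(1)),
    n_components = vapply(results, function(r)
      if (metric == "validation_accuracy") r$n_pcs else r$n_lvs, integer(1)),
    metric = score, stringsAsFactors = FALSE)
  names(report)[3] <- metric
  if (metric == "validation_accuracy") {
    report$training_accuracy <-
      vapply(results, `[[`, numeric(1), "training_accuracy")
    report$control_accuracy <-
      vapply(results, `[[`, numeric(1), "control_accuracy")
  } else {
    report$RMSECV <- vapply(results, `[[`, numeric(1), "RMSECV")
    report$RPDCV <- vapply(results, `[[`, numeric(1), "RPDCV")
  }
  list(best = results[[best_i]], best_spec = report$spec[best_i],
       report = report)
}

## PLSR ------------------------------------------------------------------------

## internal: regression vector using the first `a` latent variables
pls_coef_at <- function(model, a) {
  W <- model$W[, seq_len(a), drop = FALSE]
  P <- model$P[, seq_len(a), drop = FALSE]
  q <- model$q[seq_len(a)]
  as.numeric(W %*% solve(crossprod(P, W), q))
}

#' Cross-validated PLS regression for a task
#'
#' Replicate-blocked PLSR: per fold, pretreatment and a NIPALS PLS model are
#' fitted on the training replicates and the held-out replicate is
#' predicted. The number of latent variables minimizes RMSECV over
#' `1..max_lvs` (pooled held-out predictions). Calibration metrics (R2C,
#' RMSEC, RPDC) come from the final model refitted on the whole task subset
#' at the chosen dimension; validation metrics from the pooled held-out
#' predictions. RPD = SD(y)/RMSE with population SD, so RPD and R2 satisfy
#' RPD = 1/sqrt(1 - R2) on the same split.
#'
#' @param s spectra_set.
#' @param task model_task.
#' @param spec pretreatment spec or codec string.
#' @param max_lvs maximum latent variables (default 12).
#' @return list of class `plsr_report`.
#' @export
cv_plsr <- function(s, task, spec, max_lvs = 12) {
  idx <- task_subset(task, s$meta)
  if (length(idx) == 0) stop("task subset is empty")
  sub <- subset_spectra(s, idx)
  y_all <- task_numeric(task, sub$meta)
  keep <- !is.na(y_all)
  sub <- subset_spectra(sub, keep)
  y_all <- y_all[keep]
  if (stats::sd(y_all) == 0) stop("degenerate (constant) regression target")
  folds <- loso_folds(sub$meta)
  n <- nrow(sub$absorbance)
  pred <- matrix(NA_real_, n, max_lvs)
  for (f in folds) {
    pre <- apply_pretreatment(spec, sub$absorbance[f$train, , drop = FALSE],
                              sub$absorbance[f$validation, , drop = FALSE],
                              wavelengths = sub$wavelengths)
    m <- fit_pls(pre$train, y_all[f$train], max_lvs)
    Xvc <- sweep(pre$apply, 2, m$x_mean)
    for (a in seq_len(m$n_lvs)) {
      beta <- pls_coef_at(m, a)
      pred[f$validation, a] <- as.numeric(Xvc %*% beta) + m$y_mean
    }
  }
  rmse_cv <- apply(pred, 2, function(p)
    if (any(is.na(p))) NA_real_ else sqrt(mean((p - y_all)^2)))
  usable <- which(!is.na(rmse_cv))
  if (length(usable) == 0) stop("no usable latent-variable dimension")
  n_lvs <- usable[which.min(rmse_cv[usable])]
  sd_pop <- sqrt(mean((y_all - mean(y_all))^2))
  rmsecv <- rmse_cv[n_lvs]
  # calibration: final model on the whole task subset
  pre_all <- apply_pretreatment(spec, sub$absorbance,
                                wavelengths = sub$wavelengths)
  final <- fit_pls(pre_all$train, y_all, n_lvs)
  fitted <- predict(final, pre_all$train)
  rmsec <- sqrt(mean((fitted - y_all)^2))
  structure(list(
    spec = if (is.character(spec)) spec else format(spec),
    n_lvs = as.integer(n_lvs),
    regression_vector = final$coefficients,
    y = y_all, cv_predictions = pred[, n_lvs],
    R2C = 1 - rmsec^2 / sd_pop^2,
    R2CV = 1 - rmsecv^2 / sd_pop^2,
    RMSEC = rmsec, RMSECV = rmsecv,
    RPDC = sd_pop / rmsec, RPDCV = sd_pop / rmsecv),
    class = "plsr_report")
}

#' @export
print.plsr_report <- function(x, ...) {
  cat(sprintf(
    "<plsr_report> %d LVs  R2C=%.3f RMSEC=%.3g RPDC=%.2f | R2CV=%.3f RMSECV=%.3g RPDCV=%.2f\n",
    x$n_lvs, x$R2C, x$RMSEC, x$RPDC, x$R2CV, x$RMSECV, x$RPDCV))
  invisible(x)
}

## Subtraction spectra ---------------------------------------------------------

#' Control-subtracted group mean spectra
#'
#' Two variants, computed separately on differently pretreated spectra:
#' `msc` (multiplicative scatter correction against the subset mean) and
#' `sgol2d` (Savitzky-Golay 2nd-order polynomial, window 21, 2nd
#' derivative). In each variant the control group's mean spectrum is
#' subtracted from every group's mean spectrum, revealing the wavelengths of
#' greatest heat-induced change.
#'
#' @param s spectra_set, already subset to one comparison (one honey type
#'   and one detailed group plus control).
#' @param group_by metadata column to group on ("temperature_C" or
#'   "time_min").
#' @return list with `wavelengths` and matrices `msc`, `sgol2d`
#'   (rows = groups, control row included and identically zero).
#' @export
subtraction_spectra <- function(s, group_by = "temperature_C") {
  g <- as.character(s$meta[[group_by]])
  is_ctrl <- s$meta$temperature_C == "CONTROL"
  if (!any(is_ctrl)) stop("control group missing from the comparison set")
  g[is_ctrl] <- "CONTROL"
  variants <- list(
    msc = msc_fit_apply(s$absorbance)$corrected,
    sgol2d = sgol(s$absorbance, window = 21, poly_order = 2, deriv = 2,
                  step_nm = s$wavelengths[2] - s$wavelengths[1]))
  groups <- unique(g)
  groups <- c("CONTROL", sort(setdiff(groups, "CONTROL")))
  out <- lapply(variants, function(X) {
    means <- t(vapply(groups, function(gr)
      colMeans(X[g == gr, , drop = FALSE]), numeric(ncol(X))))
    sweep(means, 2, means["CONTROL", ])
  })
  c(list(wavelengths = s$wavelengths, groups = groups), out)
}
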