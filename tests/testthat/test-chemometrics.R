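# PCA, PCA-LDA, PLSR, blocked CV and the optimization rules.

test_that("replicate-blocked folds are disjoint, exhaustive and leak-free", {
  s <- sunflower_study()
  meta <- s$meta[s$meta$honey_type == "sunflower", ]
  folds <- loso_folds(meta)
  expect_length(folds, 3L)
  all_val <- sort(unlist(lapply(folds, `[[`, "validation")))
  expect_identical(all_val, seq_len(nrow(meta)))
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0L)
    # each held-out replicate contributes 51 samples x 15 scans / 3 = 255
    expect_equal(length(f$validation), 255L)
    # id audit: no sample of the held-out replicate appears in training
    val_samples <- unique(meta[f$validation,
                               c("temperature_C", "time_min", "replicate")])
    train_samples <- unique(meta[f$train,
                                 c("temperature_C", "time_min", "replicate")])
    expect_equal(nrow(merge(val_samples, train_samples)), 0L)
  }
  expect_error(loso_folds(meta[meta$replicate == "R1", ]), ">= 2 replicate")
})

test_that("PCA matches a brute-force eigendecomposition on a toy matrix", {
  set.seed(7)
  X <- matrix(rnorm(20 * 8), 20, 8)
  m <- fit_pca(X, 8)
  # oracle: dense eigendecomposition of the covariance matrix
  ev_oracle <- sort(eigen(stats::cov(X), symmetric = TRUE)$values,
                    decreasing = TRUE)
  expect_equal(m$eigenvalues, ev_oracle, tolerance = 1e-10)
  expect_equal(m$explained_variance_ratio,
               100 * ev_oracle / sum(ev_oracle), tolerance = 1e-10)
  # loadings orthonormal
  G <- m$loadings %*% t(m$loadings)
  expect_lt(max(abs(G - diag(8))), 1e-8)
  # deterministic sign convention
  for (k in 1:8) expect_gt(m$loadings[k, which.max(abs(m$loadings[k, ]))], 0)
  # scores reproduce the centred data
  expect_lt(max(abs(m$scores %*% m$loadings -
                      sweep(X, 2, colMeans(X)))), 1e-10)
})

test_that("rank-one data puts 100% of variance on PC1", {
  v <- seq_len(12)
  X <- outer(c(1, 2, 5, 9), v)
  m <- fit_pca(X, 2)
  expect_equal(m$explained_variance_ratio[1], 100, tolerance = 1e-9)
})

test_that("PCA-LDA separates planted classes and matches MASS::lda", {
  set.seed(8)
  n <- 60; p <- 30
  dir <- rnorm(p); dir <- dir / sqrt(sum(dir^2))
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p, sd = 1), n, p) +
    outer(ifelse(y == "a", 0, 20), dir)  # 20 sigma separation
  m <- fit_pca_lda(X, y, 2)
  expect_identical(unname(predict(m, X)), y)
  expect_equal(dim(m$wavelength_weights), c(p, 1L))
  # cross-check predictions against MASS::lda on the same PCA scores
  skip_if_not_installed("MASS")
  S <- m$pca$scores
  ml <- MASS::lda(S, grouping = y)
  expect_identical(as.character(stats::predict(ml, S)$class),
                   unname(predict(m, X)))
  # class with < 2 training spectra errors
  expect_error(fit_pca_lda(X[c(1, 31:60), ], y[c(1, 31:60)], 2),
               "class")
})

test_that("label-permuted LDA sits at chance level", {
  set.seed(9)
  accs <- replicate(8, {
    n <- 100; p <- 20
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(rep(letters[1:5], each = n / 5))
    m <- fit_pca_lda(X[1:80, ], y[1:80], 5)
    mean(predict(m, X[81:100, ]) == y[81:100])
  })
  expect_gt(mean(accs), 0.10)
  expect_lt(mean(accs), 0.30)
})

test_that("NIPALS PLS matches a brute-force recursion and the OLS limit", {
  set.seed(10)
  X <- matrix(rnorm(30 * 6), 30, 6)
  beta_true <- c(1, -2, 0.5, 0, 3, -1)
  y <- as.numeric(X %*% beta_true)
  # oracle: textbook NIPALS recursion, written independently
  nipals_oracle <- function(X, y, A) {
    E <- scale(X, scale = FALSE); f <- y - mean(y)
    W <- NULL; P <- NULL; q <- NULL
    for (a in 1:A) {
      w <- drop(t(E) %*% f); w <- w / sqrt(sum(w^2))
      tt <- drop(E %*% w)
      p <- drop(t(E) %*% tt) / sum(tt^2)
      qq <- sum(f * tt) / sum(tt^2)
      E <- E - outer(tt, p); f <- f - qq * tt
      W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qq)
    }
    drop(W %*% solve(t(P) %*% W, q))
  }
  m2 <- fit_pls(X, y, 2)
  expect_equal(m2$coefficients, nipals_oracle(X, y, 2), tolerance = 1e-9)
  # with full rank and no noise, PLS at n_lvs = p reproduces least squares
  m6 <- fit_pls(X, y, 6)
  expect_equal(m6$coefficients, beta_true, tolerance = 1e-6)
  expect_lt(max(abs(predict(m6, X) - y)), 1e-6)
  expect_error(fit_pls(X, rep(1, 30), 2), "constant")
})

test_that("cross_validate computes fold-averaged and pooled-control accuracies", {
  s <- sunflower_study()
  task <- model_task("detailed_temperature", "sunflower", 60L)
  res <- cross_validate(s, task, "sgol@2-21-0_snv", 5)
  expect_length(res$folds, 3L)
  expect_true(res$training_accuracy >= 0 && res$training_accuracy <= 100)
  expect_true(res$validation_accuracy >= 0 &&
                res$validation_accuracy <= 100)
  # pooled validation confusion covers all 45 spectra per level
  expect_true(all(rowSums(res$confusion) == 45L))
  # control accuracy definition: pooled control row of the confusion
  ctrl_row <- res$confusion["CONTROL", ]
  expect_equal(res$control_accuracy,
               100 * ctrl_row[["CONTROL"]] / sum(ctrl_row))
})

test_that("PC-number choice is lexicographic in (validation, gap, n_pcs)", {
  fake <- function(n_pcs, val, gap)
    structure(list(n_pcs = n_pcs, validation_accuracy = val,
                   training_accuracy = val + gap), class = "cv_result")
  pick <- aquaheat:::select_best_pcs(
    list(fake(2L, 90, 2), fake(3L, 95, 8), fake(4L, 95, 3)))
  expect_equal(pick$n_pcs, 4L)
  expect_equal(aquaheat:::select_best_pcs(list(fake(7L, 80, 1)))$n_pcs, 7L)
  allsame <- list(fake(5L, 90, 2), fake(3L, 90, 2), fake(9L, 90, 2))
  expect_equal(aquaheat:::select_best_pcs(allsame)$n_pcs, 3L)
})

test_that("pretreatment optimization reports every spec and prefers scatter correction", {
  # planted scatter: heavy multiplicative noise that snv/msc remove
  p <- default_synth_params(2)
  p$scatter_sd <- 0.25
  d <- generate_design()
  d <- d[d$honey_type == "sunflower" & d$time_min %in% c(0L, 240L), ]
  s <- cut_range(generate_spectra(d, p, n_fills = 2L, n_scans = 2L),
                 1300, 1600)
  task <- model_task("detailed_temperature", "sunflower", 240L)
  grid <- lapply(c("raw", "snv", "sgol@2-21-0_snv"), parse_pretreatment)
  opt <- optimize_pretreatment(s, task, grid, "validation_accuracy",
                               pc_candidates = 2:6)
  expect_equal(nrow(opt$report), 3L)
  raw_acc <- opt$report$validation_accuracy[opt$report$spec == "raw"]
  expect_gt(opt$best$validation_accuracy, raw_acc)
  expect_true(opt$best_spec != "raw")
})

test_that("PLSR metrics: exact fit, RPD identities, chemometric orderings", {
  # y exactly linear in one spectral band, no noise -> R2CV = 1, RMSECV ~ 0
  wl <- seq(1300, 1600, by = 3)
  meta <- data.frame(honey_type = "sunflower",
                     temperature_C = rep(c("40", "60", "100"), each = 15),
                     time_min = 60L,
                     replicate = rep(rep(c("R1", "R2", "R3"), each = 5), 3),
                     fill = 1L, scan = rep(1:5, 9))
  y_num <- as.numeric(meta$temperature_C)
  band <- exp(-0.5 * ((wl - 1450) / 30)^2)
  X <- 0.5 + outer(y_num, band) * 0.001
  toy <- spectra_set(wl, X, meta)
  pr <- cv_plsr(toy, model_task("general_temperature", "sunflower"),
                "raw", 3)
  expect_equal(pr$R2CV, 1, tolerance = 1e-6)
  expect_lt(pr$RMSECV, 1e-4)
  # RPD identity on both splits, tol 1e-9
  sd_pop <- sqrt(mean((pr$y - mean(pr$y))^2))
  expect_equal(pr$RPDC, sd_pop / pr$RMSEC, tolerance = 1e-9)
  expect_equal(pr$RPDCV, sd_pop / pr$RMSECV, tolerance = 1e-9)
})

test_that("noiseless dose-separated classes are perfectly classified", {
  p <- default_synth_params(1)
  p$scatter_sd <- 0; p$offset_sd <- 0; p$scan_noise_sd <- 0
  p$replicate_sd <- 0
  d <- generate_design()
  d <- d[d$honey_type == "sunflower" & (d$time_min %in% c(0L, 240L)), ]
  s <- cut_range(generate_spectra(d, p, n_fills = 2L, n_scans = 2L),
                 1300, 1600)
  task <- model_task("detailed_temperature", "sunflower", 240L)
  res <- cross_validate(s, task, "raw", 4)
  expect_equal(res$training_accuracy, 100)
  expect_equal(res$validation_accuracy, 100)
  expect_equal(res$control_accuracy, 100)
})

test_that("subtraction spectra localize the perturbed band and null cases", {
  p <- default_synth_params(1)
  p$scatter_sd <- 0.01
  d <- generate_design()
  d <- d[d$honey_type == "sunflower" & d$time_min %in% c(0L, 240L), ]
  s <- cut_range(generate_spectra(d, p), 1300, 1600)
  diffs <- subtraction_spectra(s, "temperature_C")
  # the control row is identically zero
  expect_true(all(abs(diffs$msc["CONTROL", ]) == 0))
  expect_true(all(abs(diffs$sgol2d["CONTROL", ]) == 0))
  # the strongest negative MSC-variant change for 100C sits inside the
  # strongly hydrogen-bonded water region (the generator's perturbed
  # 1490/1512 nm band complex), the strongest positive one at free water
  d100 <- diffs$msc["100", ]
  w_min <- diffs$wavelengths[which.min(d100)]
  expect_true(w_min >= 1482 && w_min <= 1520)
  w_max <- diffs$wavelengths[which.max(d100)]
  expect_true(w_max >= 1398 && w_max <= 1418)
  # missing control errors
  s2 <- subset_spectra(s, s$meta$temperature_C != "CONTROL")
  expect_error(subtraction_spectra(s2, "temperature_C"), "control")
})
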