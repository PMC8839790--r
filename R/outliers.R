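## PCA-based outlier screening (SIMCA-style Hotelling T2 + Q residuals)

#' Detect spectral outliers with Hotelling T2 and Q residuals
#'
#' Fits a mean-centred PCA with `n_pcs` components and screens each spectrum
#' by two complementary statistics: Hotelling T2 on the retained scores
#' (leverage inside the model plane, F-distribution limit at confidence
#' `alpha`) and Q, the squared reconstruction residual (distance from the
#' model plane, Box chi-square approximation limit). A spectrum is kept iff
#' both statistics are at or below their limits. Deterministic for fixed
#' input.
#'
#' @param s spectra_set.
#' @param n_pcs number of principal components; if `NULL`, the smallest
#'   number reaching 95 percent explained variance, capped at 10.
#' @param alpha confidence level for both limits (default 0.999).
#' @return list of class `outlier_report` with `keep_mask`, `t2`, `q`,
#'   `limits = c(t2_limit, q_limit)` and `n_pcs`.
#' @export
detect_outliers <- function(s, n_pcs = NULL, alpha = 0.999) {
  X <- s$absorbance
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  # eigenvalues of the covariance matrix
  ev <- sv$d^2 / (n - 1)
  if (is.null(n_pcs)) {
    cum <- cumsum(ev) / sum(ev)
    n_pcs <- min(which(cum >= 0.95), 10L)
  }
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1) stop("n_pcs must be >= 1")
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of spectra")
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  t2 <- rowSums(sweep(scores^2, 2, ev[seq_len(n_pcs)], "/"))
  t2_limit <- n_pcs * (n - 1) / (n - n_pcs) *
    stats::qf(alpha, n_pcs, n - n_pcs)
  # Q = squared residual off the n_pcs-dimensional model plane
  recon <- scores %*% t(sv$v[, seq_len(n_pcs), drop = FALSE])
  q <- rowSums((Xc - recon)^2)
  # Box approximation: Q ~ g * chi2(h) with g = theta2/theta1, h = theta1^2/theta2
  resid_ev <- ev[-seq_len(n_pcs)]
  resid_ev <- resid_ev[resid_ev > 1e-30]
  if (length(resid_ev) == 0) {
    q_limit <- Inf
  } else {
    th1 <- sum(resid_ev)
    th2 <- sum(resid_ev^2)
    g <- th2 / th1
    h <- th1^2 / th2
    q_limit <- g * stats::qchisq(alpha, h)
  }
  keep <- t2 <= t2_limit & q <= q_limit
  structure(list(keep_mask = keep, t2 = t2, q = q,
                 limits = c(t2_limit = t2_limit, q_limit = q_limit),
                 n_pcs = n_pcs),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d/%d spectra kept (n_pcs = %d)\n",
              sum(x$keep_mask), length(x$keep_mask), x$n_pcs))
  invisible(x)
}

#' Screen outliers per honey type and drop them
#'
#' Applies [detect_outliers()] separately within each honey type on the raw
#' full-range spectra (the screen is run before range cutting) and returns
#' the cleaned spectra_set plus the per-type reports.
#'
#' @param s spectra_set.
#' @param alpha confidence level (default 0.999).
#' @return list with `spectra` (cleaned set) and `reports` (per type).
#' @export
screen_outliers <- function(s, alpha = 0.999) {
  types <- unique(s$meta$honey_type)
  keep <- rep(TRUE, nrow(s$absorbance))
  reports <- list()
  for (ty in types) {
    idx <- which(s$meta$honey_type == ty)
    rep_ty <- detect_outliers(subset_spectra(s, idx), alpha = alpha)
    keep[idx] <- rep_ty$keep_mask
    reports[[ty]] <- rep_ty
  }
  list(spectra = subset_spectra(s, keep), reports = reports)
}

#' Write an outlier report as CSV
#'
#' One row per spectrum: metadata ids, T2, Q and the keep flag.
#'
#' @param report outlier_report.
#' @param meta metadata data.frame aligned with the report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, meta, path) {
  out <- cbind(meta,
               t2 = report$t2, q = report$q,
               keep = report$keep_mask)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
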