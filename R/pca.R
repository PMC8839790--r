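## Principal component analysis with a deterministic sign convention.

#' Fit a mean-centred PCA
#'
#' Singular value decomposition of the mean-centred spectra matrix. Sign
#' convention: within each loading vector the element of largest absolute
#' value is positive, making the decomposition deterministic.
#'
#' @param X spectra matrix (rows = spectra).
#' @param n_pcs number of components, `<= min(n - 1, p)`.
#' @return list of class `pca_model`: `mean`, `loadings`
#'   `[n_pcs x p]`, `scores` `[n x n_pcs]`, `explained_variance_ratio`
#'   (percent per PC), `eigenvalues`.
#' @export
fit_pca <- function(X, n_pcs) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n_pcs > min(n - 1, p))
    stop("n_pcs must be <= min(n_spectra - 1, n_wavelengths)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = n_pcs, nv = n_pcs)
  ev_all <- sv$d^2 / (n - 1)
  loadings <- t(sv$v)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  # deterministic sign: largest-|loading| element positive per component
  for (k in seq_len(n_pcs)) {
    j <- which.max(abs(loadings[k, ]))
    if (loadings[k, j] < 0) {
      loadings[k, ] <- -loadings[k, ]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(mean = mu, loadings = loadings, scores = scores,
                 explained_variance_ratio =
                   100 * ev_all[seq_len(n_pcs)] / sum(ev_all),
                 eigenvalues = ev_all[seq_len(n_pcs)]),
            class = "pca_model")
}

#' Project new spectra onto a fitted PCA
#'
#' @param model pca_model.
#' @param X new spectra matrix on the same grid.
#' @return score matrix `[n x n_pcs]`.
#' @export
project_pca <- function(model, X) {
  sweep(as.matrix(X), 2, model$mean) %*% t(model$loadings)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d PCs; explained variance: %s%%\n",
              nrow(x$loadings),
              paste(sprintf("%.2f", x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}
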