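## Hybrid PCA-LDA: linear discriminant analysis on principal component
## scores, with back-projection of the discriminant directions to
## wavelength space.

#' Fit a PCA-LDA classification model
#'
#' PCA (mean-centred, `n_pcs` components) followed by linear discriminant
#' analysis on the scores with a shared within-class covariance matrix,
#' ridge-regularized by `1e-8 * trace` to guard against rank-deficient small
#' folds. Prediction is by maximum linear discriminant score with
#' proportional priors. `wavelength_weights` back-projects the canonical
#' discriminant directions through the PCA loadings, one column per
#' discriminant axis.
#'
#' @param X training spectra matrix.
#' @param y class labels (character or factor).
#' @param n_pcs number of principal components to retain.
#' @return list of class `pcalda_model`.
#' @export
fit_pca_lda <- function(X, y, n_pcs) {
  y <- as.character(y)
  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2))
    stop("every class needs >= 2 training spectra; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  if (n_pcs >= nrow(X)) stop("n_pcs must be < n_train")
  pca <- fit_pca(X, n_pcs)
  S <- pca$scores
  k <- length(classes)
  p <- ncol(S)
  means <- t(vapply(classes, function(cl)
    colMeans(S[y == cl, , drop = FALSE]), numeric(p)))
  W <- matrix(0, p, p)
  for (cl in classes) {
    Sc <- sweep(S[y == cl, , drop = FALSE], 2, means[cl == classes, ])
    W <- W + crossprod(Sc)
  }
  W <- W / (nrow(S) - k)
  W <- W + diag(1e-8 * sum(diag(W)) / p, p)
  Winv <- solve(W)
  priors <- as.numeric(counts) / length(y)
  # linear discriminant score: x' Winv mu_k - 0.5 mu_k' Winv mu_k + log pi_k
  disc_w <- Winv %*% t(means)                       # [p x k]
  disc_b <- -0.5 * colSums(t(means) * disc_w) + log(priors)
  # canonical axes for weights/plots: eigenvectors of Winv %*% B
  gm <- colMeans(S)
  B <- matrix(0, p, p)
  for (i in seq_len(k)) {
    d <- means[i, ] - gm
    B <- B + counts[i] * tcrossprod(d)
  }
  eg <- eigen(Winv %*% B)
  n_axes <- min(k - 1, p)
  axes <- Re(eg$vectors[, seq_len(n_axes), drop = FALSE])
  wavelength_weights <- t(pca$loadings) %*% axes    # [n_wavelengths x axes]
  structure(list(pca = pca, n_pcs = n_pcs, classes = classes,
                 priors = priors, class_means = means,
                 disc_w = disc_w, disc_b = disc_b,
                 axes = axes,
                 wavelength_weights = wavelength_weights),
            class = "pcalda_model")
}

#' Predict classes with a PCA-LDA model
#'
#' @param object pcalda_model.
#' @param newdata spectra matrix on the training grid.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.pcalda_model <- function(object, newdata, ...) {
  S <- project_pca(object$pca, newdata)
  scores <- S %*% object$disc_w
  scores <- sweep(scores, 2, object$disc_b, "+")
  object$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.pcalda_model <- function(x, ...) {
  cat(sprintf("<pcalda_model> %d PCs, classes: %s\n", x$n_pcs,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
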