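## Partial least squares regression (NIPALS, univariate response).

#' Fit a PLS1 regression by the NIPALS recursion
#'
#' Mean-centres `X` and `y`, then extracts `n_lvs` latent variables:
#' weights `w = X'y / ||X'y||`, scores `t = Xw`, loadings `p = X't/(t't)`,
#' `q = y't/(t't)`, deflating `X` after each component. The regression
#' vector in original (centred) X-space is `W (P'W)^-1 q`.
#'
#' @param X predictor matrix (rows = spectra).
#' @param y numeric response.
#' @param n_lvs number of latent variables.
#' @return list of class `pls_model`: `coefficients` (per wavelength),
#'   `intercept`, `x_mean`, `y_mean`, `n_lvs`, plus the `W`, `P`, `q`
#'   matrices of the recursion.
#' @export
fit_pls <- function(X, y, n_lvs) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (stats::sd(y) == 0) stop("degenerate (constant) regression target")
  n_lvs <- min(n_lvs, n - 1, p)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  W <- matrix(0, p, n_lvs)
  P <- matrix(0, p, n_lvs)
  q <- numeric(n_lvs)
  for (a in seq_len(n_lvs)) {
    w <- as.numeric(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { n_lvs <- a - 1L; break }
    w <- w / nw
    tt <- as.numeric(E %*% w)
    t2 <- sum(tt^2)
    pp <- as.numeric(crossprod(E, tt)) / t2
    qq <- sum(f * tt) / t2
    E <- E - tcrossprod(tt, pp)
    f <- f - qq * tt
    W[, a] <- w; P[, a] <- pp; q[a] <- qq
  }
  if (n_lvs == 0) stop("no usable latent variable (X'y is zero)")
  W <- W[, seq_len(n_lvs), drop = FALSE]
  P <- P[, seq_len(n_lvs), drop = FALSE]
  q <- q[seq_len(n_lvs)]
  beta <- W %*% solve(crossprod(P, W), q)
  structure(list(coefficients = as.numeric(beta),
                 intercept = y_mean - sum(x_mean * beta),
                 x_mean = x_mean, y_mean = y_mean,
                 n_lvs = n_lvs, W = W, P = P, q = q),
            class = "pls_model")
}

#' Predict with a PLS model
#'
#' @param object pls_model.
#' @param newdata spectra matrix.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$coefficients + object$intercept)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables\n", x$n_lvs))
  invisible(x)
}
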