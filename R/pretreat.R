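## Spectral pretreatment operators, the codec for pretreatment strings and
## the 41-combination optimization grid.
##
## Codec grammar: steps joined by "_"; Savitzky-Golay rendered
## "sgol@<poly>-<window>-<deriv>", scatter/baseline steps "snv", "msc",
## "deTr". Pipeline order is the string's left-to-right order.

#' Savitzky-Golay smoothing / differentiation of a spectra matrix
#'
#' Per-row local polynomial filtering. Derivatives are scaled by the grid
#' step (units AU/nm^deriv); edges are handled by the filter's own
#' polynomial fits within the first/last half-window.
#'
#' @param X numeric matrix, rows = spectra.
#' @param window odd filter window (> poly_order).
#' @param poly_order polynomial order (default 2).
#' @param deriv derivative order, `<= poly_order`.
#' @param step_nm wavelength grid spacing in nm (default 3).
#' @return filtered matrix, same shape.
#' @export
sgol <- function(X, window, poly_order = 2, deriv = 0, step_nm = 3) {
  X <- as.matrix(X)
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= poly_order) stop("window must exceed poly_order")
  if (deriv > poly_order) stop("deriv must be <= poly_order")
  if (window >= ncol(X)) stop("window must be smaller than n_wavelengths")
  # the filter is linear, so apply its p x p matrix once (cached per shape)
  S <- sgol_filter_matrix(ncol(X), window, poly_order, deriv, step_nm)
  X %*% S
}

# cache of transposed Savitzky-Golay filter matrices, keyed by parameters
.sgol_cache <- new.env(parent = emptyenv())

sgol_filter_matrix <- function(p, window, poly_order, deriv, step_nm) {
  key <- paste(p, window, poly_order, deriv, step_nm, sep = "|")
  S <- .sgol_cache[[key]]
  if (is.null(S)) {
    cols <- vapply(seq_len(p), function(j) {
      e <- numeric(p); e[j] <- 1
      signal::sgolayfilt(e, p = poly_order, n = window, m = deriv,
                         ts = step_nm)
    }, numeric(p))
    S <- t(cols)  # output = X %*% S for row-spectra X
    .sgol_cache[[key]] <- S
  }
  S
}

#' Standard normal variate
#'
#' Centres each spectrum to mean 0 and scales it to unit population SD.
#'
#' @param X numeric matrix, rows = spectra.
#' @return transformed matrix.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  sd_pop <- sqrt(rowMeans(Xc^2))
  bad <- sd_pop <= 1e-12 * pmax(1, abs(mu))
  if (any(bad))
    stop("zero-variance spectrum row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  Xc / sd_pop
}

#' Multiplicative scatter correction
#'
#' Fits each spectrum `y` against a reference spectrum by least squares,
#' `y ~ m * ref + b`, and returns `(y - b) / m`. The reference is the column
#' mean of the training matrix, so held-out spectra are corrected against
#' the training reference (no leakage).
#'
#' @param X_train matrix used to fit the reference (column mean).
#' @param X_apply matrix to correct (default `X_train`).
#' @param reference optional explicit reference spectrum.
#' @return list with `corrected` matrix and `reference` spectrum.
#' @export
msc_fit_apply <- function(X_train, X_apply = X_train, reference = NULL) {
  X_train <- as.matrix(X_train)
  X_apply <- as.matrix(X_apply)
  if (is.null(reference)) reference <- colMeans(X_train)
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom <= 0) stop("degenerate (constant) MSC reference")
  ybar <- rowMeans(X_apply)
  m <- (as.numeric(X_apply %*% rc) - ybar * sum(rc)) / denom
  if (any(abs(m) < 1e-12))
    stop("MSC slope ~ 0 for spectrum row(s): ",
         paste(utils::head(which(abs(m) < 1e-12), 5), collapse = ", "))
  b <- ybar - m * mean(reference)
  corrected <- (X_apply - b) / m
  list(corrected = corrected, reference = reference)
}

#' Polynomial detrending
#'
#' Subtracts from each spectrum its least-squares polynomial (default
#' quadratic) in wavelength. Idempotent (a projection).
#'
#' @param X numeric matrix, rows = spectra.
#' @param wavelengths wavelength grid (nm); defaults to column index.
#' @param poly_order polynomial order (default 2).
#' @return detrended matrix.
#' @export
detrend <- function(X, wavelengths = NULL, poly_order = 2) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p <= poly_order) stop("need more wavelengths than poly_order")
  if (is.null(wavelengths)) wavelengths <- seq_len(p)
  basis <- cbind(1, stats::poly(wavelengths, degree = poly_order,
                                raw = FALSE))
  Q <- qr.Q(qr(basis))
  # project each row off the span of {1, lambda, ..., lambda^order}
  X - (X %*% Q) %*% t(Q)
}

## Codec ----------------------------------------------------------------------

#' Parse a pretreatment codec string
#'
#' @param code e.g. `"sgol@2-21-0_snv"`, `"raw"`, `"deTr_msc"`.
#' @return object of class `pretreatment_spec`: list of steps, each
#'   `list(kind, ...)`.
#' @export
parse_pretreatment <- function(code) {
  if (identical(code, "raw"))
    return(structure(list(steps = list(), code = "raw"),
                     class = "pretreatment_spec"))
  toks <- strsplit(code, "_", fixed = TRUE)[[1]]
  steps <- lapply(toks, function(tok) {
    if (grepl("^sgol@", tok)) {
      nums <- as.integer(strsplit(sub("^sgol@", "", tok), "-")[[1]])
      if (length(nums) != 3 || any(is.na(nums)))
        stop("malformed sgol token: ", tok)
      list(kind = "sgol", poly_order = nums[1], window = nums[2],
           deriv = nums[3])
    } else if (tok == "snv") list(kind = "snv")
    else if (tok == "msc") list(kind = "msc")
    else if (tok == "deTr") list(kind = "detrend", poly_order = 2)
    else stop("unknown pretreatment token: ", tok)
  })
  n_scatter <- sum(vapply(steps, function(s) s$kind %in% c("snv", "msc"),
                          logical(1)))
  if (n_scatter > 1)
    stop("at most one scatter-correction step (snv or msc) per spec")
  structure(list(steps = steps, code = code), class = "pretreatment_spec")
}

#' Format a pretreatment spec back to its codec string
#'
#' Inverse of [parse_pretreatment()]: `format(parse(code)) == code`.
#'
#' @param x pretreatment_spec.
#' @param ... unused.
#' @return canonical codec string.
#' @export
format.pretreatment_spec <- function(x, ...) {
  if (length(x$steps) == 0) return("raw")
  paste(vapply(x$steps, function(s) {
    switch(s$kind,
           sgol = sprintf("sgol@%d-%d-%d", s$poly_order, s$window, s$deriv),
           snv = "snv",
           msc = "msc",
           detrend = "deTr")
  }, character(1)), collapse = "_")
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  cat("<pretreatment_spec>", format(x), "\n")
  invisible(x)
}

#' Enumerate the 41-combination pretreatment grid
#'
#' The optimization grid used throughout: the raw spectra; the four
#' smoothing-free scatter/baseline treatments snv, msc, deTr, deTr_msc; and
#' Savitzky-Golay smoothing (2nd-order polynomial, window 13/17/21)
#' followed by one of {nothing, snv, msc, deTr, deTr_snv, deTr_msc} or by a
#' Savitzky-Golay derivative pass (window 13/17/21, 1st or 2nd derivative):
#' 1 + 4 + 3 x (6 + 6) = 41 specs. Deterministic and duplicate-free; every
#' published model's pretreatment string is a member.
#'
#' @return list of 41 `pretreatment_spec` objects.
#' @export
enumerate_grid <- function() {
  codes <- c("raw", "snv", "msc", "deTr", "deTr_msc")
  for (w in c(13, 17, 21)) {
    base <- sprintf("sgol@2-%d-0", w)
    codes <- c(codes, base,
               paste0(base, "_", c("snv", "msc", "deTr",
                                   "deTr_snv", "deTr_msc")))
    for (w2 in c(13, 17, 21))
      for (d in 1:2)
        codes <- c(codes, sprintf("%s_sgol@2-%d-%d", base, w2, d))
  }
  stopifnot(!anyDuplicated(codes), length(codes) == 41L)
  lapply(codes, parse_pretreatment)
}

#' Apply a pretreatment spec, fitting any state on the training set only
#'
#' Steps are applied in the spec's left-to-right order to the training and
#' application matrices in lockstep. The MSC reference is the column mean of
#' the (partially transformed) training matrix at that step, reused for the
#' application matrix, so cross-validated pretreatment is leakage-free.
#'
#' @param spec pretreatment_spec or codec string.
#' @param X_train training spectra matrix.
#' @param X_apply matrix to transform with training state (default
#'   `X_train`).
#' @param wavelengths wavelength grid (nm) for detrending and SG scaling.
#' @return list `train`, `apply` (transformed matrices), `spec`,
#'   `msc_reference` (or NULL).
#' @export
apply_pretreatment <- function(spec, X_train, X_apply = X_train,
                               wavelengths = NULL) {
  if (is.character(spec)) spec <- parse_pretreatment(spec)
  step_nm <- if (!is.null(wavelengths) && length(wavelengths) > 1)
    wavelengths[2] - wavelengths[1] else 3
  Xt <- as.matrix(X_train)
  Xa <- as.matrix(X_apply)
  msc_ref <- NULL
  for (i in seq_along(spec$steps)) {
    s <- spec$steps[[i]]
    res <- tryCatch(switch(
      s$kind,
      sgol = {
        Xt <- sgol(Xt, s$window, s$poly_order, s$deriv, step_nm)
        Xa <- sgol(Xa, s$window, s$poly_order, s$deriv, step_nm)
        NULL
      },
      snv = {
        Xt <- snv(Xt); Xa <- snv(Xa); NULL
      },
      msc = {
        fit <- msc_fit_apply(Xt)
        msc_ref <- fit$reference
        Xt <- fit$corrected
        Xa <- msc_fit_apply(Xt, Xa, reference = msc_ref)$corrected
        NULL
      },
      detrend = {
        Xt <- detrend(Xt, wavelengths, s$poly_order)
        Xa <- detrend(Xa, wavelengths, s$poly_order)
        NULL
      }), error = function(e)
        stop(sprintf("pretreatment step %d (%s) failed: %s",
                     i, s$kind, conditionMessage(e)), call. = FALSE))
  }
  list(train = Xt, apply = Xa, spec = spec, msc_reference = msc_ref)
}
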