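## Water matrix coordinates (WAMACs), wavelength voting, classic aquagrams
## and radar rendering.

#' The 12 water matrix coordinates of the 1300-1600 nm first overtone
#'
#' Characteristic wavelength ranges, each attributed to a water molecular
#' species, used to bucket the wavelengths that models and difference
#' spectra flag as most affected. C12's upper bound extends to 1520 nm so
#' the strongly hydrogen-bonded anchors at 1511-1513 nm fall inside it.
#'
#' @return data.frame `index, lo, hi, label`.
#' @export
default_wamacs <- function() {
  data.frame(
    index = 1:12,
    lo = c(1336, 1360, 1370, 1380, 1398, 1421, 1432, 1448, 1458, 1472,
           1482, 1506),
    hi = c(1348, 1366, 1376, 1388, 1418, 1430, 1444, 1454, 1468, 1482,
           1495, 1520),
    label = c("weakly H-bonded water / free OH (nu3)",
              "water shells / OH-(H2O)1,2,4",
              "trapped water (nu1 + nu3)",
              "water confined / hydration shell",
              "free water / free OH (S0)",
              "water hydration / H-OH bend",
              "water molecules with one hydrogen bond (S1)",
              "water solvation shell OH-(H2O)4,5",
              "water molecules with two hydrogen bonds (S2)",
              "water molecules with three hydrogen bonds (S3)",
              "water molecules with four hydrogen bonds (S4)",
              "strongly hydrogen-bonded water (nu1, nu2)"),
    stringsAsFactors = FALSE)
}

#' WAMAC index of wavelengths
#'
#' @param wavelength numeric nm.
#' @param wamacs WAMAC registry (default [default_wamacs()]).
#' @return integer WAMAC index (NA if outside every range).
#' @export
wamac_of <- function(wavelength, wamacs = default_wamacs()) {
  vapply(wavelength, function(w) {
    hit <- which(w >= wamacs$lo & w <= wamacs$hi)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

#' Collect wavelength-importance votes from models and difference spectra
#'
#' For each source, the `top_k` wavelengths by absolute weight vote once.
#' Sources: `pca_model` (PC1 loading), `pcalda_model` (first discriminant
#' axis in wavelength space), `plsr_report` (regression vector), and
#' difference spectra (numeric vectors; votes go to the local extrema with
#' the largest absolute values). All-zero sources contribute no votes.
#'
#' @param sources named list of models / numeric difference spectra.
#' @param wavelengths the shared wavelength grid.
#' @param top_k votes per source (default 20).
#' @return data.frame `wavelength, source, magnitude`.
#' @export
collect_votes <- function(sources, wavelengths, top_k = 20) {
  votes <- list()
  for (nm in names(sources)) {
    src <- sources[[nm]]
    if (inherits(src, "pca_model")) {
      w <- abs(src$loadings[1, ])
      if (length(w) != length(wavelengths))
        stop("grid mismatch for source ", nm)
    } else if (inherits(src, "pcalda_model")) {
      w <- abs(src$wavelength_weights[, 1])
      if (length(w) != length(wavelengths))
        stop("grid mismatch for source ", nm)
    } else if (inherits(src, "plsr_report")) {
      w <- abs(src$regression_vector)
      if (length(w) != length(wavelengths))
        stop("grid mismatch for source ", nm)
    } else if (is.numeric(src)) {
      if (length(src) != length(wavelengths))
        stop("grid mismatch for source ", nm)
      # difference spectrum: only local extrema of |value| are candidates
      a <- abs(src)
      n <- length(a)
      is_ext <- rep(FALSE, n)
      interior <- 2:(n - 1)
      is_ext[interior] <- a[interior] >= a[interior - 1] &
        a[interior] >= a[interior + 1]
      is_ext[1] <- a[1] >= a[2]
      is_ext[n] <- a[n] >= a[n - 1]
      w <- ifelse(is_ext, a, 0)
    } else stop("unsupported vote source: ", nm)
    pos <- which(w > 0)
    if (length(pos) == 0) next
    ord <- pos[order(-w[pos])]
    take <- utils::head(ord, top_k)
    votes[[nm]] <- data.frame(wavelength = wavelengths[take],
                              source = nm, magnitude = w[take],
                              stringsAsFactors = FALSE)
  }
  if (length(votes) == 0)
    return(data.frame(wavelength = numeric(0), source = character(0),
                      magnitude = numeric(0)))
  do.call(rbind, c(votes, list(make.row.names = FALSE)))
}

#' Select one display wavelength per WAMAC from pooled votes
#'
#' Votes outside every WAMAC are discarded. Within each populated WAMAC the
#' modal (most frequently voted) wavelength wins; ties break by the highest
#' summed magnitude, then by proximity to the range midpoint. WAMACs with no
#' votes are omitted.
#'
#' @param votes data.frame from [collect_votes()].
#' @param wamacs WAMAC registry.
#' @return data.frame `wamac, wavelength, label` of class `aquagram_spec`.
#' @export
select_coordinates <- function(votes, wamacs = default_wamacs()) {
  votes$wamac <- wamac_of(votes$wavelength, wamacs)
  votes <- votes[!is.na(votes$wamac), , drop = FALSE]
  if (nrow(votes) == 0) stop("no votes fall inside any WAMAC")
  picks <- lapply(sort(unique(votes$wamac)), function(ci) {
    v <- votes[votes$wamac == ci, ]
    tab <- stats::aggregate(magnitude ~ wavelength, v,
                            FUN = function(x) c(n = length(x), mag = sum(x)))
    n_votes <- tab$magnitude[, "n"]
    mag <- tab$magnitude[, "mag"]
    mid <- (wamacs$lo[ci] + wamacs$hi[ci]) / 2
    ord <- order(-n_votes, -mag, abs(tab$wavelength - mid))
    data.frame(wamac = ci, wavelength = tab$wavelength[ord[1]],
               label = wamacs$label[ci], stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, picks), class = c("aquagram_spec", "data.frame"))
}

#' Compute a classic aquagram
#'
#' Display pretreatment first: Savitzky-Golay smoothing (2nd-order
#' polynomial, window 21, no derivative) followed by MSC against the
#' comparison set's mean spectrum. At each selected coordinate wavelength
#' the absorbance is standardized over all spectra of the comparison set
#' (`z = (A - mu)/sigma`, population sigma) and averaged within groups. The
#' size-weighted mean of the group values is therefore 0 at every
#' coordinate, and the result is invariant to duplicating every spectrum.
#'
#' @param s spectra_set restricted to the comparison (e.g. one honey type,
#'   one time group plus control).
#' @param spec aquagram_spec from [select_coordinates()].
#' @param grouping character vector of group labels, one per spectrum, or a
#'   metadata column name.
#' @param pretreat apply the display pretreatment (default TRUE).
#' @return list of class `aquagram`: `groups`, `coordinates`, `values`
#'   matrix `[n_groups x n_coords]`, `group_n`.
#' @export
classic_aquagram <- function(s, spec, grouping, pretreat = TRUE) {
  g <- if (length(grouping) == 1 && grouping %in% names(s$meta))
    as.character(s$meta[[grouping]]) else as.character(grouping)
  if (length(g) != nrow(s$absorbance))
    stop("grouping length does not match spectra")
  if (length(unique(g)) < 2) stop("need >= 2 groups for an aquagram")
  X <- s$absorbance
  if (pretreat) {
    X <- sgol(X, window = 21, poly_order = 2, deriv = 0,
              step_nm = s$wavelengths[2] - s$wavelengths[1])
    X <- msc_fit_apply(X)$corrected
  }
  cols <- vapply(spec$wavelength, function(wv) {
    j <- which(abs(s$wavelengths - wv) < 1e-9)
    if (length(j) != 1) stop("coordinate ", wv, " nm is not on the grid")
    j
  }, integer(1))
  A <- X[, cols, drop = FALSE]
  mu <- colMeans(A)
  sdev <- sqrt(colMeans(sweep(A, 2, mu)^2))
  if (any(sdev <= 0))
    stop("degenerate coordinate (zero variance) at ",
         paste(spec$wavelength[sdev <= 0], collapse = ", "), " nm")
  Z <- sweep(sweep(A, 2, mu), 2, sdev, "/")
  groups <- unique(g)
  values <- t(vapply(groups, function(gr)
    colMeans(Z[g == gr, , drop = FALSE]), numeric(ncol(Z))))
  colnames(values) <- format(spec$wavelength, trim = TRUE)
  structure(list(groups = groups, coordinates = spec,
                 values = values,
                 group_n = as.integer(table(factor(g, groups)))),
            class = "aquagram")
}

#' @export
print.aquagram <- function(x, ...) {
  cat(sprintf("<aquagram> %d groups x %d coordinates (%s nm)\n",
              length(x$groups), nrow(x$coordinates),
              paste(x$coordinates$wavelength, collapse = ", ")))
  invisible(x)
}

#' Render an aquagram as a radar chart
#'
#' One closed trace per group, coordinates ordered by wavelength, legend =
#' group labels. Written as PNG or SVG depending on the file extension.
#' Deterministic for fixed input.
#'
#' @param a aquagram.
#' @param path output file (.png or .svg).
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
render_radar <- function(a, path, main = "Aquagram") {
  if (nrow(a$coordinates) < 3)
    stop("need >= 3 coordinates to draw a radar polygon")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") grDevices::png(path, width = 800, height = 800)
  else if (ext == "svg") grDevices::svg(path, width = 8, height = 8)
  else stop("unsupported image extension: ", ext)
  on.exit(grDevices::dev.off())
  ord <- order(a$coordinates$wavelength)
  vals <- a$values[, ord, drop = FALSE]
  labs <- paste0(a$coordinates$wavelength[ord], " nm")
  k <- ncol(vals)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k
  rng <- range(vals)
  pad <- 0.1 * diff(rng)
  r0 <- rng[1] - pad
  rscale <- function(v) (v - r0) / (rng[2] + pad - r0)
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NA, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), axes = FALSE,
                 xlab = "", ylab = "", asp = 1, main = main)
  for (rr in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(rr * cos(ang), rr * sin(ang), border = "grey80")
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey80")
  graphics::text(1.2 * cos(ang), 1.2 * sin(ang), labs, cex = 0.8)
  cols <- grDevices::hcl.colors(max(3, nrow(vals)), "Dark 3")
  for (i in seq_len(nrow(vals))) {
    r <- rscale(vals[i, ])
    graphics::polygon(r * cos(ang), r * sin(ang), border = cols[i],
                      lwd = 2)
  }
  graphics::legend("topleft", legend = a$groups, col = cols[seq_along(a$groups)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(path)
}
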