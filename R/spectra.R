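#' @keywords internal
"_PACKAGE"

## Experimental design vocabulary -------------------------------------------

#' Honey types, temperature levels and holding times of the heat-treatment
#' design
#'
#' The study design crosses three unifloral honey types with four treatment
#' temperatures and four holding times, plus one untreated control per type:
#' 17 treatment levels per type. `WATER_REF` marks periodic reference water
#' scans, accepted by the reader but excluded from modelling.
#'
#' @name design-vocabulary
#' @keywords internal
NULL

honey_types <- function() c("sunflower", "bastard_indigo", "acacia")
temperature_levels <- function() c("CONTROL", "40", "60", "80", "100")
time_levels <- function() c(0L, 60L, 120L, 180L, 240L)
replicate_ids <- function() c("R1", "R2", "R3")

meta_columns <- c("honey_type", "temperature_C", "time_min",
                  "replicate", "fill", "scan")

#' Is a (temperature, time) pair a legal design cell?
#'
#' The control is the single cell with `temperature_C = "CONTROL"` and
#' `time_min = 0`; every other legal cell crosses a treatment temperature
#' (40/60/80/100 degrees C) with a non-zero holding time (60/120/180/240 min).
#'
#' @param temperature_C character vector of temperature labels.
#' @param time_min integer vector of holding times in minutes.
#' @return logical vector.
#' @export
legal_design_cell <- function(temperature_C, time_min) {
  temperature_C <- as.character(temperature_C)
  time_min <- as.integer(time_min)
  is_ctrl <- temperature_C == "CONTROL" & time_min == 0L
  is_treat <- temperature_C %in% c("40", "60", "80", "100") &
    time_min %in% c(60L, 120L, 180L, 240L)
  is_ctrl | is_treat
}

## SpectraSet ----------------------------------------------------------------

#' Construct a SpectraSet
#'
#' A `spectra_set` bundles an absorbance matrix (rows = individual scans,
#' columns = wavelengths in nm) with one row of treatment metadata per
#' spectrum. It is the object every pipeline stage consumes and emits.
#'
#' @param wavelengths numeric vector of wavelengths (nm), strictly increasing,
#'   uniformly spaced, within 900-1700 nm.
#' @param absorbance numeric matrix `[n_spectra x n_wavelengths]` in
#'   absorbance units (AU).
#' @param meta data.frame with columns `honey_type`, `temperature_C`,
#'   `time_min`, `replicate`, `fill`, `scan`; one row per spectrum.
#' @param validate validate invariants (default TRUE).
#' @return object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, absorbance, meta, validate = TRUE) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  dimnames(absorbance) <- NULL
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  s <- structure(list(wavelengths = wavelengths,
                      absorbance = absorbance,
                      meta = meta),
                 class = "spectra_set")
  if (validate) validate_spectra_set(s)
  s
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d wavelengths (%.0f-%.0f nm)\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  cat("types:", paste(unique(x$meta$honey_type), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Validate a spectra_set's invariants
#'
#' Checks the wavelength grid (strictly increasing, uniform spacing to
#' 1e-9 nm, inside 900-1700 nm), metadata shape and design-cell legality, and
#' that the absorbance matrix contains no NaN/Inf. Raw instrument absorbance
#' above 2 AU triggers a warning, not an error.
#'
#' @param s spectra_set.
#' @return `s`, invisibly.
#' @export
validate_spectra_set <- function(s) {
  w <- s$wavelengths
  if (length(w) < 2) stop("wavelength grid needs at least 2 points")
  dw <- diff(w)
  if (any(dw <= 0)) stop("wavelengths must be strictly increasing")
  if (max(dw) - min(dw) > 1e-9)
    stop("wavelength grid spacing is not uniform (tolerance 1e-9 nm)")
  if (min(w) < 900 - 1e-9 || max(w) > 1700 + 1e-9)
    stop("wavelengths must lie within [900, 1700] nm")
  if (ncol(s$absorbance) != length(w))
    stop("absorbance column count does not match wavelength grid")
  if (nrow(s$absorbance) != nrow(s$meta))
    stop("absorbance row count does not match metadata rows")
  missing_cols <- setdiff(meta_columns, names(s$meta))
  if (length(missing_cols))
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(s$absorbance)))
    stop("absorbance contains NaN/Inf or missing values")
  m <- s$meta
  known <- m$honey_type %in% c(honey_types(), "WATER_REF")
  if (any(!known))
    stop("unknown honey_type: ", paste(unique(m$honey_type[!known]),
                                       collapse = ", "))
  chk <- m$honey_type != "WATER_REF"
  bad <- chk & !legal_design_cell(m$temperature_C, m$time_min)
  if (any(bad))
    stop(sprintf(
      "illegal (temperature, time) design cell in row(s) %s, e.g. (%s, %s)",
      paste(utils::head(which(bad), 5), collapse = ","),
      m$temperature_C[which(bad)[1]], m$time_min[which(bad)[1]]))
  if (max(s$absorbance) > 2.0)
    warning("absorbance exceeds 2 AU; raw transflectance data should not")
  invisible(s)
}

#' Subset a spectra_set by spectrum index
#'
#' @param s spectra_set.
#' @param i integer or logical row index.
#' @return spectra_set with the selected spectra.
#' @export
subset_spectra <- function(s, i) {
  spectra_set(s$wavelengths, s$absorbance[i, , drop = FALSE],
              s$meta[i, , drop = FALSE], validate = FALSE)
}

#' Drop reference water scans from a spectra_set
#'
#' Reference water samples (`honey_type == "WATER_REF"`) are recorded during
#' acquisition but never modelled.
#'
#' @param s spectra_set.
#' @return spectra_set without water-reference rows.
#' @export
drop_water_refs <- function(s) {
  keep <- s$meta$honey_type != "WATER_REF"
  subset_spectra(s, keep)
}

## CSV I/O --------------------------------------------------------------------

#' Read a wide-format spectra CSV
#'
#' Expects the six metadata columns (`honey_type`, `temperature_C`,
#' `time_min`, `replicate`, `fill`, `scan`) plus numeric wavelength columns
#' whose headers parse as nm values. Wavelength columns are sorted ascending
#' regardless of file order. Control rows carry `temperature_C = "CONTROL"`
#' and `time_min = 0`.
#'
#' @param path CSV file path.
#' @return spectra_set.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(meta_columns, names(df))
  if (length(missing_cols))
    stop("spectra CSV is missing metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  wl_names <- setdiff(names(df), meta_columns)
  wl <- suppressWarnings(as.numeric(wl_names))
  if (any(is.na(wl)))
    stop("non-wavelength extra column(s): ",
         paste(wl_names[is.na(wl)], collapse = ", "))
  if (length(wl) < 2)
    stop("spectra CSV needs at least 2 wavelength columns")
  ord <- order(wl)
  absorb <- df[, wl_names[ord], drop = FALSE]
  for (j in seq_along(absorb)) {
    v <- absorb[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v)))
        stop(sprintf("non-numeric absorbance at row %d, column %s",
                     which(is.na(vn) & !is.na(v))[1], wl_names[ord][j]))
      absorb[[j]] <- vn
    }
  }
  meta <- df[, meta_columns]
  meta$temperature_C <- as.character(meta$temperature_C)
  meta$time_min <- as.integer(meta$time_min)
  meta$replicate <- as.character(meta$replicate)
  meta$fill <- as.integer(meta$fill)
  meta$scan <- as.integer(meta$scan)
  spectra_set(wl[ord], as.matrix(absorb), meta)
}

#' Write a spectra_set to wide-format CSV
#'
#' Inverse of [read_spectra_csv()]: metadata columns first, then one column
#' per wavelength (plain decimal nm headers).
#'
#' @param s spectra_set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  absorb <- as.data.frame(s$absorbance)
  names(absorb) <- format(s$wavelengths, trim = TRUE, scientific = FALSE)
  out <- cbind(s$meta, absorb)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Range cutting --------------------------------------------------------------

#' Cut a spectra_set to a wavelength range
#'
#' Keeps wavelengths `lo <= lambda <= hi`, inclusive on both ends; `lo` and
#' `hi` snap to the nearest grid point before cutting (the working range
#' 1300-1600 nm sits exactly on the 3 nm grid anchored at 900 nm). Metadata
#' is unchanged. Idempotent.
#'
#' @param s spectra_set.
#' @param lo,hi range bounds in nm, `lo < hi`.
#' @return spectra_set restricted to the range.
#' @export
cut_range <- function(s, lo, hi) {
  if (!(lo < hi)) stop("lo must be < hi")
  w <- s$wavelengths
  lo_s <- w[which.min(abs(w - lo))]
  hi_s <- w[which.min(abs(w - hi))]
  keep <- w >= lo_s - 1e-9 & w <= hi_s + 1e-9
  if (!any(keep) || lo > max(w) || hi < min(w))
    stop(sprintf("range [%g, %g] nm does not overlap the grid (%g-%g nm)",
                 lo, hi, min(w), max(w)))
  spectra_set(w[keep], s$absorbance[, keep, drop = FALSE], s$meta,
              validate = FALSE)
}
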