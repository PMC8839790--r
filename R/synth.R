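## Synthetic honey NIR spectra and HMF generator
##
## Emulates the heat-treatment study design: 3 unifloral honey types x
## (4 temperatures x 4 holding times + control) x 3 replicate bottles x
## 3 fills x 5 scans. Heat dose transfers absorbance from strongly
## hydrogen-bonded water bands (~1490-1512 nm) to free-water bands
## (~1412 nm), scaled by the honey's crystallinity; fills carry
## multiplicative/additive scatter artifacts; HMF follows saturating
## Arrhenius-type kinetics.

#' Generate the heat-treatment design table
#'
#' One row per physical sample: the cross of temperatures {40,60,80,100} C
#' and holding times {60,120,180,240} min plus the untreated control, for
#' each honey type and each of three replicate bottles. 17 levels and 51
#' samples per type, 153 samples in total.
#'
#' @return data.frame with columns `honey_type`, `temperature_C`,
#'   `time_min`, `replicate`.
#' @export
generate_design <- function() {
  levels <- rbind(
    data.frame(temperature_C = "CONTROL", time_min = 0L),
    expand.grid(temperature_C = c("40", "60", "80", "100"),
                time_min = c(60L, 120L, 180L, 240L),
                stringsAsFactors = FALSE))
  out <- expand.grid(replicate = replicate_ids(),
                     level = seq_len(nrow(levels)),
                     honey_type = honey_types(),
                     stringsAsFactors = FALSE)
  data.frame(honey_type = out$honey_type,
             temperature_C = levels$temperature_C[out$level],
             time_min = levels$time_min[out$level],
             replicate = out$replicate,
             stringsAsFactors = FALSE)
}

#' Honey archetypes
#'
#' Baseline water-band coefficients, sugar-band coefficient, crystallinity
#' and heat-dose sensitivity per honey type. Crystallinity is ordered
#' sunflower (fully crystallized) > bastard indigo (mid-crystallized) >
#' acacia (liquid); the acacia archetype also carries three-fold larger
#' replicate heterogeneity, which makes its models the weakest.
#'
#' @return named list of archetype lists.
#' @export
default_archetypes <- function() {
  # band order matches band_centers of default_synth_params()
  list(
    sunflower = list(
      name = "sunflower",
      band_weights0 = c(0.10, 0.12, 0.10, 0.11, 0.16, 0.18, 0.22,
                        0.24, 0.22, 0.24, 0.30, 0.34),
      sugar_band_weight0 = 0.28,
      crystallinity = 0.90,
      dose_sensitivity = 1.0,
      replicate_sd_mult = 1.0,
      hmf0 = 18.5,
      hmf_gain = 1.00),
    bastard_indigo = list(
      name = "bastard_indigo",
      band_weights0 = c(0.10, 0.11, 0.10, 0.11, 0.20, 0.18, 0.22,
                        0.23, 0.21, 0.22, 0.27, 0.30),
      sugar_band_weight0 = 0.26,
      crystallinity = 0.50,
      dose_sensitivity = 1.0,
      replicate_sd_mult = 1.0,
      hmf0 = 14.7,
      hmf_gain = 0.65),
    acacia = list(
      name = "acacia",
      band_weights0 = c(0.11, 0.14, 0.11, 0.12, 0.26, 0.22, 0.24,
                        0.22, 0.20, 0.19, 0.20, 0.20),
      sugar_band_weight0 = 0.24,
      crystallinity = 0.10,
      dose_sensitivity = 1.0,
      replicate_sd_mult = 3.0,
      hmf0 = 7.0,
      hmf_gain = 0.46)
  )
}

#' Default generator parameters
#'
#' Band centres sit on the 12 WAMAC anchor wavelengths of the 1300-1600 nm
#' first overtone region plus the 1583 nm sugar band, with Gaussian widths
#' of 12-22 nm. The heat-dose response is a multiplicative transfer of a
#' fixed absorbance budget from the strongly hydrogen-bonded bands
#' (>= 1490 nm) to the free-water band (1412 nm), preserving total band
#' mass. Noise terms: per-replicate lognormal effect on band weights,
#' per-fill multiplicative scatter and additive offset, per-scan Gaussian
#' noise. HMF kinetics: superlinear accumulation in time with Arrhenius
#' temperature scaling (see the methods vignette for the calibration).
#'
#' @param seed integer seed for the generator's deterministic stream.
#' @return list of class `synth_params`.
#' @export
default_synth_params <- function(seed = 1L) {
  structure(list(
    archetypes = default_archetypes(),
    band_centers = c(1344, 1364, 1374, 1384, 1412, 1426, 1440,
                     1452, 1462, 1476, 1490, 1512),
    band_widths = c(14, 12, 12, 13, 16, 14, 15, 13, 13, 14, 16, 20),
    sugar_band_center = 1583,
    sugar_band_width = 18,
    dose_halftime = 60,       # min; saturation half-time of the dose
    dose_activation = 0.030,  # 1/K; temperature gain of the dose
    transfer_scale = 0.18,    # max fraction of bound-band mass moved
    sugar_dose_gain = 0.03,   # weak dose response of the 1583 nm band
    scatter_sd = 0.012,       # per-fill multiplicative (lognormal sigma)
    offset_sd = 0.004,        # AU, per-fill additive
    scan_noise_sd = 0.0015,   # AU, per-scan per-wavelength
    replicate_sd = 0.015,     # lognormal sigma on band weights
    hmf_rate = 1.17e-6,       # mg/kg/min^time_exponent at 40 C
    hmf_activation = 17100,   # K
    hmf_time_exponent = 2,
    hmf_noise_sd = 0.05,      # lognormal sigma on the heat increment
    hmf_base_sd = 0.05,       # lognormal sigma on the baseline HMF
    seed = as.integer(seed)),
    class = "synth_params")
}

#' Heat dose of a design cell
#'
#' A unitless monotone surrogate for the heat perturbation:
#' `dose = (1 - 2^(-t / halftime)) * exp(activation * (T - 40))`, zero for
#' the control. Strictly increasing in temperature at fixed time and in time
#' at fixed temperature, saturating in time.
#'
#' @param temperature_C temperature label ("CONTROL", "40", ... "100").
#' @param time_min holding time in minutes.
#' @param params synth_params.
#' @return numeric dose >= 0 (vectorized).
#' @export
heat_dose <- function(temperature_C, time_min, params = default_synth_params()) {
  temperature_C <- as.character(temperature_C)
  time_min <- as.numeric(time_min)
  dose <- numeric(length(temperature_C))
  trt <- temperature_C != "CONTROL"
  Tn <- suppressWarnings(as.numeric(temperature_C[trt]))
  dose[trt] <- (1 - 2^(-time_min[trt] / params$dose_halftime)) *
    exp(params$dose_activation * (Tn - 40))
  dose
}

## internal: Gaussian band profile matrix [n_bands x n_wavelengths]
band_profiles <- function(wavelengths, centers, widths) {
  t(vapply(seq_along(centers),
           function(i) exp(-0.5 * ((wavelengths - centers[i]) / widths[i])^2),
           numeric(length(wavelengths))))
}

## internal: dose-shifted band weights for one sample (pre-noise)
dosed_band_weights <- function(arch, dose, params) {
  w <- arch$band_weights0
  centers <- params$band_centers
  bound <- centers >= 1489
  free <- centers >= 1405 & centers <= 1415
  frac <- tanh(params$transfer_scale * arch$crystallinity *
                 arch$dose_sensitivity * dose)
  moved <- sum(w[bound]) * frac
  w[bound] <- w[bound] * (1 - frac)
  w[free] <- w[free] + moved * w[free] / sum(w[free])
  w
}

#' Generate synthetic NIR spectra for a design table
#'
#' For each sample, 3 fills x 5 scans (configurable). Each spectrum is a sum
#' of Gaussian water bands whose coefficients shift with heat dose (bound
#' bands >= 1489 nm lose absorbance to the 1412 nm free-water band, scaled
#' by crystallinity x dose sensitivity), a weakly dosed sugar band at
#' 1583 nm, and a smooth quadratic baseline spanning 900-1700 nm; plus a
#' replicate-level lognormal effect on band weights, a per-fill
#' multiplicative scatter factor and additive offset, and per-scan Gaussian
#' noise. Deterministic per `params$seed`.
#'
#' @param design design table from [generate_design()] (any subset).
#' @param params synth_params.
#' @param n_fills,n_scans fills per sample and scans per fill (defaults 3, 5).
#' @param wavelengths grid (default 901-1699 nm at 3 nm, the 267-point
#'   instrument grid; it contains 1300 and 1600 exactly).
#' @return spectra_set.
#' @export
generate_spectra <- function(design, params = default_synth_params(),
                             n_fills = 3L, n_scans = 5L,
                             wavelengths = seq(901, 1699, by = 3)) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(params$seed)
  B <- band_profiles(wavelengths, params$band_centers, params$band_widths)
  sugar <- exp(-0.5 * ((wavelengths - params$sugar_band_center) /
                         params$sugar_band_width)^2)
  # smooth baseline common to all honeys: gentle quadratic in lambda
  lam01 <- (wavelengths - 900) / 800
  baseline <- 0.15 + 0.10 * lam01 + 0.05 * lam01^2

  # replicate-level multiplicative effects, one per (type, replicate)
  rep_key <- unique(data.frame(honey_type = design$honey_type,
                               replicate = design$replicate,
                               stringsAsFactors = FALSE))
  n_bands <- length(params$band_centers)
  rep_eff <- list()
  for (k in seq_len(nrow(rep_key))) {
    arch <- params$archetypes[[rep_key$honey_type[k]]]
    sdk <- params$replicate_sd * arch$replicate_sd_mult
    rep_eff[[paste(rep_key$honey_type[k], rep_key$replicate[k])]] <-
      exp(stats::rnorm(n_bands, 0, sdk))
  }

  n_per_sample <- n_fills * n_scans
  n_total <- nrow(design) * n_per_sample
  X <- matrix(0, n_total, length(wavelengths))
  meta <- data.frame(honey_type = character(n_total),
                     temperature_C = character(n_total),
                     time_min = integer(n_total),
                     replicate = character(n_total),
                     fill = integer(n_total), scan = integer(n_total),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(nrow(design))) {
    arch <- params$archetypes[[design$honey_type[i]]]
    dose <- heat_dose(design$temperature_C[i], design$time_min[i], params)
    w <- dosed_band_weights(arch, dose, params) *
      rep_eff[[paste(design$honey_type[i], design$replicate[i])]]
    sugar_w <- arch$sugar_band_weight0 *
      (1 + params$sugar_dose_gain * tanh(dose))
    clean <- baseline + as.numeric(w %*% B) + sugar_w * sugar
    for (f in seq_len(n_fills)) {
      mult <- exp(stats::rnorm(1, 0, params$scatter_sd))
      off <- stats::rnorm(1, 0, params$offset_sd)
      for (sc in seq_len(n_scans)) {
        row <- row + 1L
        X[row, ] <- mult * clean + off +
          stats::rnorm(length(wavelengths), 0, params$scan_noise_sd)
        meta$honey_type[row] <- design$honey_type[i]
        meta$temperature_C[row] <- design$temperature_C[i]
        meta$time_min[row] <- design$time_min[i]
        meta$replicate[row] <- design$replicate[i]
        meta$fill[row] <- f
        meta$scan[row] <- sc
      }
    }
  }
  spectra_set(wavelengths, X, meta)
}

#' Generate a synthetic HMF table for a design table
#'
#' `HMF = hmf0 * exp(N(0, base_sd)) + gain * rate *
#' exp(activation * (1/313 - 1/T_K)) * time^exponent * exp(N(0, noise_sd))`,
#' in mg/kg; the control carries only the baseline term. With the default
#' exponent of 2 the accumulation is superlinear in time, reproducing the
#' observed induction-like lag at 80 C (negligible increment at 60 min, a
#' clear one from 120 min) together with the strong 100 C response.
#'
#' @param design design table.
#' @param params synth_params.
#' @return data.frame `honey_type, temperature_C, time_min, replicate,
#'   hmf_mg_kg`.
#' @export
generate_hmf <- function(design, params = default_synth_params()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(params$seed + 1L)
  n <- nrow(design)
  hmf <- numeric(n)
  for (i in seq_len(n)) {
    arch <- params$archetypes[[design$honey_type[i]]]
    base <- arch$hmf0 * exp(stats::rnorm(1, 0, params$hmf_base_sd))
    inc <- 0
    if (design$temperature_C[i] != "CONTROL") {
      TK <- as.numeric(design$temperature_C[i]) + 273.15
      inc <- arch$hmf_gain * params$hmf_rate *
        exp(params$hmf_activation * (1 / 313.15 - 1 / TK)) *
        design$time_min[i]^params$hmf_time_exponent *
        exp(stats::rnorm(1, 0, params$hmf_noise_sd))
    }
    hmf[i] <- base + inc
  }
  data.frame(design, hmf_mg_kg = hmf, stringsAsFactors = FALSE)
}
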