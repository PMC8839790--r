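# Shared fixtures, built in code.

# A small valid spectra_set: `n_per_cell` spectra for each of a few design
# cells, smooth Gaussian-bump spectra on the full 900-1700 nm grid.
toy_spectra <- function(n_per_cell = 2, seed = 42,
                        wavelengths = seq(901, 1699, by = 3)) {
  set.seed(seed)
  cells <- data.frame(
    honey_type = "sunflower",
    temperature_C = c("CONTROL", "40", "100"),
    time_min = c(0L, 60L, 240L),
    stringsAsFactors = FALSE)
  rows <- cells[rep(seq_len(nrow(cells)), each = n_per_cell * 3), ]
  rows$replicate <- rep(rep(c("R1", "R2", "R3"), each = n_per_cell),
                        nrow(cells))
  rows$fill <- 1L
  rows$scan <- rep(seq_len(n_per_cell), nrow(cells) * 3)
  n <- nrow(rows)
  X <- t(vapply(seq_len(n), function(i)
    0.3 + 0.4 * exp(-0.5 * ((wavelengths - 1450) / 40)^2) +
      rnorm(length(wavelengths), 0, 0.002),
    numeric(length(wavelengths))))
  spectra_set(wavelengths, X, rows)
}

# The default sunflower-archetype study subset used in several tests:
# full design, default params, cut to the working range. Cached per session.
sunflower_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- generate_spectra(generate_design(), default_synth_params(1))
      cache <<- cut_range(s, 1300, 1600)
    }
    cache
  }
})

# Raw values matching a (mean, sd, n) summary exactly: affine-transform a
# fixed sample to hit the target moments.
raw_matching_summary <- function(mean, sd, n) {
  x <- seq_len(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}
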