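# shared fixtures built in code

# small random spectra set on an integer-nm grid
random_spectra <- function(n = 10, p = 20, seed = 1, reference = FALSE,
                           grid = NULL) {
  set.seed(seed)
  if (is.null(grid)) grid <- seq(1000, by = 2, length.out = p)
  spectra_set(grid, matrix(rnorm(n * length(grid)), n),
              reference = if (reference) rnorm(n, 19, 2) else NULL)
}

# smooth Gaussian-band spectra used by transfer tests: rows differ in band
# amplitudes, so windows have structure an instrument map can act on
smooth_spectra <- function(n = 20, grid = seq(1000, 1200, by = 2),
                           seed = 1, reference = FALSE) {
  set.seed(seed)
  bands <- cbind(exp(-((grid - 1050) / 30)^2),
                 exp(-((grid - 1120) / 40)^2),
                 exp(-((grid - 1180) / 35)^2))
  amp <- matrix(runif(n * 3, 0.5, 1.5), n)
  spectra_set(grid, amp %*% t(bands) + 0.2,
              reference = if (reference) amp[, 2] * 10 + rnorm(n, 0, 0.05)
                          else NULL)
}

# small fast experiment scenario for pipeline tests: coarse grids covering
# the analyte bands, fixed LS-SVM parameters so no tuning loop runs
small_config <- function(seed = 1, half_width = 5, master = "master", ...) {
  mp <- instrument_profile(seq(1000, 1800, by = 4), gain = 1,
                           baseline = c(0.02, 0), smoothing_fwhm = 8,
                           noise_sd = 0.0015)
  wn <- seq(1e7 / 998, 1e7 / 1802, length.out = 420)
  sp <- instrument_profile(sort(1e7 / wn), gain = c(1.2, -0.6, -0.8),
                           baseline = c(0.1, 0.2), wavelength_shift = 6,
                           smoothing_fwhm = 2, noise_sd = 0.003)
  experiment_config(n = 140, seed = seed, master_profile = mp,
                    slave_profile = sp, n_calibration = 100,
                    n_standardization = 20, gamma = 100, sigma2 = 10,
                    slave_plan = preprocess_plan(ma(5)),
                    half_width = half_width, master = master, ...)
}
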