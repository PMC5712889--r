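# Seeded simulator of paired master/slave NIR spectra of single fruit
# berries with soluble-solids (SSC, %Brix) reference values. It emulates a
# portable grating instrument on a uniform 1 nm grid and a benchtop
# Fourier-transform instrument on a wavenumber-uniform grid, observing the
# same berries, so every stage of the transfer chain can be exercised
# without proprietary data.

#' Analyte absorption model for simulated berry spectra
#'
#' Clean spectra are a sum of Gaussian absorption bands at the wavelengths
#' where sugar/water overtone and combination bands appear in berries
#' (defaults 1050, 1185, 1450, 1770 nm), each with an amplitude affine in
#' the SSC value, on top of a broad water-dominated background with a
#' gentle baseline. Band widths and amplitudes are package defaults chosen
#' to give realistic signal-to-noise; they are configuration, not measured
#' constants.
#'
#' @param band_centers,band_fwhm Band positions and full widths at half
#'   maximum, nm.
#' @param band_amp_base Band amplitude at SSC = 0 (absorbance units).
#' @param band_amp_ssc Band amplitude per unit SSC (%Brix).
#' @param bg_centers,bg_fwhm,bg_amp Background (water) bands.
#' @param bg_offset,bg_slope Baseline offset and slope (per 1000 nm).
#' @return An object of class `analyte_model`.
#' @export
analyte_model <- function(band_centers = c(1050, 1185, 1450, 1770),
                          band_fwhm = c(45, 55, 70, 90),
                          band_amp_base = c(0.03, 0.06, 0.28, 0.20),
                          band_amp_ssc = c(0.0020, 0.0035, 0.0065, 0.0090),
                          bg_centers = c(960, 1440, 1790),
                          bg_fwhm = c(100, 110, 180),
                          bg_amp = c(0.20, 0.85, 0.50),
                          bg_offset = 0.15, bg_slope = 0.05) {
  stopifnot(all(band_fwhm > 0), all(bg_fwhm > 0),
            length(band_centers) == length(band_fwhm),
            length(band_centers) == length(band_amp_base),
            length(band_centers) == length(band_amp_ssc))
  structure(list(band_centers = band_centers, band_fwhm = band_fwhm,
                 band_amp_base = band_amp_base, band_amp_ssc = band_amp_ssc,
                 bg_centers = bg_centers, bg_fwhm = bg_fwhm, bg_amp = bg_amp,
                 bg_offset = bg_offset, bg_slope = bg_slope),
            class = "analyte_model")
}

#' Instrument response profile
#'
#' Describes how an instrument observes a clean spectrum: its reporting
#' grid, a multiplicative gain, an additive baseline (constant plus a mild
#' slope per 1000 nm), a wavelength-registration shift, a Gaussian
#' resolution blur (FWHM in nm), and i.i.d. Gaussian photometric noise.
#'
#' @param grid Strictly increasing reporting wavelengths, nm.
#' @param gain Multiplicative response: either a scalar or
#'   `c(g0, slope, curvature)` describing the smooth detector response
#'   curve `g0 (1 + slope u + curvature u^2)` with `u = (lambda - 1400) /
#'   1000` (detector families differ most in this curve, and it is the
#'   dominant cross-instrument distortion scatter correction cannot
#'   remove).
#' @param baseline Length-2 numeric `c(offset, slope_per_1000nm)`.
#' @param wavelength_shift Registration error in nm (the instrument reports
#'   wavelength `lambda` while actually sampling `lambda + shift`).
#' @param smoothing_fwhm Resolution blur FWHM in nm (0 = none).
#' @param noise_sd Photometric noise SD, absorbance units.
#' @param nonlinearity Photometric nonlinearity coefficient `c`: the
#'   recorded absorbance is `y + c y^2` (detector/stray-light deviation
#'   from Beer's law; 0 = perfectly linear response).
#' @return An object of class `instrument_profile`.
#' @export
instrument_profile <- function(grid, gain = 1, baseline = c(0, 0),
                               wavelength_shift = 0, smoothing_fwhm = 0,
                               noise_sd = 0, nonlinearity = 0) {
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (smoothing_fwhm < 0 || noise_sd < 0) {
    stop("smoothing_fwhm and noise_sd must be >= 0")
  }
  if (length(baseline) == 1) baseline <- c(baseline, 0)
  gain <- as.numeric(gain)
  if (!length(gain) %in% c(1, 3)) stop("gain must have length 1 or 3")
  structure(list(grid = grid, gain = gain, baseline = baseline,
                 wavelength_shift = wavelength_shift,
                 smoothing_fwhm = smoothing_fwhm, noise_sd = noise_sd,
                 nonlinearity = nonlinearity),
            class = "instrument_profile")
}

#' Default simulated instruments
#'
#' `default_master_profile()` emulates a portable grating scanner: uniform
#' 1000-1800 nm grid at 1 nm, mild blur and noise. `default_slave_profile()`
#' emulates a benchtop Fourier-transform instrument: a wavenumber-uniform
#' grid from 12000 to 5556 cm^-1 (~833-1800 nm, so nm spacing widens with
#' wavelength), different gain and sloped baseline, a small wavelength
#' registration shift, and a broader resolution blur. The distortions are
#' deliberately strong enough that a master-instrument model applied to
#' merely re-gridded slave spectra fails, which is the situation
#' calibration transfer exists for.
#'
#' @return An [instrument_profile()].
#' @export
default_master_profile <- function() {
  instrument_profile(grid = seq(1000, 1800, by = 1),
                     gain = 1, baseline = c(0.02, 0),
                     wavelength_shift = 0, smoothing_fwhm = 8,
                     noise_sd = 0.0015)
}

#' @rdname default_master_profile
#' @export
default_slave_profile <- function() {
  wn <- seq(12000, 5556, length.out = 1670)
  instrument_profile(grid = sort(1e7 / wn),
                     gain = c(1.25, -0.90, -1.10), baseline = c(0.10, 0.30),
                     wavelength_shift = 8, smoothing_fwhm = 2,
                     noise_sd = 0.003)
}

#' Draw SSC reference values
#'
#' Samples from a normal distribution with mean 19.1 and SD 2.0 %Brix,
#' truncated (by rejection) to the observed berry range [12.9, 23.2],
#' matching the descriptive statistics of ripe table-grape berries.
#'
#' @param n Number of samples.
#' @param seed Optional integer seed (uses the current RNG stream if NULL).
#' @param mean,sd,range Distribution parameters.
#' @return Numeric vector of length `n`.
#' @export
generate_reference <- function(n, seed = NULL, mean = 19.1, sd = 2.0,
                               range = c(12.9, 23.2)) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
  }
  out[seq_len(n)]
}

.gauss_band <- function(grid, center, fwhm) {
  exp(-4 * log(2) * (grid - center)^2 / fwhm^2)
}

#' Clean (noise-free, instrument-free) berry spectrum
#'
#' Deterministic in `ssc`: the SSC-dependent band amplitudes are
#' `band_amp_base + band_amp_ssc * ssc`, so the spectral difference of two
#' SSC values is exactly proportional to `band_amp_ssc`.
#'
#' @param ssc SSC value(s), %Brix; a vector gives one spectrum per row.
#' @param model An [analyte_model()].
#' @param grid Wavelengths, nm.
#' @return A numeric vector (single `ssc`) or matrix (rows = samples).
#' @export
generate_clean_spectrum <- function(ssc, model = analyte_model(), grid) {
  G <- vapply(seq_along(model$band_centers), function(k) {
    .gauss_band(grid, model$band_centers[k], model$band_fwhm[k])
  }, numeric(length(grid)))              # p x n_bands
  amp <- outer(ssc, model$band_amp_ssc) +
    matrix(model$band_amp_base, length(ssc), length(model$band_amp_base),
           byrow = TRUE)                 # n x n_bands
  bg <- model$bg_offset + model$bg_slope * (grid - 1400) / 1000
  for (k in seq_along(model$bg_centers)) {
    bg <- bg + model$bg_amp[k] *
      .gauss_band(grid, model$bg_centers[k], model$bg_fwhm[k])
  }
  out <- tcrossprod(amp, G) + matrix(bg, length(ssc), length(grid),
                                     byrow = TRUE)
  if (length(ssc) == 1) drop(out) else out
}

# Gaussian blur of spectra rows sampled on a uniform dense grid, with
# truncated-window normalization at the edges.
.blur_rows <- function(Y, step, fwhm) {
  if (fwhm <= 0) return(Y)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / step))
  kern <- stats::dnorm(seq(-half, half) * step, sd = sigma)
  num <- t(stats::filter(t(Y), kern, sides = 2))
  den <- stats::filter(rep(1, ncol(Y)), kern, sides = 2)
  # edge windows: renormalize by the kernel mass actually inside the grid
  edge <- is.na(den)
  den[edge] <- vapply(which(edge), function(j) {
    lo <- max(1L, j - half); hi <- min(ncol(Y), j + half)
    sum(kern[(lo - j + half + 1L):(hi - j + half + 1L)])
  }, numeric(1))
  for (j in which(is.na(num[1, ]))) {
    lo <- max(1L, j - half); hi <- min(ncol(Y), j + half)
    kk <- kern[(lo - j + half + 1L):(hi - j + half + 1L)]
    num[, j] <- Y[, lo:hi, drop = FALSE] %*% kk
  }
  sweep(num, 2, as.numeric(den), "/")
}

#' Observe clean spectra through an instrument
#'
#' Applies, in order: Gaussian resolution blur on the dense grid,
#' wavelength-shifted resampling onto the instrument grid (linear
#' interpolation at `grid + wavelength_shift`), multiplicative gain,
#' additive baseline, and i.i.d. Gaussian noise.
#'
#' @param clean Numeric vector or matrix of clean spectra on `dense_grid`.
#' @param dense_grid Uniform, strictly increasing nm vector covering
#'   `profile$grid + wavelength_shift` (plus blur margin).
#' @param profile An [instrument_profile()].
#' @param seed Optional integer seed for the noise draw.
#' @return Absorbance matrix on `profile$grid` (rows = samples).
#' @export
measure <- function(clean, dense_grid, profile, seed = NULL) {
  stopifnot(inherits(profile, "instrument_profile"))
  if (is.null(dim(clean))) clean <- matrix(clean, nrow = 1)
  step <- dense_grid[2] - dense_grid[1]
  Y <- .blur_rows(clean, step, profile$smoothing_fwhm)
  q <- profile$grid + profile$wavelength_shift
  if (q[1] < dense_grid[1] || q[length(q)] > dense_grid[length(dense_grid)]) {
    stop("instrument grid (plus shift) outside the dense grid span")
  }
  Y <- .interp_rows(Y, dense_grid, q)
  u <- (profile$grid - 1400) / 1000
  g <- profile$gain
  resp <- if (length(g) == 1) rep(g, length(u)) else {
    g[1] * (1 + g[2] * u + g[3] * u^2)
  }
  base <- profile$baseline[1] + profile$baseline[2] * u
  Y <- sweep(sweep(Y, 2, resp, "*"), 2, base, "+")
  nl <- profile$nonlinearity
  if (!is.null(nl) && nl != 0) Y <- Y + nl * Y^2
  if (profile$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    Y <- Y + matrix(stats::rnorm(length(Y), 0, profile$noise_sd),
                    nrow(Y), ncol(Y))
  }
  Y
}

#' Generate a paired master/slave dataset
#'
#' Draws `n` berries (SSC reference values plus per-berry chemistry and
#' scatter variability) and observes the same clean spectra through both
#' instrument profiles. Berries are grouped into bunches of
#' `n_per_cluster`: bunch-level mean SSC varies between bunches
#' (`ssc_between_sd`) and berries vary around their bunch mean
#' (`ssc_within_sd`), reproducing the grouped sampling design of orchard
#' studies (several berries picked per bunch). The chemistry noise
#' (`chem_sd`, in %Brix equivalents) models the imperfect link between the
#' spectral signature and the refractometer value and sets the attainable
#' prediction error; per-berry multiplicative/additive scatter emulates
#' particle-size and surface effects (largely removed by SNV). Fully
#' deterministic given `seed`.
#'
#' @param n Number of berries.
#' @param master_profile,slave_profile [instrument_profile()]s.
#' @param model An [analyte_model()].
#' @param seed Integer seed.
#' @param n_per_cluster Berries per bunch.
#' @param ssc_between_sd,ssc_within_sd Between-/within-bunch SSC SDs
#'   (their quadrature sum is the overall SD of about 2 %Brix).
#' @param chem_sd Chemistry-noise SD, %Brix equivalents.
#' @param scatter_mult_sd,scatter_offset_sd,scatter_slope_sd Per-berry
#'   scatter parameter SDs.
#' @param temp_sd SD (nm) of the bunch-level band shift emulating
#'   sample-temperature variation; water-band position is strongly
#'   temperature dependent in the NIR, and the effect is nonlinear in the
#'   shift, which is what makes kernel models preferable to purely linear
#'   ones on real berry spectra.
#' @param flesh_between_sd,flesh_within_sd Log-scale SDs of the
#'   multiplicative path-length factor applied to the analyte bands
#'   (bunch level and berry level). Berry size and skin thickness change
#'   the effective optical path through the flesh, scaling the
#'   sugar-related band amplitudes relative to the water background.
#' @param hydration_sd Log-scale SD of the per-berry multiplicative factor
#'   on the water background bands (hydration varies between berries and
#'   dominates sample-to-sample spectral diversity).
#' @param saturation_scale Curvature scale `s0` (in %Brix) of the
#'   saturating link between the refractometer SSC and the spectrally
#'   active sugar signal: the band amplitudes follow
#'   `h(ssc) = 12.9 + a (1 - exp(-(ssc - 12.9)/s0))` (with `a` chosen so
#'   `h` maps the SSC range onto itself). High absorbance deviates from
#'   Beer's law, so the absorbance-concentration relation flattens at
#'   high concentration; inverting the curve is what makes kernel
#'   regression outperform purely linear models on these spectra. `0`
#'   disables the curvature.
#' @param dense_grid Internal simulation grid.
#' @return A list with `master` and `slave` [spectra_set()]s sharing sample
#'   ids and reference values.
#' @export
generate_paired_dataset <- function(n = 700,
                                    master_profile = default_master_profile(),
                                    slave_profile = default_slave_profile(),
                                    model = analyte_model(),
                                    seed = 1,
                                    n_per_cluster = 10,
                                    ssc_between_sd = 1.6,
                                    ssc_within_sd = 1.2,
                                    chem_sd = 0.45,
                                    scatter_mult_sd = 0.06,
                                    scatter_offset_sd = 0.04,
                                    scatter_slope_sd = 0.03,
                                    temp_sd = 0.8,
                                    flesh_between_sd = 0.02,
                                    flesh_within_sd = 0.02,
                                    hydration_sd = 0.08,
                                    saturation_scale = 6,
                                    dense_grid = seq(810, 1860, by = 0.5)) {
  set.seed(seed)
  n_cl <- ceiling(n / n_per_cluster)
  cluster <- rep(seq_len(n_cl), each = n_per_cluster)[seq_len(n)]
  mu <- generate_reference(n_cl, sd = ssc_between_sd)
  ssc <- mu[cluster] + stats::rnorm(n, 0, ssc_within_sd)
  # truncate by resampling so the range limits carry no point mass
  bad <- which(ssc < 12.9 | ssc > 23.2)
  while (length(bad) > 0) {
    ssc[bad] <- mu[cluster[bad]] + stats::rnorm(length(bad), 0, ssc_within_sd)
    bad <- bad[ssc[bad] < 12.9 | ssc[bad] > 23.2]
  }
  spectral <- if (saturation_scale > 0) {
    u <- ssc - 12.9
    a <- 10.3 / (1 - exp(-10.3 / saturation_scale))
    12.9 + a * (1 - exp(-u / saturation_scale))
  } else {
    ssc
  }
  latent <- spectral + stats::rnorm(n, 0, chem_sd)
  # analyte bands scaled by a per-berry optical path factor (bunch-level
  # times berry-level, lognormal); the water background is unaffected
  flesh <- exp(stats::rnorm(n_cl, 0, flesh_between_sd))[cluster] *
    exp(stats::rnorm(n, 0, flesh_within_sd))
  model_bands <- model
  model_bands$bg_amp <- 0 * model_bands$bg_amp
  model_bands$bg_offset <- 0
  model_bands$bg_slope <- 0
  bands <- generate_clean_spectrum(latent, model_bands, dense_grid)
  # water background with per-berry hydration variation (broad, smooth,
  # SSC-independent nuisance; the dominant source of spectral diversity)
  bg_bands <- numeric(length(dense_grid))
  for (k in seq_along(model$bg_centers)) {
    bg_bands <- bg_bands + model$bg_amp[k] *
      .gauss_band(dense_grid, model$bg_centers[k], model$bg_fwhm[k])
  }
  hydr <- exp(stats::rnorm(n, 0, hydration_sd))
  base_line <- model$bg_offset + model$bg_slope * (dense_grid - 1400) / 1000
  clean <- bands * flesh + outer(hydr, bg_bands) +
    matrix(base_line, n, length(dense_grid), byrow = TRUE)
  if (temp_sd > 0) {
    # temperature-like band shift, shared within a bunch (berries of one
    # bunch are measured together): the whole absorption pattern drifts by
    # a few nm (water-band positions are strongly temperature dependent);
    # the effect is nonlinear in the shift
    tshift <- stats::rnorm(n_cl, 0, temp_sd)[cluster]
    pad <- 4 * temp_sd + 1
    gpad <- c(dense_grid[1] - pad, dense_grid,
              dense_grid[length(dense_grid)] + pad)
    for (i in seq_len(n)) {
      row <- matrix(c(clean[i, 1], clean[i, ], clean[i, ncol(clean)]),
                    nrow = 1)
      clean[i, ] <- .interp_rows(row, gpad, dense_grid + tshift[i])
    }
  }
  mult <- 1 + stats::rnorm(n, 0, scatter_mult_sd)
  offs <- stats::rnorm(n, 0, scatter_offset_sd)
  slp <- stats::rnorm(n, 0, scatter_slope_sd)
  clean <- clean * mult + outer(offs, rep(1, length(dense_grid))) +
    outer(slp, (dense_grid - 1340) / 1000)
  ids <- sprintf("B%04d", seq_len(n))
  m <- measure(clean, dense_grid, master_profile)
  s <- measure(clean, dense_grid, slave_profile)
  list(master = spectra_set(master_profile$grid, m, ids, ssc),
       slave = spectra_set(slave_profile$grid, s, ids, ssc))
}
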