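test_that("interpolation is exact on nodes and affine spectra", {
  g <- seq(1000, 1100, by = 2.5)
  s <- spectra_set(g, matrix(2 * g + 3, 1))
  # node queries are bit-preserving
  node <- interpolate_to_grid(s, g[c(3, 17)])
  expect_identical(drop(node$absorbance), s$absorbance[1, c(3, 17)])
  # affine spectra reproduced exactly anywhere, including the endpoints
  q <- c(1000, 1001.3, 1049.99, 1100)
  out <- interpolate_to_grid(s, q)
  expect_equal(drop(out$absorbance), 2 * q + 3, tolerance = 1e-10)
  # midpoint of neighbours with values 0.4 / 0.8
  s2 <- spectra_set(c(1000, 1002), matrix(c(0.4, 0.8), 1))
  expect_equal(drop(interpolate_to_grid(s2, 1001)$absorbance), 0.6)
  expect_error(interpolate_to_grid(s, c(999, 1050)), "999")
})

test_that("interpolation matches stats::approx on dense random grids", {
  set.seed(51)
  g <- sort(runif(80, 1000, 1800))
  Y <- matrix(rnorm(3 * 80), 3)
  s <- spectra_set(g, Y)
  q <- sort(runif(200, min(g), max(g)))
  out <- interpolate_to_grid(s, q)$absorbance
  # grid may be reordered inside the constructor; compare per sample
  for (i in 1:3) {
    ref <- stats::approx(s$wavelengths, s$absorbance[i, ], xout = q)$y
    expect_equal(out[i, ], ref, tolerance = 1e-12)
  }
})

test_that("interpolation map brackets every query between adjacent nodes", {
  g <- c(1000, 1001.5, 1004, 1010)
  q <- c(1000, 1002, 1009.9, 1010)
  m <- interpolation_map(g, q)
  expect_true(all(g[m$lower] <= m$wavelength + 1e-12))
  expect_true(all(g[m$upper] >= m$wavelength - 1e-12))
  expect_true(all(m$upper - m$lower <= 1))
  expect_error(interpolation_map(g, 1011), "span")
})

test_that("identity and scalar-gain transfers are recovered exactly", {
  s <- smooth_spectra(12, seed = 52)
  t0 <- build_pds(s, s, half_width = 0, n_window_components = 1,
                  intercept = FALSE)
  expect_lt(max(abs(pds_matrix(t0) - diag(n_wavelengths(s)))), 1e-12)
  expect_equal(apply_transfer(t0, s)$absorbance, s$absorbance,
               tolerance = 1e-12)
  doubled <- spectra_set(s$wavelengths, 2 * s$absorbance, s$sample_ids)
  t2 <- build_pds(s, doubled, half_width = 0, n_window_components = 1,
                  intercept = FALSE)
  expect_equal(unlist(t2$coefs), rep(0.5, n_wavelengths(s)),
               tolerance = 1e-10)
})

test_that("the PDS matrix is banded and equals the applied operator", {
  m <- smooth_spectra(15, seed = 53)
  sl <- spectra_set(m$wavelengths, 1.1 * m$absorbance + 0.05,
                    m$sample_ids)
  t <- build_pds(m, sl, half_width = 3, n_window_components = 2,
                 intercept = FALSE)
  F_ <- pds_matrix(t)
  p <- nrow(F_)
  for (i in seq_len(p)) {
    out_of_band <- setdiff(seq_len(p), max(1, i - 3):min(p, i + 3))
    expect_true(all(F_[out_of_band, i] == 0))
  }
  q <- smooth_spectra(4, seed = 54)
  expect_equal(apply_transfer(t, q)$absorbance, q$absorbance %*% F_,
               tolerance = 1e-10)
})

test_that("transfer application is linear in the spectra", {
  m <- smooth_spectra(15, seed = 55)
  sl <- spectra_set(m$wavelengths, 0.9 * m$absorbance + 0.02)
  t <- build_pds(m, sl, half_width = 2, intercept = FALSE)
  A <- smooth_spectra(5, seed = 56)
  B <- smooth_spectra(5, seed = 57)
  mix <- spectra_set(A$wavelengths, 0.4 * A$absorbance + 1.6 * B$absorbance)
  expect_equal(apply_transfer(t, mix)$absorbance,
               0.4 * apply_transfer(t, A)$absorbance +
                 1.6 * apply_transfer(t, B)$absorbance,
               tolerance = 1e-10)
})

test_that("linear interpolation-PDS corrects a distorted instrument pair", {
  # slave: gain 1.1, +0.5 nm shift, mild baseline, denser uneven grid
  set.seed(58)
  dense <- seq(995, 1210, by = 0.25)
  bands <- cbind(exp(-((dense - 1050) / 30)^2),
                 exp(-((dense - 1120) / 40)^2),
                 exp(-((dense - 1180) / 35)^2))
  n <- 40
  amp <- matrix(runif(n * 3, 0.5, 1.5), n)
  clean <- amp %*% t(bands) + 0.2
  mg <- seq(1000, 1200, by = 2)
  sg <- sort(1e7 / seq(1e7 / 998, 1e7 / 1205, length.out = 150))
  master <- spectra_set(mg, nirtransfer:::.interp_rows(clean, dense, mg))
  slave_raw <- nirtransfer:::.interp_rows(clean, dense, sg + 0.5)
  slave <- spectra_set(sg, 1.1 * slave_raw + 0.03 +
                         outer(rep(1, n), (sg - 1100) / 5000))
  std <- 1:20; pred <- 21:40
  untr <- interpolate_to_grid(slave[pred, ], mg)
  base_rmse <- sqrt(mean((untr$absorbance - master$absorbance[pred, ])^2))
  for (hw in c(5, 10, 15)) {
    t <- linear_interp_pds(master[std, ], slave[std, ], mg, hw,
                           n_window_components = 2, intercept = TRUE)
    tr <- apply_transfer(t, slave[pred, ])
    rmse <- sqrt(mean((tr$absorbance - master$absorbance[pred, ])^2))
    expect_lt(rmse, 0.2 * base_rmse, label = paste("half-width", hw))
  }
  # in-sample residual does not exceed out-of-sample residual
  t <- linear_interp_pds(master[std, ], slave[std, ], mg, 10, 2, TRUE)
  in_res <- mean((apply_transfer(t, slave[std, ])$absorbance -
                    master$absorbance[std, ])^2)
  out_res <- mean((apply_transfer(t, slave[pred, ])$absorbance -
                     master$absorbance[pred, ])^2)
  expect_lte(in_res, out_res)
})

test_that("composition with identical grids and responses is the identity", {
  s <- smooth_spectra(10, seed = 59)
  t <- linear_interp_pds(s, s, half_width = 0, n_window_components = 1,
                         intercept = FALSE)
  expect_equal(apply_transfer(t, s)$absorbance, s$absorbance,
               tolerance = 1e-10)
})

test_that("a wavenumber-spaced slave with no distortion needs only regridding", {
  set.seed(60)
  dense <- seq(995, 1210, by = 0.25)
  bands <- cbind(exp(-((dense - 1060) / 35)^2),
                 exp(-((dense - 1150) / 45)^2))
  amp <- matrix(runif(24 * 2, 0.5, 1.5), 24)
  clean <- amp %*% t(bands) + 0.3
  mg <- seq(1000, 1200, by = 2)
  sg <- sort(1e7 / seq(1e7 / 999, 1e7 / 1203, length.out = 140))
  master <- spectra_set(mg, nirtransfer:::.interp_rows(clean, dense, mg))
  slave <- spectra_set(sg, nirtransfer:::.interp_rows(clean, dense, sg))
  interp <- interpolate_to_grid(slave, mg)
  expect_lt(max(abs(interp$absorbance - master$absorbance)), 1e-3)
  t <- linear_interp_pds(master[1:12, ], slave[1:12, ], mg, 2, 2)
  tr <- apply_transfer(t, slave[13:24, ])
  expect_lt(sqrt(mean((tr$absorbance - master$absorbance[13:24, ])^2)),
            1e-3)
})

test_that("common wavelength matching is a nearest-first matching", {
  g <- seq(1000, 1010, by = 1)
  same <- common_wavelengths(g, g, 0)
  expect_equal(nrow(same), length(g))
  expect_equal(same$a, same$b)
  expect_equal(nrow(common_wavelengths(c(1000, 1002), 1001, 0)), 0)
  # brute-force oracle on an FT-style grid vs a 1 nm grid
  brute_match <- function(ga, gb, tol) {
    cand <- expand.grid(a = seq_along(ga), b = seq_along(gb))
    cand$d <- abs(ga[cand$a] - gb[cand$b])
    cand <- cand[cand$d <= tol, ]
    cand <- cand[order(cand$d, cand$a, cand$b), ]
    ua <- logical(length(ga)); ub <- logical(length(gb)); k <- 0
    for (r in seq_len(nrow(cand))) {
      if (!ua[cand$a[r]] && !ub[cand$b[r]]) {
        ua[cand$a[r]] <- ub[cand$b[r]] <- TRUE; k <- k + 1
      }
    }
    k
  }
  ga <- seq(1000, 1800, by = 1)
  gb <- sort(1e7 / seq(12000, 5556, length.out = 400))
  gb <- gb[gb >= 1000 & gb <= 1800]
  pairs <- common_wavelengths(ga, gb, 0.5)
  expect_equal(nrow(pairs), brute_match(ga, gb, 0.5))
  expect_true(all(abs(pairs$wavelength_a - pairs$wavelength_b) <= 0.5))
  expect_true(!anyDuplicated(pairs$a) && !anyDuplicated(pairs$b))
})

test_that("transfer models survive a serialization round trip", {
  m <- smooth_spectra(12, seed = 61)
  sl <- spectra_set(m$wavelengths, 1.2 * m$absorbance + 0.1)
  t <- build_pds(m, sl, half_width = 2, n_window_components = 2,
                 intercept = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_transfer_model(t, path)
  t2 <- read_transfer_model(path)
  q <- smooth_spectra(3, seed = 62)
  expect_equal(apply_transfer(t2, q)$absorbance,
               apply_transfer(t, q)$absorbance, tolerance = 1e-10)
  expect_equal(t2$method, t$method)
})
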