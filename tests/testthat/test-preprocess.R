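test_that("moving average matches a direct truncated-window oracle", {
  s <- random_spectra(4, 15, seed = 7)
  for (window in c(1, 2, 3, 4, 7, 15)) {
    out <- moving_average(s, window)
    left <- if (window %% 2 == 0) window / 2 else (window - 1) / 2
    right <- window - 1 - left
    oracle <- s$absorbance
    for (i in seq_len(nrow(oracle))) {
      for (j in seq_len(ncol(oracle))) {
        idx <- max(1, j - left):min(ncol(oracle), j + right)
        oracle[i, j] <- mean(s$absorbance[i, idx])
      }
    }
    expect_equal(out$absorbance, oracle, tolerance = 1e-12,
                 label = paste("window", window))
    expect_equal(out$wavelengths, s$wavelengths)
  }
})

test_that("moving average identity, constant rows, and errors", {
  s <- random_spectra(3, 8)
  expect_equal(moving_average(s, 1)$absorbance, s$absorbance)
  const <- spectra_set(s$wavelengths, matrix(2.5, 2, 8))
  expect_equal(moving_average(const, 5)$absorbance, const$absorbance)
  expect_error(moving_average(s, 0), "window")
  expect_error(moving_average(s, 9), "window")
  # [1,2,4,8] window 3: interior = three-point means
  r <- spectra_set(1:4, matrix(c(1, 2, 4, 8), 1))
  expect_equal(drop(moving_average(r, 3)$absorbance),
               c(1.5, 7 / 3, 14 / 3, 6))
})

test_that("moving average is linear in the spectra", {
  a <- 0.7; b <- -1.3
  X <- random_spectra(5, 12, seed = 1)
  Y <- random_spectra(5, 12, seed = 2)
  mix <- spectra_set(X$wavelengths, a * X$absorbance + b * Y$absorbance)
  expect_equal(moving_average(mix, 4)$absorbance,
               a * moving_average(X, 4)$absorbance +
                 b * moving_average(Y, 4)$absorbance,
               tolerance = 1e-12)
})

test_that("snv standardizes rows and is affine invariant", {
  s <- spectra_set(1:3, matrix(c(1, 2, 3), 1))
  expect_equal(drop(snv(s)$absorbance), c(-1, 0, 1))
  expect_error(snv(spectra_set(1:3, matrix(5, 1, 3), sample_ids = "bad")),
               "bad")
  r <- random_spectra(6, 30, seed = 4)
  out <- snv(r)$absorbance
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_equal(apply(out, 1, stats::sd), rep(1, 6), tolerance = 1e-12)
  shifted <- spectra_set(r$wavelengths, 2.5 * r$absorbance + 7)
  expect_equal(snv(shifted)$absorbance, out, tolerance = 1e-12)
})

test_that("mean normalization scales rows to mean one", {
  s <- spectra_set(1:3, matrix(c(2, 4, 6), 1))
  expect_equal(drop(mean_normalize(s)$absorbance), c(0.5, 1, 1.5))
  unit <- spectra_set(1:3, matrix(c(0.5, 1, 1.5), 1))
  expect_equal(mean_normalize(unit)$absorbance, unit$absorbance)
  r <- random_spectra(5, 10, seed = 5)
  r$absorbance <- r$absorbance + 3   # keep means away from zero
  expect_equal(rowMeans(mean_normalize(r)$absorbance), rep(1, 5),
               tolerance = 1e-12)
  zero <- spectra_set(1:2, matrix(c(-1, 1), 1), sample_ids = "z")
  expect_error(mean_normalize(zero), "z")
})

test_that("plans apply steps in order and preserve shape", {
  s <- random_spectra(4, 20, seed = 6)
  plan <- preprocess_plan(ma(3), "snv")
  out <- apply_plan(s, plan)
  expect_equal(out$absorbance, snv(moving_average(s, 3))$absorbance)
  expect_equal(dim(out$absorbance), dim(s$absorbance))
  expect_equal(out$wavelengths, s$wavelengths)
  expect_error(preprocess_plan("derivative"), "unknown")
  expect_error(preprocess_plan(list(step = "moving_average")), "window")
  expect_identical(apply_plan(s, NULL), s)
})
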