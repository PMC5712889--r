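test_that("evaluation metrics match their definitions", {
  ev <- evaluate(c(2, 3, 4), c(1, 2, 3))
  expect_equal(ev$rmse, 1)
  expect_equal(ev$r2, 1)
  expect_equal(ev$rpd, 1)
  perfect <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_identical(perfect$rpd, Inf)
  set.seed(41)
  p <- rnorm(50, 19, 2); r <- rnorm(50, 19, 2)
  ev2 <- evaluate(p, r)
  expect_equal(ev2$rmse, sqrt(mean((p - r)^2)), tolerance = 1e-12)
  expect_equal(ev2$r2, cor(p, r)^2, tolerance = 1e-12)
  expect_equal(ev2$rpd, sd(r) / ev2$rmse, tolerance = 1e-12)
  perm <- sample(50)
  expect_equal(evaluate(p[perm], r[perm])$rmse, ev2$rmse)
  expect_error(evaluate(1:3, rep(2, 3)), "degenerate")
  expect_error(evaluate(1:3, 1:4), "equal length")
})

test_that("SEL follows the replicate formula", {
  expect_equal(sel(matrix(5, 4, 3)), 0)
  expect_equal(sel(matrix(c(1, 2, 3), 1, 3)), sqrt(2))
  # rows with a single finite replicate are dropped with a warning
  tab <- data.frame(id = c("a", "b"), y1 = c(1, 4), y2 = c(3, NA),
                    y3 = c(NA, NA))
  expect_warning(out <- sel(tab), "excluded")
  expect_equal(out, sqrt(2))  # only row a, deviations (1,3) around 2
  expect_error(sel(matrix(c(1, NA, NA), 1, 3)), "finite")
})

test_that("SEL on simulated replicates matches its analytic expectation", {
  set.seed(42)
  sigma <- 0.3
  sels <- replicate(100, {
    truth <- rnorm(50, 19, 2)
    sel(matrix(truth, 50, 3) + matrix(rnorm(150, 0, sigma), 50, 3))
  })
  expect_lt(abs(mean(sels) - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.1)
})

test_that("Passing-Bablok agrees with exhaustive slope enumeration", {
  set.seed(43)
  x <- rnorm(8, 19, 2)
  y <- 1.1 * x - 1 + rnorm(8, 0, 0.3)
  pb <- suppressWarnings(passing_bablok(x, y))  # n < 10 small-sample note
  ij <- t(combn(8, 2))
  S <- (y[ij[, 2]] - y[ij[, 1]]) / (x[ij[, 2]] - x[ij[, 1]])
  S <- sort(S[S != -1 & is.finite(S)])
  K <- sum(S < -1)
  N <- length(S)
  est <- if (N %% 2 == 1) S[(N + 1) / 2 + K] else
    (S[N / 2 + K] + S[N / 2 + 1 + K]) / 2
  expect_equal(pb$n_slopes, N)
  expect_equal(pb$K, K)
  expect_equal(pb$slope, est, tolerance = 1e-12)
  expect_equal(pb$intercept, median(y - est * x), tolerance = 1e-12)
  expect_lte(pb$slope_ci[1], pb$slope)
  expect_gte(pb$slope_ci[2], pb$slope)
})

test_that("Passing-Bablok decides agreement as specified", {
  set.seed(44)
  x <- rnorm(15, 19, 2)
  id <- passing_bablok(x, x + rnorm(15, 0, 1e-8))
  expect_equal(id$slope, 1, tolerance = 1e-6)
  expect_equal(id$intercept, 0, tolerance = 1e-6)
  expect_true(id$h0_accepted)
  prop <- passing_bablok(x, 2 * x + rnorm(15, 0, 1e-8))
  expect_equal(prop$slope, 2, tolerance = 1e-6)
  expect_false(prop$h0_accepted)
  expect_error(passing_bablok(rep(1, 12), rnorm(12)), "identical")
  expect_warning(passing_bablok(rnorm(5), rnorm(5)), "n >= 10")
})

test_that("swapping the axes inverts the slope on error-free data", {
  set.seed(45)
  x <- sort(rnorm(20, 19, 2))
  y <- 1.4 * x + 2
  expect_equal(passing_bablok(x, y)$slope,
               1 / passing_bablok(y, x)$slope, tolerance = 1e-8)
})

test_that("master choice follows acceptance then slope closeness", {
  pb <- function(slope, ok) {
    structure(list(slope = slope, h0_accepted = ok),
              class = "passing_bablok")
  }
  out <- choose_master(list(A = pb(1.05, TRUE), B = pb(1.0, FALSE)))
  expect_equal(out$instrument, "A")
  expect_false(out$no_acceptable_master)
  out2 <- choose_master(list(A = pb(1.2, FALSE), B = pb(0.5, FALSE)))
  expect_true(out2$no_acceptable_master)
  expect_true(is.na(out2$instrument))
  out3 <- choose_master(list(A = pb(1.01, TRUE), B = pb(1.2, TRUE)))
  expect_equal(out3$instrument, "A")
  expect_error(choose_master(list(pb(1, TRUE))), "named list")
})
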