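test_that("vanishing regularization interpolates the training data", {
  set.seed(31)
  X <- matrix(rnorm(5 * 3), 5, 3)
  y <- rnorm(5, 19, 2)
  m <- lssvm_fit(X, y, gamma = 1e8, sigma2 = 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-4)
})

test_that("the returned solution satisfies its own linear system", {
  set.seed(32)
  X <- matrix(rnorm(8 * 4), 8, 4)
  y <- rnorm(8)
  m <- lssvm_fit(X, y, gamma = 50, sigma2 = 2)
  K <- exp(-as.matrix(dist(X))^2 / 2)
  C <- rbind(c(0, rep(1, 8)), cbind(1, K + diag(1 / 50, 8)))
  resid <- C %*% c(m$b, m$alpha) - c(0, y)
  expect_lt(sqrt(sum(resid^2)), 1e-8 * sqrt(sum(y^2)))
})

test_that("a 6-point instance matches an independent dense solve", {
  set.seed(33)
  X <- matrix(rnorm(6 * 2), 6, 2)
  y <- rnorm(6)
  gamma <- 12; sigma2 <- 0.7
  m <- lssvm_fit(X, y, gamma, sigma2)
  K <- exp(-as.matrix(dist(X))^2 / sigma2)
  sol <- qr.solve(rbind(c(0, rep(1, 6)), cbind(1, K + diag(1 / gamma, 6))),
                  c(0, y))
  expect_equal(m$b, unname(sol[1]), tolerance = 1e-8)
  expect_equal(unname(m$alpha), unname(sol[-1]), tolerance = 1e-8)
})

test_that("closed-form LOOCV equals exhaustive refits", {
  set.seed(34)
  X <- matrix(rnorm(12 * 5), 12, 5)
  y <- rnorm(12, 19, 2)
  for (hp in list(c(10, 1), c(1000, 10), c(5, 100))) {
    expect_equal(lssvm_loocv_mse(X, y, hp[1], hp[2]),
                 lssvm_loocv_mse(X, y, hp[1], hp[2], exact = TRUE),
                 tolerance = 1e-8)
  }
})

test_that("tuning returns the grid argmin and avoids degenerate overfit", {
  set.seed(35)
  X <- matrix(rnorm(10 * 3), 10, 3)
  y <- rnorm(10)
  one <- lssvm_tune(X, y, gamma_grid = 7, sigma2_grid = 0.5)
  expect_equal(one$gamma, 7)
  expect_equal(one$sigma2, 0.5)
  # smooth 1-D relation: the chosen bandwidth should not be the smallest
  picks <- integer(20)
  for (seed in 1:20) {
    set.seed(seed)
    x1 <- sort(runif(20, -2, 2))
    Xs <- cbind(x1, x1^2, rnorm(20, 0, 0.05))
    ys <- sin(x1) + rnorm(20, 0, 0.05)
    tn <- lssvm_tune(Xs, ys, gamma_grid = c(1, 100),
                     sigma2_grid = c(1e-3, 1, 100))
    picks[seed] <- tn$sigma2 == 1e-3
  }
  expect_lt(mean(picks), 0.5)
})

test_that("prediction follows the kernel expansion and decays to the bias", {
  set.seed(36)
  X <- matrix(rnorm(9 * 4), 9, 4)
  y <- rnorm(9, 19, 2)
  m <- lssvm_fit(X, y, 100, 3)
  # training point query equals the training prediction
  K <- exp(-as.matrix(dist(X))^2 / 3)
  expect_equal(predict(m, X), unname(drop(K %*% m$alpha + m$b)),
               tolerance = 1e-10)
  # direct-formula oracle at random queries
  Xq <- matrix(rnorm(4 * 4), 4, 4)
  oracle <- sapply(seq_len(4), function(i) {
    sum(m$alpha * exp(-colSums((t(X) - Xq[i, ])^2) / 3)) + m$b
  })
  expect_equal(predict(m, Xq), oracle, tolerance = 1e-10)
  far <- matrix(100, 1, 4)
  expect_equal(predict(m, far), m$b, tolerance = 1e-8)
  expect_error(predict(m, Xq[, 1:2]), "mismatch")
})

test_that("fitting is invariant to sample order", {
  set.seed(37)
  X <- matrix(rnorm(15 * 4), 15, 4)
  y <- rnorm(15)
  perm <- sample(15)
  m1 <- lssvm_fit(X, y, 30, 2)
  m2 <- lssvm_fit(X[perm, ], y[perm], 30, 2)
  Xq <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(predict(m1, Xq), predict(m2, Xq), tolerance = 1e-8)
})

test_that("parameter validation and training-error monotonicity in gamma", {
  set.seed(38)
  X <- matrix(rnorm(10 * 3), 10, 3)
  y <- rnorm(10)
  expect_error(lssvm_fit(X, y, -1, 1), "gamma")
  expect_error(lssvm_fit(X, y, 1, 0), "sigma2")
  errs <- sapply(c(0.1, 1, 10, 100, 1000), function(g) {
    m <- lssvm_fit(X, y, g, 2)
    mean((predict(m, X) - y)^2)
  })
  expect_true(all(diff(errs) <= 1e-10))
})
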