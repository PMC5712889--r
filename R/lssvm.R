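# Least-squares support vector machine regression with an RBF kernel.
# Training solves the single dual linear system
#   [[0, 1'], [1, K + I/gamma]] [b; alpha] = [0; y],
# K_kl = exp(-||x_k - x_l||^2 / sigma2).

# pairwise squared Euclidean distances between rows of A and rows of B
.sqdist <- function(A, B = A) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

.lssvm_system <- function(K, gamma, y) {
  n <- nrow(K)
  C <- rbind(c(0, rep(1, n)), cbind(1, K + diag(1 / gamma, n)))
  list(C = C, rhs = c(0, y))
}

#' Fit an LS-SVM regression model
#'
#' Solves the LS-SVM dual system for the bias `b` and dual coefficients
#' `alpha` with a radial-basis-function kernel
#' `K(x, z) = exp(-||x - z||^2 / sigma2)`. The regularization `gamma`
#' trades training error against smoothness (large `gamma` interpolates the
#' training data). The solution is refused if the linear system is too
#' ill-conditioned to satisfy its own equations to 1e-8 relative residual.
#'
#' @param X Spectra matrix (samples in rows) or [spectra_set()].
#' @param y Numeric reference vector (taken from `X$reference` when `X` is a
#'   `spectra_set` and `y` is `NULL`).
#' @param gamma Positive regularization constant.
#' @param sigma2 Positive RBF bandwidth (squared length scale).
#' @return An object of class `lssvm_model` holding `alpha`, `b`, `gamma`,
#'   `sigma2`, and the training spectra.
#' @export
lssvm_fit <- function(X, y = NULL, gamma, sigma2) {
  if (inherits(X, "spectra_set")) {
    if (is.null(y)) y <- X$reference
    X <- X$absorbance
  }
  X <- as.matrix(X)
  if (is.null(y) || length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  K <- exp(-.sqdist(X) / sigma2)
  sys <- .lssvm_system(K, gamma, y)
  sol <- tryCatch(solve(sys$C, sys$rhs), error = function(e) {
    stop("LS-SVM system is singular (duplicate samples with very large ",
         "gamma?); increase regularization or remove duplicates")
  })
  resid <- sys$C %*% sol - sys$rhs
  if (sqrt(sum(resid^2)) > 1e-8 * max(1, sqrt(sum(sys$rhs^2)))) {
    stop("LS-SVM system too ill-conditioned (relative residual > 1e-8); ",
         "reduce gamma or deduplicate samples")
  }
  structure(
    list(b = sol[1], alpha = sol[-1], gamma = gamma, sigma2 = sigma2,
         X = X),
    class = "lssvm_model"
  )
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat(sprintf("lssvm_model: n = %d, gamma = %g, sigma2 = %g\n",
              nrow(x$X), x$gamma, x$sigma2))
  invisible(x)
}

#' Predict from an LS-SVM model
#'
#' `yhat(x) = sum_k alpha_k exp(-||x - x_k||^2 / sigma2) + b`. Far from all
#' training samples the kernel terms vanish and predictions tend to `b`.
#'
#' @param object An `lssvm_model`.
#' @param X Query spectra matrix or [spectra_set()] on the training grid.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.lssvm_model <- function(object, X, ...) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X)
  if (ncol(X) != ncol(object$X)) {
    stop("wavelength count mismatch: model has ", ncol(object$X),
         ", input has ", ncol(X))
  }
  Kq <- exp(-.sqdist(X, object$X) / object$sigma2)
  drop(Kq %*% object$alpha + object$b)
}

#' Leave-one-out mean squared error of an LS-SVM parameter pair
#'
#' By default uses the closed-form leave-one-out residual
#' `e_i = alpha_i / (C^-1)_{ii}` (diagonal of the alpha block of the
#' inverted dual system), which is algebraically equal to refitting with
#' sample i held out. `exact = TRUE` performs the n explicit refits; the
#' two routes agree to numerical precision and the test suite asserts it.
#'
#' @param X Spectra matrix; `y` reference vector.
#' @param y Numeric reference vector.
#' @param gamma,sigma2 LS-SVM parameters.
#' @param exact Logical; brute-force refits instead of the algebraic form.
#' @return Mean squared leave-one-out prediction error.
#' @export
lssvm_loocv_mse <- function(X, y, gamma, sigma2, exact = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (exact) {
    err <- vapply(seq_len(n), function(i) {
      m <- lssvm_fit(X[-i, , drop = FALSE], y[-i], gamma, sigma2)
      y[i] - predict(m, X[i, , drop = FALSE])
    }, numeric(1))
    return(mean(err^2))
  }
  K <- exp(-.sqdist(X) / sigma2)
  sys <- .lssvm_system(K, gamma, y)
  Cinv <- solve(sys$C)
  sol <- drop(Cinv %*% sys$rhs)
  alpha <- sol[-1]
  loo_resid <- alpha / diag(Cinv)[-1]
  mean(loo_resid^2)
}

#' Grid-tune LS-SVM parameters by leave-one-out cross-validation
#'
#' Evaluates every `(gamma, sigma2)` pair on the grid and returns the pair
#' with the smallest LOOCV mean squared error (first grid pair on ties,
#' gamma varying fastest). Grid points whose system is numerically singular
#' are skipped; it is an error if all of them fail.
#'
#' @param X Spectra matrix or [spectra_set()].
#' @param y Reference vector.
#' @param gamma_grid,sigma2_grid Positive candidate values (log-spaced grids
#'   are customary; defaults span `10^0..10^6` and `10^-1..10^5`).
#' @return A list with `gamma`, `sigma2`, and the full `cv` table
#'   (data frame of gamma, sigma2, loocv_mse).
#' @export
lssvm_tune <- function(X, y = NULL, gamma_grid = 10^(0:6),
                       sigma2_grid = 10^(-1:5)) {
  if (inherits(X, "spectra_set")) {
    if (is.null(y)) y <- X$reference
    X <- X$absorbance
  }
  X <- as.matrix(X)
  if (length(gamma_grid) < 1 || length(sigma2_grid) < 1) {
    stop("tuning grids must be nonempty")
  }
  D2 <- .sqdist(X)
  n <- nrow(X)
  cv <- expand.grid(gamma = gamma_grid, sigma2 = sigma2_grid)
  cv$loocv_mse <- NA_real_
  for (j in seq_along(sigma2_grid)) {
    K <- exp(-D2 / sigma2_grid[j])
    for (i in seq_along(gamma_grid)) {
      row <- (j - 1L) * length(gamma_grid) + i
      sys <- .lssvm_system(K, gamma_grid[i], y)
      Cinv <- tryCatch(solve(sys$C), error = function(e) NULL)
      if (is.null(Cinv)) next
      sol <- drop(Cinv %*% sys$rhs)
      cv$loocv_mse[row] <- mean((sol[-1] / diag(Cinv)[-1])^2)
    }
  }
  if (all(is.na(cv$loocv_mse))) stop("all tuning grid points failed")
  best <- which.min(cv$loocv_mse)
  list(gamma = cv$gamma[best], sigma2 = cv$sigma2[best], cv = cv)
}
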