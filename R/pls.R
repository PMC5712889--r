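# NIPALS PLS1. The same core serves the calibration models (centred, with
# PRESS-based component selection) and the per-channel transfer regressions
# in PDS (optionally uncentred so the transfer has no additive term).

# Returns the coefficient path B (p x a): column k holds the regression
# vector using k latent components, for the model y ~ (x - x_mean) B + y_mean.
.pls1 <- function(X, y, ncomp, center = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (center) {
    xm <- colMeans(X); ym <- mean(y)
    Xd <- sweep(X, 2, xm); yd <- y - ym
  } else {
    xm <- rep(0, p); ym <- 0
    Xd <- X; yd <- y
  }
  A <- max(1L, min(ncomp, p, n - as.integer(center)))
  W <- P <- matrix(0, p, A)
  qv <- numeric(A)
  a <- 0L
  for (k in seq_len(A)) {
    w <- crossprod(Xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-300) break
    w <- w / wn
    tt_vec <- Xd %*% w
    tt <- sum(tt_vec^2)
    if (tt < 1e-300) break
    q <- sum(tt_vec * yd) / tt
    pv <- crossprod(Xd, tt_vec) / tt
    Xd <- Xd - tt_vec %*% t(pv)
    yd <- yd - q * tt_vec
    W[, k] <- w; P[, k] <- pv; qv[k] <- q
    a <- k
  }
  B <- matrix(0, p, a)
  for (k in seq_len(a)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    B[, k] <- Wk %*% solve(crossprod(Pk, Wk), qv[seq_len(k)])
  }
  list(coef_path = B, ncomp = a, x_mean = xm, y_mean = ym)
}

# First local minimum of a PRESS curve: the smallest component count whose
# PRESS is below both neighbours (endpoints compare on the available side);
# falls back to the global minimum when no interior minimum exists.
.first_press_min <- function(press) {
  A <- length(press)
  if (A == 1) return(1L)
  for (k in seq_len(A)) {
    ok_left <- k == 1 || press[k] < press[k - 1]
    ok_right <- k == A || press[k] < press[k + 1]
    if (ok_left && ok_right) return(as.integer(k))
  }
  as.integer(which.min(press))
}

#' Fit a PLS1 calibration model
#'
#' NIPALS partial least squares on mean-centred data. The number of latent
#' components is chosen from the cross-validated PRESS curve (prediction
#' residual error sum of squares): the first local minimum, i.e. the
#' smallest component count whose PRESS is below both neighbours, falling
#' back to the global minimum when the curve is monotone. Cross-validation
#' uses contiguous blocks.
#'
#' @param X Numeric matrix of spectra (samples in rows), or a
#'   [spectra_set()].
#' @param y Numeric reference vector.
#' @param max_components Largest component count to consider; silently
#'   clipped to what the data and folds support (with a warning).
#' @param cv_folds Number of contiguous cross-validation blocks.
#' @return An object of class `pls_model` with elements `n_components`,
#'   `coefficients`, `x_mean`, `y_mean`, `press`, `coef_path`.
#' @export
pls_fit <- function(X, y, max_components = 15, cv_folds = 10) {
  if (inherits(X, "spectra_set")) {
    if (is.null(y)) y <- X$reference
    X <- X$absorbance
  }
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (stats::sd(y) == 0) stop("degenerate target: y is constant")
  if (cv_folds < 2 || cv_folds > n) stop("cv_folds must be in [2, n]")
  fold <- as.integer(cut(seq_len(n), breaks = cv_folds, labels = FALSE))
  min_train <- n - max(tabulate(fold))
  A <- min(max_components, p, min_train - 1L)
  if (A < 1) stop("too few samples for cross-validation")
  if (A < max_components) {
    warning("max_components clipped to ", A)
  }
  press <- numeric(A)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    fit <- .pls1(X[tr, , drop = FALSE], y[tr], A)
    pred <- sweep(X[!tr, , drop = FALSE], 2, fit$x_mean) %*% fit$coef_path +
      fit$y_mean
    if (fit$ncomp < A) {
      pred <- cbind(pred, matrix(pred[, fit$ncomp],
                                 nrow(pred), A - fit$ncomp))
    }
    press <- press + colSums((pred - y[!tr])^2)
  }
  ncomp <- .first_press_min(press)
  fit <- .pls1(X, y, ncomp)
  ncomp <- min(ncomp, fit$ncomp)
  structure(
    list(n_components = ncomp,
         coefficients = fit$coef_path[, ncomp],
         x_mean = fit$x_mean, y_mean = fit$y_mean,
         press = press, coef_path = fit$coef_path,
         n_train = n),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent components, %d wavelengths, n = %d\n",
              x$n_components, length(x$coefficients), x$n_train))
  invisible(x)
}

#' Predict from a PLS model
#'
#' Computes `(X - x_mean) %*% beta + y_mean`.
#'
#' @param object A `pls_model`.
#' @param X Spectra matrix or [spectra_set()] on the training grid.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, X, ...) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X)
  if (ncol(X) != length(object$coefficients)) {
    stop("wavelength count mismatch: model has ",
         length(object$coefficients), ", input has ", ncol(X))
  }
  drop(sweep(X, 2, object$x_mean) %*% object$coefficients + object$y_mean)
}
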