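#' Evaluate predictions against reference values
#'
#' Computes the standard NIR calibration metrics: root mean squared error
#' (RMSEC/RMSEP depending on the set), the determination coefficient R^2
#' defined as the squared Pearson correlation between predictions and
#' reference, and RPD, the ratio of the reference standard deviation (n - 1
#' denominator) to the RMSE. An RPD above 2 conventionally indicates a
#' useful calibration.
#'
#' @param predictions,reference Numeric vectors of equal length (>= 2).
#' @param label Name of the evaluated set (e.g. `"calibration"`).
#' @return An object of class `evaluation_report` with `r2`, `rmse`, `rpd`,
#'   `n`, `label`. A perfect fit reports `rmse = 0` and `rpd = Inf`.
#' @export
evaluate <- function(predictions, reference, label = "set") {
  if (length(predictions) != length(reference)) {
    stop("predictions and reference must have equal length")
  }
  n <- length(reference)
  if (n < 2) stop("need at least 2 samples")
  if (stats::sd(reference) == 0) {
    stop("degenerate reference: zero variance")
  }
  rmse <- sqrt(mean((predictions - reference)^2))
  r2 <- if (stats::sd(predictions) == 0 && rmse > 0) {
    0
  } else if (rmse == 0) {
    1
  } else {
    stats::cor(predictions, reference)^2
  }
  rpd <- if (rmse > 0) stats::sd(reference) / rmse else Inf
  structure(list(r2 = r2, rmse = rmse, rpd = rpd, n = n, label = label),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s (n = %d): R2 = %.3f, RMSE = %.3f, RPD = %.3f\n",
              x$label, x$n, x$r2, x$rmse, x$rpd))
  invisible(x)
}

#' Standard error of laboratory from replicate measurements
#'
#' `SEL = sqrt( sum_samples sum_reps (y_r - ybar)^2 / N )` where `ybar` is
#' the per-sample replicate mean and `N` the number of samples. SEL is the
#' replicate-based error of the reference method itself and a lower bound
#' on the RMSE any calibration can honestly reach.
#'
#' Rows with fewer than two finite replicates carry no spread information
#' and are excluded with a warning.
#'
#' @param replicates A data frame with a sample-id column `id` (optional)
#'   and one numeric column per replicate, as produced by
#'   [read_replicates()], or a numeric matrix of replicates.
#' @return The SEL (same units as the replicates).
#' @export
sel <- function(replicates) {
  if (is.data.frame(replicates)) {
    replicates <- replicates[setdiff(names(replicates), "id")]
  }
  Y <- as.matrix(replicates)
  storage.mode(Y) <- "double"
  ok <- rowSums(is.finite(Y)) >= 2
  if (!any(ok)) stop("no sample has >= 2 finite replicates")
  if (!all(ok)) {
    warning(sum(!ok), " sample(s) with < 2 finite replicates excluded")
    Y <- Y[ok, , drop = FALSE]
  }
  dev2 <- apply(Y, 1, function(r) {
    r <- r[is.finite(r)]
    sum((r - mean(r))^2)
  })
  sqrt(sum(dev2) / nrow(Y))
}

#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression for comparing two measurement methods, robust
#' to errors in both variables. The slope is the shifted median of all
#' pairwise slopes `S_ij = (y_j - y_i)/(x_j - x_i)` (pairs with equal x are
#' skipped; slopes exactly -1 are excluded; the shift K counts slopes below
#' -1). Confidence bounds come from the rank positions given by the normal
#' approximation with variance `n (n - 1) (2 n + 5) / 18`. The intercept is
#' `median(y - slope x)` with its CI evaluated at the slope CI endpoints.
#' H0 (the methods agree) is accepted when the slope CI contains 1 and the
#' intercept CI contains 0.
#'
#' @param x,y Paired measurements from the two methods.
#' @param confidence Confidence level (default 0.95).
#' @return An object of class `passing_bablok`: slope and intercept
#'   estimates with CIs, `n_slopes` (valid pairwise slopes), `K` (offset),
#'   and `h0_accepted`.
#' @export
passing_bablok <- function(x, y, confidence = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (n < 10) warning("Passing-Bablok is recommended for n >= 10")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  if (all(dx == 0)) stop("undefined slope: all x values identical")
  S <- dy[dx != 0] / dx[dx != 0]
  S <- S[S != -1]
  if (length(S) == 0) stop("no valid pairwise slopes")
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  pick <- function(idx) S[min(max(idx, 1L), N)]
  slope <- if (N %% 2 == 1) {
    pick((N + 1) %/% 2 + K)
  } else {
    (pick(N %/% 2 + K) + pick(N %/% 2 + 1L + K)) / 2
  }
  w <- stats::qnorm(1 - (1 - confidence) / 2)
  Cq <- w * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - Cq) / 2)
  M2 <- N - M1 + 1
  slope_lo <- pick(M1 + K)
  slope_hi <- pick(M2 + K)
  intercept <- stats::median(y - slope * x)
  int_lo <- stats::median(y - slope_hi * x)
  int_hi <- stats::median(y - slope_lo * x)
  h0 <- (slope_lo <= 1 && 1 <= slope_hi) && (int_lo <= 0 && 0 <= int_hi)
  structure(
    list(slope = slope, slope_ci = c(slope_lo, slope_hi),
         intercept = intercept, intercept_ci = c(int_lo, int_hi),
         n = n, n_slopes = N, K = K, confidence = confidence,
         h0_accepted = h0),
    class = "passing_bablok"
  )
}

#' @export
print.passing_bablok <- function(x, ...) {
  cat(sprintf(paste0(
    "Passing-Bablok (n = %d, %.0f%% CI)\n",
    "  slope:     %.4f [%.4f, %.4f]\n",
    "  intercept: %.4f [%.4f, %.4f]\n",
    "  H0 (slope = 1, intercept = 0): %s\n"),
    x$n, 100 * x$confidence,
    x$slope, x$slope_ci[1], x$slope_ci[2],
    x$intercept, x$intercept_ci[1], x$intercept_ci[2],
    if (x$h0_accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Choose the master instrument from Passing-Bablok comparisons
#'
#' Given one Passing-Bablok result per candidate instrument (each
#' comparing that instrument's predictions against the same reference
#' values), returns the instrument whose H0 is accepted; among several
#' accepted, the one whose slope is closest to 1 (first on ties). When no
#' instrument is acceptable the result carries a `no_acceptable_master`
#' flag and an `NA` instrument.
#'
#' @param results Named list of [passing_bablok()] results (>= 2 entries).
#' @return A list with `instrument` (name or `NA`), `no_acceptable_master`
#'   (logical), and the input `results`.
#' @export
choose_master <- function(results) {
  if (length(results) < 2 || is.null(names(results))) {
    stop("need a named list of >= 2 Passing-Bablok results")
  }
  accepted <- vapply(results, function(r) isTRUE(r$h0_accepted), logical(1))
  if (!any(accepted)) {
    return(list(instrument = NA_character_, no_acceptable_master = TRUE,
                results = results))
  }
  cand <- names(results)[accepted]
  dev <- vapply(results[accepted], function(r) abs(r$slope - 1), numeric(1))
  list(instrument = cand[which.min(dev)], no_acceptable_master = FALSE,
       results = results)
}
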