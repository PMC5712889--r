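#' Moving-average smoothing
#'
#' Replaces each spectrum by a centred moving mean over `window` channels.
#' At the spectrum edges the window truncates to the available points, so no
#' out-of-range absorbance is fabricated and the grid length is unchanged.
#' An even window is centred with one extra point on the left (window 18 =
#' 9 left + current + 8 right), so the even smoothing widths customary for
#' Fourier-transform spectra are representable.
#'
#' @param s A [spectra_set()].
#' @param window Window width in channels, `1 <= window <= n_wavelengths`.
#' @return A smoothed `spectra_set` on the same grid.
#' @export
moving_average <- function(s, window) {
  stopifnot(inherits(s, "spectra_set"))
  p <- n_wavelengths(s)
  window <- as.integer(window)
  if (length(window) != 1 || is.na(window) || window < 1 || window > p) {
    stop("window must be an integer in [1, n_wavelengths]")
  }
  if (window == 1) return(s)
  left <- if (window %% 2 == 0) window %/% 2 else (window - 1L) %/% 2
  right <- window - 1L - left
  A <- s$absorbance
  cs <- cbind(0, t(apply(A, 1, cumsum)))            # n x (p+1) running sums
  lo <- pmax(seq_len(p) - left, 1L)
  hi <- pmin(seq_len(p) + right, p)
  sums <- cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
  out <- sweep(sums, 2, hi - lo + 1, "/")
  spectra_set(s$wavelengths, out, s$sample_ids, s$reference)
}

#' Standard normal variate
#'
#' Centres and scales each spectrum to mean 0 and standard deviation 1
#' (n - 1 denominator), removing per-sample additive offsets and
#' multiplicative scatter/particle-size effects. A spectrum with zero
#' variance cannot be scaled and raises an error naming the sample.
#'
#' @param s A [spectra_set()].
#' @return The transformed `spectra_set`.
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  A <- s$absorbance
  m <- rowMeans(A)
  sd_ <- sqrt(rowSums((A - m)^2) / (ncol(A) - 1))
  if (any(sd_ == 0)) {
    stop("SNV undefined for constant spectra: sample(s) ",
         paste(s$sample_ids[sd_ == 0], collapse = ", "))
  }
  spectra_set(s$wavelengths, (A - m) / sd_, s$sample_ids, s$reference)
}

#' Mean normalization
#'
#' Divides each spectrum by its own mean so that spectra from instruments
#' with different overall response levels end up on approximately the same
#' scale (post-transform every row has mean exactly 1).
#'
#' @param s A [spectra_set()].
#' @return The normalized `spectra_set`.
#' @export
mean_normalize <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  m <- rowMeans(s$absorbance)
  if (any(m == 0)) {
    stop("mean normalization undefined for zero-mean spectra: sample(s) ",
         paste(s$sample_ids[m == 0], collapse = ", "))
  }
  spectra_set(s$wavelengths, s$absorbance / m, s$sample_ids, s$reference)
}

#' Ordered preprocessing plan
#'
#' A plan is an ordered list of pretreatment steps, each one of
#' `moving_average` (with a `window`), `snv`, or `mean_normalize`, applied
#' left to right by [apply_plan()]. Plans are plain lists so they serialize
#' naturally to YAML/JSON run configs.
#'
#' @param ... Steps: either the strings `"snv"` / `"mean_normalize"`, or
#'   `list(step = "moving_average", window = w)`. The shorthand `ma(w)` from
#'   this package builds the latter.
#' @return An object of class `preprocess_plan`.
#' @examples
#' plan <- preprocess_plan(ma(3), "snv")
#' @export
preprocess_plan <- function(...) {
  steps <- lapply(list(...), function(st) {
    if (is.character(st)) st <- list(step = st)
    if (!is.list(st) || is.null(st$step)) stop("malformed preprocessing step")
    if (!st$step %in% c("moving_average", "snv", "mean_normalize")) {
      stop("unknown preprocessing step: ", st$step)
    }
    if (st$step == "moving_average" && is.null(st$window)) {
      stop("moving_average step needs a window")
    }
    st
  })
  structure(steps, class = "preprocess_plan")
}

#' @rdname preprocess_plan
#' @param window Window width in channels.
#' @export
ma <- function(window) list(step = "moving_average", window = window)

#' Apply a preprocessing plan
#'
#' @param s A [spectra_set()].
#' @param plan A [preprocess_plan()] (or a bare list of steps).
#' @return The pretreated `spectra_set`.
#' @export
apply_plan <- function(s, plan) {
  if (is.null(plan)) return(s)
  for (st in plan) {
    s <- switch(st$step,
      moving_average = moving_average(s, st$window),
      snv = snv(s),
      mean_normalize = mean_normalize(s),
      stop("unknown preprocessing step: ", st$step)
    )
  }
  s
}
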