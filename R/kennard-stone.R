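#' Kennard-Stone sample selection
#'
#' Deterministic max-min selection on Euclidean distances between spectra.
#' The first two picks are the globally farthest pair; every subsequent pick
#' maximizes its minimum distance to the already-selected set. Ties are
#' broken by the smallest index at every argmax, which makes the selection
#' fully reproducible.
#'
#' @param s A [spectra_set()] or a numeric matrix (samples in rows).
#' @param n_select Number of samples to select, `2 <= n_select <= n`.
#' @return An object of class `ks_selection`: a list with `selected`
#'   (indices in selection order) and `remaining` (the rest, in original
#'   order).
#' @export
kennard_stone <- function(s, n_select) {
  X <- if (inherits(s, "spectra_set")) s$absorbance else as.matrix(s)
  n <- nrow(X)
  n_select <- as.integer(n_select)
  if (length(n_select) != 1 || is.na(n_select) ||
      n_select < 2 || n_select > n) {
    stop("n_select must be an integer in [2, n_samples]")
  }
  D <- as.matrix(stats::dist(X))
  # globally farthest pair; smallest (i, j) with i < j on ties
  hits <- which(D == max(D), arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  sel <- as.integer(hits[1, ])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_select) {
    nxt <- as.integer(which.max(mind))     # first max = smallest index
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  structure(list(selected = unname(sel),
                 remaining = setdiff(seq_len(n), sel)),
            class = "ks_selection")
}

#' @export
print.ks_selection <- function(x, ...) {
  cat(sprintf("ks_selection: %d selected, %d remaining\n",
              length(x$selected), length(x$remaining)))
  invisible(x)
}

#' Kennard-Stone calibration/prediction split
#'
#' Splits a spectra set into a Kennard-Stone-selected calibration set and a
#' prediction set made of the remaining samples; reference values travel
#' with their samples.
#'
#' @param s A [spectra_set()].
#' @param n_calibration Calibration-set size, `2 <= n_calibration < n`.
#' @return A list with `calibration` and `prediction` (`spectra_set`s) and
#'   the underlying `selection`.
#' @export
ks_split <- function(s, n_calibration) {
  stopifnot(inherits(s, "spectra_set"))
  if (n_calibration >= n_samples(s)) {
    stop("n_calibration must be smaller than n_samples")
  }
  sel <- kennard_stone(s, n_calibration)
  list(calibration = s[sel$selected, ],
       prediction = s[sel$remaining, ],
       selection = sel)
}

#' Select standardization (transfer standard) samples
#'
#' Kennard-Stone subset of the calibration set, used as the transfer
#' standard set measured on both instruments.
#'
#' @param calibration A [spectra_set()] (the calibration set).
#' @param n_std Number of standardization samples.
#' @return A `ks_selection` with indices into the calibration set.
#' @export
select_standardization <- function(calibration, n_std) {
  kennard_stone(calibration, n_std)
}
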