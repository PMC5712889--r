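# Calibration transfer: linear-interpolation wavelength correction,
# piecewise direct standardization (PDS), their combination, and the
# common-wavelengths-reserved baseline.

# Piecewise-linear resampling of the rows of Y (on strictly increasing grid
# g) at query wavelengths q. Queries coinciding with a grid node return the
# stored value bit-for-bit. Queries outside [min(g), max(g)] are an error.
.interp_rows <- function(Y, g, q) {
  p <- length(g)
  bad <- q < g[1] | q > g[p]
  if (any(bad)) {
    stop("extrapolation requested at wavelength(s): ",
         paste(utils::head(signif(q[bad], 8), 5), collapse = ", "),
         if (sum(bad) > 5) " ..." else "")
  }
  idx <- findInterval(q, g)
  exact <- g[idx] == q
  i2 <- pmin(idx + 1L, p)
  tfrac <- ifelse(exact, 0, (q - g[idx]) / (g[i2] - g[idx]))
  n <- nrow(Y)
  Tm <- matrix(tfrac, n, length(q), byrow = TRUE)
  out <- Y[, idx, drop = FALSE] * (1 - Tm) + Y[, i2, drop = FALSE] * Tm
  if (any(exact)) out[, exact] <- Y[, idx[exact], drop = FALSE]
  out
}

#' Map between a slave and a master wavelength grid
#'
#' For every master wavelength `c` inside the slave grid span, records the
#' bracketing adjacent slave wavelengths `i <= c <= j`. The per-sample
#' interpolation rule is the two-point line through the responses at `i`
#' and `j`: `Slope_c = (y_j - y_i) / (lambda_j - lambda_i)` and
#' `y_c = y_i + Slope_c (c - lambda_i)`.
#'
#' @param slave_grid,master_grid Strictly increasing nm vectors; the master
#'   grid must lie inside the slave grid span.
#' @return A data frame with columns `wavelength`, `lower`, `upper` (slave
#'   channel indices; equal when `c` is itself a slave node).
#' @export
interpolation_map <- function(slave_grid, master_grid) {
  p <- length(slave_grid)
  if (any(master_grid < slave_grid[1] | master_grid > slave_grid[p])) {
    stop("master grid extends beyond the slave grid span")
  }
  idx <- findInterval(master_grid, slave_grid)
  exact <- slave_grid[idx] == master_grid
  data.frame(wavelength = master_grid,
             lower = idx,
             upper = ifelse(exact, idx, pmin(idx + 1L, p)))
}

#' Resample spectra onto a target wavelength grid by linear interpolation
#'
#' Wavelength correction for transfer between instruments with different
#' grids: each sample's response at a master wavelength `c` is computed
#' from the line through the two bracketing slave channels (see
#' [interpolation_map()]). Node queries are returned unchanged; requests
#' outside the slave span raise an error listing the offending
#' wavelengths.
#'
#' @param slave A [spectra_set()].
#' @param master_grid Target nm vector inside the slave grid span.
#' @return A `spectra_set` on `master_grid`.
#' @export
interpolate_to_grid <- function(slave, master_grid) {
  stopifnot(inherits(slave, "spectra_set"))
  out <- .interp_rows(slave$absorbance, slave$wavelengths, master_grid)
  spectra_set(master_grid, out, slave$sample_ids, slave$reference)
}

# Shared PDS core: per master channel i, regress the master standards'
# column i on the slave standards' window [i - hw, i + hw] (clipped at the
# edges) with a low-rank PLS; collect the window coefficient vectors.
.pds_core <- function(Mm, Ms, half_width, ncomp, intercept) {
  p <- ncol(Mm)
  if (ncol(Ms) != p) stop("master and slave standards differ in channels")
  if (nrow(Mm) != nrow(Ms)) stop("standard sets differ in sample count")
  if (nrow(Mm) < 3) stop("need at least 3 standardization samples")
  if (half_width < 0) stop("half_width must be >= 0")
  coefs <- vector("list", p)
  starts <- integer(p)
  intercepts <- numeric(p)
  for (i in seq_len(p)) {
    cols <- max(1L, i - half_width):min(p, i + half_width)
    nc <- min(ncomp, length(cols))
    fit <- tryCatch(
      .pls1(Ms[, cols, drop = FALSE], Mm[, i], nc, center = intercept),
      error = function(e) stop("window PLS failed at channel ", i, ": ",
                               conditionMessage(e)))
    b <- fit$coef_path[, fit$ncomp]
    if (any(!is.finite(b))) stop("non-finite coefficients at channel ", i)
    coefs[[i]] <- b
    starts[i] <- cols[1]
    intercepts[i] <- if (intercept) {
      fit$y_mean - sum(fit$x_mean * b)
    } else 0
  }
  list(coefs = coefs, starts = starts,
       intercepts = if (intercept) intercepts else NULL)
}

.new_transfer_model <- function(method, master_grid, slave_grid, core = NULL,
                                half_width = NULL, ncomp = NULL,
                                slave_cols = NULL) {
  structure(
    list(method = method, master_grid = master_grid, slave_grid = slave_grid,
         half_width = half_width, n_window_components = ncomp,
         coefs = core$coefs, window_starts = core$starts,
         intercepts = core$intercepts, slave_cols = slave_cols),
    class = "transfer_model"
  )
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf("transfer_model: method = %s, %d master channels%s\n",
              x$method, length(x$master_grid),
              if (is.null(x$half_width)) "" else
                sprintf(", half-width = %d", x$half_width)))
  invisible(x)
}

#' Build a piecewise direct standardization model
#'
#' Both standard sets must share sample order and the same channel count
#' (the slave standards already resampled to the master grid; see
#' [linear_interp_pds()] for the one-call combination). For each master
#' channel `i` the master standards' column `i` is regressed on the slave
#' standards' window of `2 half_width + 1` channels centred on `i`
#' (clipped at the grid edges, so all channels are kept), using a PLS with
#' `n_window_components` latent variables (clipped to the window size).
#' The window vectors assemble into the banded transformation matrix `F`
#' (see [pds_matrix()]); transfer is `X_slave F`.
#'
#' By default the per-channel regressions are computed without centring, so
#' the transfer has no additive term (scatter-corrected spectra carry no
#' offsets); `intercept = TRUE` adds a per-channel additive correction.
#'
#' @param master_std,slave_std_on_master_grid Standard-set [spectra_set()]s
#'   with identical grids and sample order.
#' @param half_width Window half-width in channels (0 = single channel).
#' @param n_window_components PLS components per window (default 2).
#' @param intercept Include a per-channel additive term.
#' @return A `transfer_model` with method `"pds"`.
#' @export
build_pds <- function(master_std, slave_std_on_master_grid, half_width,
                      n_window_components = 2, intercept = FALSE) {
  m <- master_std; sl <- slave_std_on_master_grid
  stopifnot(inherits(m, "spectra_set"), inherits(sl, "spectra_set"))
  if (!isTRUE(all.equal(m$wavelengths, sl$wavelengths))) {
    stop("standard sets must share the master grid; interpolate first")
  }
  half_width <- as.integer(half_width)
  core <- .pds_core(m$absorbance, sl$absorbance, half_width,
                    n_window_components, intercept)
  .new_transfer_model("pds", m$wavelengths, sl$wavelengths, core,
                      half_width, n_window_components)
}

#' Linear interpolation-PDS transfer
#'
#' The combined transfer for instruments with different wavelength grids:
#' the slave standards are first resampled onto the master grid by
#' two-point linear interpolation ([interpolate_to_grid()]), then a PDS
#' model is built between the resampled slave standards and the master
#' standards. The resulting model consumes raw slave spectra on the
#' original slave grid.
#'
#' @param master_std Master-instrument standard set.
#' @param slave_std Slave-instrument standard set (same samples, own grid).
#' @param master_grid Target grid; defaults to the master standards' grid.
#' @param half_width,n_window_components,intercept As in [build_pds()].
#' @return A `transfer_model` with method `"linear_interp_pds"`.
#' @export
linear_interp_pds <- function(master_std, slave_std, master_grid = NULL,
                              half_width = 5, n_window_components = 2,
                              intercept = FALSE) {
  stopifnot(inherits(master_std, "spectra_set"),
            inherits(slave_std, "spectra_set"))
  if (is.null(master_grid)) master_grid <- master_std$wavelengths
  sl_i <- interpolate_to_grid(slave_std, master_grid)
  half_width <- as.integer(half_width)
  core <- .pds_core(master_std$absorbance, sl_i$absorbance, half_width,
                    n_window_components, intercept)
  .new_transfer_model("linear_interp_pds", master_grid,
                      slave_std$wavelengths, core, half_width,
                      n_window_components)
}

#' Interpolation-only transfer (wavelength correction without PDS)
#'
#' Resamples slave spectra onto the master grid and stops there: no
#' photometric correction. Useful as the untransferred baseline when
#' comparing transfer methods across instruments with different grids.
#'
#' @param slave_grid,master_grid Instrument grids (master inside slave span).
#' @return A `transfer_model` with method `"interp_only"`.
#' @export
interp_only_transfer <- function(slave_grid, master_grid) {
  interpolation_map(slave_grid, master_grid)  # validates the span
  .new_transfer_model("interp_only", master_grid, slave_grid)
}

#' Match common wavelengths of two grids
#'
#' Greedy nearest-first matching: candidate pairs with
#' `|gridA[a] - gridB[b]| <= tolerance` are taken in order of increasing
#' discrepancy, each wavelength used at most once. An empty result is
#' allowed.
#'
#' @param gridA,gridB Strictly increasing nm vectors.
#' @param tolerance Maximum nm discrepancy for a match (>= 0).
#' @return A data frame with columns `a`, `b` (channel indices into the two
#'   grids, ordered by `a`), `wavelength_a`, `wavelength_b`.
#' @export
common_wavelengths <- function(gridA, gridB, tolerance) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  # for each a, only the bracketing b channels can be nearest
  idx <- findInterval(gridA, gridB)
  cand_b <- cbind(pmax(idx, 1L), pmin(idx + 1L, length(gridB)))
  pairs <- data.frame(
    a = rep(seq_along(gridA), 2),
    b = c(cand_b[, 1], cand_b[, 2])
  )
  pairs <- unique(pairs)
  pairs$d <- abs(gridA[pairs$a] - gridB[pairs$b])
  pairs <- pairs[pairs$d <= tolerance, , drop = FALSE]
  pairs <- pairs[order(pairs$d, pairs$a, pairs$b), , drop = FALSE]
  used_a <- logical(length(gridA))
  used_b <- logical(length(gridB))
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    if (!used_a[a] && !used_b[b]) {
      keep[r] <- TRUE
      used_a[a] <- TRUE
      used_b[b] <- TRUE
    }
  }
  out <- pairs[keep, c("a", "b"), drop = FALSE]
  out <- out[order(out$a), , drop = FALSE]
  rownames(out) <- NULL
  out$wavelength_a <- gridA[out$a]
  out$wavelength_b <- gridB[out$b]
  out
}

#' Common-wavelengths-reserved PDS
#'
#' The traditional baseline for instruments with different grids: only the
#' wavelength channels the two instruments (approximately) share are kept,
#' and PDS is built between the reserved slave channels and the reserved
#' master channels, discarding the rest of the spectrum.
#'
#' @param master_std,slave_std Standard sets on their own grids.
#' @param tolerance Matching tolerance in nm (see [common_wavelengths()]).
#' @param half_width,n_window_components,intercept As in [build_pds()].
#' @return A `transfer_model` with method `"common_pds"`; its `master_grid`
#'   is the reserved master wavelengths and `slave_cols` records the
#'   reserved slave channels.
#' @export
common_pds <- function(master_std, slave_std, tolerance, half_width,
                       n_window_components = 2, intercept = FALSE) {
  stopifnot(inherits(master_std, "spectra_set"),
            inherits(slave_std, "spectra_set"))
  pairs <- common_wavelengths(master_std$wavelengths, slave_std$wavelengths,
                              tolerance)
  if (nrow(pairs) < 2 * half_width + 1) {
    stop("too few common wavelengths (", nrow(pairs), ") for half_width ",
         half_width)
  }
  half_width <- as.integer(half_width)
  core <- .pds_core(master_std$absorbance[, pairs$a, drop = FALSE],
                    slave_std$absorbance[, pairs$b, drop = FALSE],
                    half_width, n_window_components, intercept)
  .new_transfer_model("common_pds", master_std$wavelengths[pairs$a],
                      slave_std$wavelengths, core, half_width,
                      n_window_components, slave_cols = pairs$b)
}

#' Apply a transfer model to slave spectra
#'
#' Maps raw slave spectra into the master instrument's response space. For
#' `linear_interp_pds` the spectra are first resampled to the master grid
#' and then pushed through the banded PDS matrix; for `common_pds` the
#' reserved slave channels are extracted and transformed; for
#' `interp_only` the resampling alone is applied; a plain `pds` model
#' expects input already on the master grid.
#'
#' @param t A `transfer_model`.
#' @param slave A [spectra_set()] on the grid the model was built from.
#' @return A `spectra_set` on the model's master grid.
#' @export
apply_transfer <- function(t, slave) {
  stopifnot(inherits(t, "transfer_model"), inherits(slave, "spectra_set"))
  if (!isTRUE(all.equal(slave$wavelengths, t$slave_grid))) {
    stop("slave grid does not match the grid the model was built from")
  }
  S <- switch(t$method,
    interp_only = ,
    linear_interp_pds = .interp_rows(slave$absorbance, slave$wavelengths,
                                     t$master_grid),
    common_pds = slave$absorbance[, t$slave_cols, drop = FALSE],
    pds = slave$absorbance,
    stop("unknown transfer method: ", t$method)
  )
  if (t$method != "interp_only") {
    p <- length(t$master_grid)
    out <- matrix(0, nrow(S), p)
    for (i in seq_len(p)) {
      b <- t$coefs[[i]]
      cols <- t$window_starts[i] + seq_along(b) - 1L
      out[, i] <- S[, cols, drop = FALSE] %*% b
    }
    if (!is.null(t$intercepts)) out <- sweep(out, 2, t$intercepts, "+")
    S <- out
  }
  spectra_set(t$master_grid, S, slave$sample_ids, slave$reference)
}

#' Dense PDS transformation matrix
#'
#' Assembles the banded matrix `F` whose column `i` carries the window
#' regression vector `b_i` in the rows of its window (all other entries
#' zero), so that transfer is the matrix product `X_slave F`. Mainly for
#' inspection and testing; [apply_transfer()] uses the band directly.
#'
#' @param t A `transfer_model` with a PDS component.
#' @return A square numeric matrix of dimension `length(master_grid)`.
#' @export
pds_matrix <- function(t) {
  stopifnot(inherits(t, "transfer_model"))
  if (t$method == "interp_only") stop("interp_only model has no PDS matrix")
  p <- length(t$master_grid)
  F_ <- matrix(0, p, p)
  for (i in seq_len(p)) {
    b <- t$coefs[[i]]
    rows <- t$window_starts[i] + seq_along(b) - 1L
    F_[rows, i] <- b
  }
  F_
}

#' Serialize / restore a transfer model
#'
#' Writes the full model (grids, band structure, coefficient vectors,
#' method tag) to a portable JSON text file and reads it back.
#'
#' @param t A `transfer_model`.
#' @param path File path.
#' @return `write_transfer_model` returns `path` invisibly;
#'   `read_transfer_model` returns the restored `transfer_model`.
#' @export
write_transfer_model <- function(t, path) {
  stopifnot(inherits(t, "transfer_model"))
  jsonlite::write_json(unclass(t), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_transfer_model
#' @export
read_transfer_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.matrix(obj$coefs)) {
    obj$coefs <- lapply(seq_len(nrow(obj$coefs)),
                        function(i) as.numeric(obj$coefs[i, ]))
  } else {
    obj$coefs <- lapply(obj$coefs, as.numeric)
  }
  for (f in c("master_grid", "slave_grid", "intercepts")) {
    if (!is.null(obj[[f]])) obj[[f]] <- as.numeric(obj[[f]])
  }
  for (f in c("window_starts", "slave_cols", "half_width",
              "n_window_components")) {
    if (!is.null(obj[[f]])) obj[[f]] <- as.integer(obj[[f]])
  }
  class(obj) <- "transfer_model"
  obj
}
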