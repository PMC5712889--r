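#' Construct a spectra set
#'
#' A `spectra_set` bundles an ordered wavelength grid (nm), an absorbance
#' matrix (samples in rows, wavelengths in columns), sample identifiers, and
#' optional per-sample reference analyte values (e.g. soluble solids content
#' in \%Brix). It is the common currency of every stage of the package:
#' preprocessing, sample selection, regression, and calibration transfer all
#' consume and produce `spectra_set` objects.
#'
#' Columns are reordered so the grid is strictly increasing; duplicate
#' wavelengths are an error because they make the grid ambiguous.
#'
#' @param wavelengths Numeric vector of wavelengths in nm.
#' @param absorbance Numeric matrix, `n_samples x n_wavelengths`.
#' @param sample_ids Optional character vector of sample labels; defaults to
#'   `"S1"`, `"S2"`, ...
#' @param reference Optional numeric vector of reference analyte values, one
#'   per sample.
#' @return An object of class `spectra_set` with fields `wavelengths`,
#'   `absorbance`, `sample_ids`, `reference`.
#' @examples
#' s <- spectra_set(c(1000, 1001, 1002), matrix(rnorm(6), nrow = 2))
#' n_samples(s)
#' @export
spectra_set <- function(wavelengths, absorbance, sample_ids = NULL,
                        reference = NULL) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (length(wavelengths) != ncol(absorbance)) {
    stop("length(wavelengths) must equal ncol(absorbance)")
  }
  if (anyDuplicated(wavelengths)) {
    stop("duplicate wavelengths in grid")
  }
  if (!all(is.finite(wavelengths))) stop("non-finite wavelengths")
  if (!all(is.finite(absorbance))) stop("non-finite absorbance values")
  ord <- order(wavelengths)
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    wavelengths <- wavelengths[ord]
    absorbance <- absorbance[, ord, drop = FALSE]
  }
  n <- nrow(absorbance)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids length must equal n_samples")
  if (!is.null(reference)) {
    reference <- as.numeric(reference)
    if (length(reference) != n) {
      stop("reference length must equal n_samples")
    }
  }
  dimnames(absorbance) <- NULL
  structure(
    list(wavelengths = wavelengths, absorbance = absorbance,
         sample_ids = sample_ids, reference = reference),
    class = "spectra_set"
  )
}

#' @rdname spectra_set
#' @param s A `spectra_set`.
#' @export
n_samples <- function(s) nrow(s$absorbance)

#' @rdname spectra_set
#' @export
n_wavelengths <- function(s) length(s$wavelengths)

#' @export
print.spectra_set <- function(x, ...) {
  rng <- range(x$wavelengths)
  cat(sprintf("spectra_set: %d samples x %d wavelengths (%.1f-%.1f nm)%s\n",
              n_samples(x), n_wavelengths(x), rng[1], rng[2],
              if (is.null(x$reference)) "" else ", with reference values"))
  invisible(x)
}

#' Subset a spectra set
#'
#' `i` indexes samples, `j` indexes wavelength channels (both standard R
#' index vectors). Reference values and sample ids follow the sample index.
#'
#' @param x A `spectra_set`.
#' @param i Sample indices (optional).
#' @param j Wavelength-channel indices (optional).
#' @param ... Unused.
#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_wavelengths(x))
  spectra_set(x$wavelengths[j], x$absorbance[i, j, drop = FALSE],
              x$sample_ids[i],
              if (is.null(x$reference)) NULL else x$reference[i])
}

#' Restrict a spectra set to a wavelength range
#'
#' Keeps the channels whose wavelength lies in `[lower, upper]` (inclusive).
#' Used to crop both instruments to their common modelling range before
#' preprocessing and transfer.
#'
#' @param s A `spectra_set`.
#' @param lower,upper Range bounds in nm.
#' @return A `spectra_set` on the restricted grid.
#' @export
crop_wavelengths <- function(s, lower, upper) {
  keep <- which(s$wavelengths >= lower & s$wavelengths <= upper)
  if (length(keep) < 1) stop("no wavelengths inside [lower, upper]")
  s[, keep]
}

#' Read spectra from delimited text
#'
#' Expected layout: comma-separated UTF-8 text; the first column holds sample
#' ids, an optional column named by `reference_column` holds reference
#' values, and every remaining header cell must parse as a numeric
#' wavelength. Columns are reordered to an ascending grid if needed. With
#' `wavenumber = TRUE` the header is interpreted as wavenumbers in cm^-1 and
#' converted to nm via lambda = 1e7 / nu (Fourier-transform instruments are
#' specified on a wavenumber axis; all transfer math here runs in nm).
#'
#' @param path Path to a CSV file.
#' @param reference_column Name of the reference-value column, or `NULL`.
#' @param wavenumber Logical; header is in cm^-1 and is converted to nm.
#' @return A `spectra_set`.
#' @export
read_spectra <- function(path, reference_column = NULL, wavenumber = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1) {
    stop("format error: ragged rows in ", path)
  }
  # parse the header ourselves: data-frame column subsetting would
  # silently deduplicate repeated wavelength names
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  df <- utils::read.csv(path, header = FALSE, skip = 1,
                        stringsAsFactors = FALSE)
  if (length(header) < 2) stop("format error: need an id column plus spectra")
  ids <- as.character(df[[1]])
  keep <- seq_along(header)[-1]
  reference <- NULL
  if (!is.null(reference_column)) {
    ref_col <- which(header == reference_column)
    if (length(ref_col) != 1) {
      stop("reference column '", reference_column, "' not found")
    }
    reference <- as.numeric(df[[ref_col]])
    keep <- setdiff(keep, ref_col)
  }
  wl <- suppressWarnings(as.numeric(header[keep]))
  if (anyNA(wl)) {
    stop("format error: non-numeric header cell(s): ",
         paste(header[keep][is.na(wl)], collapse = ", "))
  }
  if (wavenumber) wl <- 1e7 / wl
  if (anyDuplicated(wl)) stop("format error: duplicate wavelengths")
  spectra_set(wl, as.matrix(df[keep]), sample_ids = ids,
              reference = reference)
}

#' Write spectra to delimited text
#'
#' Inverse of [read_spectra()]: emits a CSV whose header row is the
#' wavelength grid, with sample ids in the first column and the reference
#' values (when present) in a column named `reference`. Numbers are written
#' with 17 significant digits so a read/write round trip preserves the
#' matrix to full double precision.
#'
#' @param s A `spectra_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  fmt <- function(x) sprintf("%.17g", x)
  header <- c("id",
              if (!is.null(s$reference)) "reference",
              fmt(s$wavelengths))
  rows <- vapply(seq_len(n_samples(s)), function(i) {
    paste(c(s$sample_ids[i],
            if (!is.null(s$reference)) fmt(s$reference[i]),
            fmt(s$absorbance[i, ])), collapse = ",")
  }, character(1))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), rows), con)
  invisible(path)
}

#' Read a table of replicate reference measurements
#'
#' The file must have a sample-id column named `id` followed by one column
#' per replicate (e.g. `y1,y2,y3`). Used with [sel()] to estimate the
#' standard error of laboratory of the reference method.
#'
#' @param path Path to a CSV file.
#' @return A data frame with the id column first.
#' @export
read_replicates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("replicate table needs an 'id' column")
  rep_cols <- setdiff(names(df), "id")
  if (length(rep_cols) < 2) stop("need at least two replicate columns")
  df[c("id", rep_cols)]
}
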