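#' Uniform wavenumber grid
#'
#' Constructs the wavenumber axis of a liquid-phase FTIR measurement:
#' strictly increasing, uniformly spaced values in cm^-1. The default covers
#' the mid-infrared fingerprint window 950--3050 cm^-1 sampled every 2 cm^-1
#' (an acquisition at 4 cm^-1 optical resolution is conventionally sampled at
#' half the resolution).
#'
#' @param from,to Range endpoints in cm^-1.
#' @param by Sampling interval in cm^-1.
#' @return Numeric vector of wavenumbers.
#' @export
#' @examples
#' g <- wavenumber_grid()
#' length(g) # 1051
wavenumber_grid <- function(from = 950, to = 3050, by = 2) {
  stopifnot(from < to, by > 0)
  seq(from, to, by = by)
}

assert_grid <- function(grid) {
  if (length(grid) < 3L || any(!is.finite(grid))) {
    stop("wavenumber grid must be finite and have at least 3 points")
  }
  d <- diff(grid)
  if (any(d <= 0)) stop("wavenumber grid must be strictly increasing")
  if (max(d) - min(d) > 1e-9) stop("wavenumber grid must be uniformly spaced")
  invisible(grid)
}

#' Single absorption spectrum
#'
#' A spectrum is a wavenumber grid plus one absorbance value (in absorbance
#' units, AU) per grid point.
#'
#' @param wavenumbers Numeric vector, cm^-1, strictly increasing.
#' @param absorbance Numeric vector of the same length, AU.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavenumbers, absorbance) {
  if (length(wavenumbers) != length(absorbance)) {
    stop("absorbance length must equal grid length")
  }
  if (any(!is.finite(absorbance))) stop("absorbance values must be finite")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 absorbance = as.numeric(absorbance)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.0f-%.0f cm^-1, absorbance [%.4g, %.4g] AU\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' Cohort of spectra with aligned sample metadata
#'
#' The central data container: an `n x p` absorbance matrix (rows are samples,
#' columns are wavenumbers), the shared wavenumber axis, and a metadata table
#' aligned row-for-row with the spectra. Every pipeline stage consumes and
#' returns this container.
#'
#' @param spectra Numeric matrix, one row per sample, one column per
#'   wavenumber; rownames are sample ids.
#' @param wavenumbers Numeric vector of column wavenumbers in cm^-1.
#' @param meta `data.frame` with at least a `sample_id` column matching the
#'   spectra rownames; typically also `group`, `age`, `sex`, `bmi`, `site`,
#'   `t_class`, `grade`.
#' @param water Optional `spectrum`: the pure-water reference recorded on the
#'   same grid, needed for water-displacement correction.
#' @param provenance Optional list recording how the cohort was produced.
#' @return An object of class `"cohort"`.
#' @export
cohort <- function(spectra, wavenumbers, meta, water = NULL, provenance = list()) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavenumbers)) {
    stop("spectra columns must match wavenumber grid length")
  }
  if (nrow(spectra) != nrow(meta)) stop("metadata rows must match spectra rows")
  if (is.null(meta$sample_id)) stop("meta must contain a sample_id column")
  meta$sample_id <- as.character(meta$sample_id)
  rownames(spectra) <- meta$sample_id
  if (!is.null(water)) {
    stopifnot(inherits(water, "spectrum"))
    if (length(water$wavenumbers) != length(wavenumbers) ||
        max(abs(water$wavenumbers - wavenumbers)) > 1e-9) {
      stop("water reference must share the cohort grid")
    }
  }
  structure(list(spectra = spectra, wavenumbers = as.numeric(wavenumbers),
                 meta = meta, water = water, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples x %d wavenumbers (%.0f-%.0f cm^-1)\n",
              nrow(x$spectra), ncol(x$spectra),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (!is.null(x$meta$group)) print(table(x$meta$group))
  invisible(x)
}

#' Subset a cohort by sample
#'
#' @param x A `cohort`.
#' @param idx Logical, integer, or character (sample id) index.
#' @return The subsetted `cohort`, metadata kept aligned.
#' @export
cohort_subset <- function(x, idx) {
  stopifnot(inherits(x, "cohort"))
  if (is.character(idx)) idx <- match(idx, x$meta$sample_id)
  cohort(x$spectra[idx, , drop = FALSE], x$wavenumbers,
         x$meta[idx, , drop = FALSE], water = x$water,
         provenance = x$provenance)
}

#' Read / write wide spectra tables
#'
#' The on-disk interchange format is a wide CSV: first column `sample_id`,
#' remaining column headers the wavenumbers in cm^-1, cells the absorbance.
#'
#' @param x A `cohort`.
#' @param path File path.
#' @return `read_spectra_csv` returns a list with `spectra` (matrix) and
#'   `wavenumbers`; `write_spectra_csv` returns `path` invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- data.frame(sample_id = x$meta$sample_id, x$spectra,
                   check.names = FALSE)
  colnames(df) <- c("sample_id", format(x$wavenumbers, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wn <- as.numeric(colnames(df)[-1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  list(spectra = m, wavenumbers = wn, sample_id = rownames(m))
}

#' Read / write the sample metadata table
#'
#' @param meta Metadata `data.frame`.
#' @param path File path.
#' @export
write_metadata_csv <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
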