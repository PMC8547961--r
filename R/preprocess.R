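#' Preprocessing configuration
#'
#' Controls the chemometric preprocessing chain applied per sample, in fixed
#' order: water correction, truncation + silent-region masking, L2 vector
#' normalization, optional Savitzky-Golay second derivative.
#'
#' @param do_water_correction,do_normalize,do_second_derivative Stage flags.
#' @param flat_window Window (cm^-1) with no significant solute absorption in
#'   dried serum/plasma, used to fit the water-correction coefficient.
#' @param keep_range Truncation range (cm^-1), boundaries inclusive.
#' @param silent_region Open interval (cm^-1) removed from the features; the
#'   printed endpoints themselves are retained.
#' @param sg_window,sg_polyorder Savitzky-Golay filter length (odd, points)
#'   and polynomial order.
#' @return List of class `"preprocess_config"`.
#' @export
preprocess_config <- function(do_water_correction = TRUE,
                              do_normalize = TRUE,
                              do_second_derivative = FALSE,
                              flat_window = c(2000, 2300),
                              keep_range = c(1000, 3000),
                              silent_region = c(1750, 2800),
                              sg_window = 9,
                              sg_polyorder = 3) {
  stopifnot(length(flat_window) == 2, flat_window[1] < flat_window[2],
            length(keep_range) == 2, keep_range[1] < keep_range[2],
            length(silent_region) == 2, silent_region[1] < silent_region[2],
            silent_region[1] > keep_range[1], silent_region[2] < keep_range[2],
            sg_window %% 2 == 1, sg_window > sg_polyorder)
  structure(list(do_water_correction = do_water_correction,
                 do_normalize = do_normalize,
                 do_second_derivative = do_second_derivative,
                 flat_window = flat_window, keep_range = keep_range,
                 silent_region = silent_region,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder)),
            class = "preprocess_config")
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Water-displacement baseline correction
#'
#' A liquid sample containing less water than the pure-water reference shows
#' apparently negative absorption. Because dried serum/plasma has no
#' significant absorption over 2000--2300 cm^-1, a solute spectrum is flat
#' there; any residual slope comes from the displaced water. The correction
#' adds `alpha` times the water reference, with `alpha` chosen to zero the
#' ordinary-least-squares slope of the spectrum over the flat window:
#' `alpha = -slope(s) / slope(water)` (closed form of minimizing the absolute
#' average slope). `alpha` may be negative.
#'
#' @param s `spectrum` to correct.
#' @param water `spectrum`: water reference on the same grid.
#' @param flat_window Length-2 window in cm^-1.
#' @return List: `spectrum` (corrected) and `alpha`.
#' @export
#' @examples
#' g <- wavenumber_grid()
#' w <- water_reference_spectrum(g)
#' s <- spectrum(g, 0.1 * exp(-((g - 1650) / 30)^2) - 0.3 * w$absorbance)
#' water_correct(s, w)$alpha # ~0.3
water_correct <- function(s, water, flat_window = c(2000, 2300)) {
  stopifnot(inherits(s, "spectrum"), inherits(water, "spectrum"))
  if (length(s$wavenumbers) != length(water$wavenumbers) ||
      max(abs(s$wavenumbers - water$wavenumbers)) > 1e-9) {
    stop("spectrum and water reference must share the same grid")
  }
  win <- s$wavenumbers >= flat_window[1] & s$wavenumbers <= flat_window[2]
  if (sum(win) < 3) stop("flat window contains fewer than 3 grid points")
  x <- s$wavenumbers[win]
  slope_w <- ols_slope(x, water$absorbance[win])
  if (abs(slope_w) <= 1e-12) {
    stop("water reference slope over the flat window is numerically zero; ",
         "the correction coefficient is unidentifiable")
  }
  slope_s <- ols_slope(x, s$absorbance[win])
  alpha <- -slope_s / slope_w
  list(spectrum = spectrum(s$wavenumbers, s$absorbance + alpha * water$absorbance),
       alpha = alpha)
}

#' Truncate and mask the silent region
#'
#' Keeps wavenumbers in `keep_range` (boundaries inclusive) and removes the
#' open interval `silent_region`, i.e. the default retains
#' `[1000, 1750] U [2800, 3000]` cm^-1, endpoints included. Idempotent.
#'
#' @param s A `spectrum`.
#' @param cfg A `preprocess_config` (only `keep_range`/`silent_region` used).
#' @return The masked `spectrum`.
#' @export
restrict_and_mask <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "spectrum"))
  keep <- retained_index(s$wavenumbers, cfg)
  if (!any(keep)) stop("no wavenumbers retained by keep_range/silent_region")
  spectrum(s$wavenumbers[keep], s$absorbance[keep])
}

retained_index <- function(wavenumbers, cfg) {
  wavenumbers >= cfg$keep_range[1] & wavenumbers <= cfg$keep_range[2] &
    !(wavenumbers > cfg$silent_region[1] & wavenumbers < cfg$silent_region[2])
}

#' Euclidean (L2) vector normalization
#'
#' @param s A `spectrum` with nonzero absorbance vector.
#' @return The `spectrum` scaled to unit Euclidean norm.
#' @export
vector_normalize <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  nrm <- sqrt(sum(s$absorbance^2))
  if (nrm <= 0) stop("cannot normalize a zero spectrum")
  spectrum(s$wavenumbers, s$absorbance / nrm)
}

# split a (possibly gapped) grid into contiguous uniformly spaced segments
contiguous_segments <- function(wavenumbers) {
  if (length(wavenumbers) < 2) return(list(seq_along(wavenumbers)))
  d <- diff(wavenumbers)
  step <- min(d)
  breaks <- which(d > 1.5 * step)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(wavenumbers))
  mapply(seq, starts, ends, SIMPLIFY = FALSE)
}

#' Savitzky-Golay second derivative
#'
#' Computes the second derivative with respect to wavenumber using a
#' Savitzky-Golay filter, applied separately to each contiguous grid segment
#' so the two retained ranges are never smoothed across the silent-region gap.
#'
#' @param s A `spectrum` (possibly masked, i.e. with a grid gap).
#' @param cfg A `preprocess_config` (`sg_window`, `sg_polyorder` used).
#' @return `spectrum` of the same length holding the second derivative
#'   (AU per (cm^-1)^2).
#' @export
second_derivative <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "spectrum"))
  segs <- contiguous_segments(s$wavenumbers)
  out <- numeric(length(s$absorbance))
  for (idx in segs) {
    if (length(idx) < cfg$sg_window) {
      stop("grid segment shorter than the Savitzky-Golay window")
    }
    ts <- s$wavenumbers[idx[2]] - s$wavenumbers[idx[1]]
    out[idx] <- signal::sgolayfilt(s$absorbance[idx], p = cfg$sg_polyorder,
                                   n = cfg$sg_window, m = 2, ts = ts)
  }
  spectrum(s$wavenumbers, out)
}

#' Apply the preprocessing chain to a whole cohort
#'
#' Per-sample application, in fixed order: water correction (if enabled) ->
#' truncation + silent-region masking -> L2 normalization (if enabled) ->
#' Savitzky-Golay second derivative (if enabled). No statistics are shared
#' across samples, so preprocessing cannot leak information between training
#' and test folds downstream.
#'
#' @param x A `cohort`; must carry a water reference when water correction is
#'   enabled.
#' @param cfg A `preprocess_config`.
#' @return The preprocessed `cohort`; `provenance$preprocess` records the
#'   config and `provenance$alpha` the per-sample water-correction
#'   coefficients (named by sample id).
#' @export
apply_pipeline <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "cohort"), inherits(cfg, "preprocess_config"))
  if (cfg$do_water_correction && is.null(x$water)) {
    stop("water correction requested but the cohort has no water reference")
  }
  keep <- retained_index(x$wavenumbers, cfg)
  wn_out <- x$wavenumbers[keep]
  out <- matrix(0, nrow(x$spectra), length(wn_out))
  alphas <- rep(NA_real_, nrow(x$spectra))
  for (i in seq_len(nrow(x$spectra))) {
    s <- spectrum(x$wavenumbers, x$spectra[i, ])
    if (cfg$do_water_correction) {
      wc <- water_correct(s, x$water, cfg$flat_window)
      s <- wc$spectrum
      alphas[i] <- wc$alpha
    }
    s <- restrict_and_mask(s, cfg)
    if (cfg$do_normalize) s <- vector_normalize(s)
    if (cfg$do_second_derivative) s <- second_derivative(s, cfg)
    out[i, ] <- s$absorbance
  }
  prov <- x$provenance
  prov$preprocess <- cfg
  prov$alpha <- stats::setNames(alphas, x$meta$sample_id)
  cohort(out, wn_out, x$meta, water = NULL, provenance = prov)
}

#' Write per-sample water-correction coefficients
#'
#' @param x A preprocessed `cohort` (output of [apply_pipeline()]).
#' @param path Output CSV path (`sample_id, alpha`).
#' @export
write_alpha_csv <- function(x, path) {
  a <- x$provenance$alpha
  if (is.null(a)) stop("cohort carries no water-correction coefficients")
  utils::write.csv(data.frame(sample_id = names(a), alpha = as.numeric(a)),
                   path, row.names = FALSE)
  invisible(path)
}
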