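#' Gaussian absorption band model
#'
#' @param center Band center in cm^-1.
#' @param width Gaussian sigma in cm^-1.
#' @param amplitude Peak absorbance in AU for the population-average person.
#' @param concentration_cv Coefficient of variation of the per-person
#'   (log-normal) band amplitude; models between-person biological variability
#'   of the underlying molecular concentrations.
#' @return A list of class `"band_model"`.
#' @export
band_model <- function(center, width, amplitude, concentration_cv = 0) {
  stopifnot(width > 0, amplitude >= 0, concentration_cv >= 0)
  structure(list(center = center, width = width, amplitude = amplitude,
                 concentration_cv = concentration_cv),
            class = "band_model")
}

gaussian_band <- function(grid, center, width) {
  exp(-0.5 * ((grid - center) / width)^2)
}

#' Default serum-like absorption band set
#'
#' Eight Gaussian bands mimicking the dominant liquid-serum absorption
#' features: amide I (1652 cm^-1, dominant), amide II (1545), CH2/CH3
#' deformations (1455/1400), carbohydrate/phosphate region (1080/1160), the
#' lipid ester carbonyl (1740), and the C-H stretch region (2930). Amplitudes
#' are loosely calibrated so amide I dominates, as in measured serum spectra;
#' per-band concentration CVs encode that lipids vary more between persons
#' than total protein.
#'
#' @return List of `band_model` objects, named by feature.
#' @export
serum_bands <- function() {
  list(
    amide_I      = band_model(1652, 25, 0.50, 0.05),
    amide_II     = band_model(1545, 22, 0.30, 0.06),
    ch_def_1455  = band_model(1455, 18, 0.10, 0.08),
    ch_def_1400  = band_model(1400, 18, 0.09, 0.08),
    carb_1160    = band_model(1160, 25, 0.06, 0.10),
    carb_1080    = band_model(1080, 40, 0.09, 0.10),
    lipid_ester  = band_model(1740, 15, 0.05, 0.15),
    ch_stretch   = band_model(2930, 35, 0.12, 0.10)
  )
}

#' Synthetic pure-water reference spectrum
#'
#' Deterministic stand-in for the measured water reference recorded after each
#' sample measurement: a broad H-O-H bending band near 1640 cm^-1, the rising
#' flank of the O-H stretch toward 3050 cm^-1, a weak association band around
#' 2130 cm^-1, and a gentle linear ramp. The ramp guarantees a nonzero
#' ordinary-least-squares slope over the 2000--2300 cm^-1 window, which is
#' what makes the water-displacement correction identifiable.
#'
#' @param grid Wavenumber grid (cm^-1).
#' @return A `spectrum`.
#' @export
#' @examples
#' w <- water_reference_spectrum(wavenumber_grid())
water_reference_spectrum <- function(grid) {
  assert_grid(grid)
  a <- 1.00 * gaussian_band(grid, 1640, 90) +
       0.10 * gaussian_band(grid, 2130, 160) +
       1.50 * gaussian_band(grid, 3380, 230) +
       3e-5 * (grid - 950)
  spectrum(grid, a)
}

#' Draw one person's serum spectrum
#'
#' Simulates the liquid-phase absorption spectrum of a single person:
#' the sum of the band set with log-normal per-person amplitudes (mean 1,
#' CV = each band's `concentration_cv`), minus `beta` times the water
#' reference (water displacement: a sample containing less water than the
#' pure-water reference shows apparently negative absorption), plus additive
#' Gaussian measurement noise.
#'
#' The water deficit `beta` is drawn log-normally with mean proportional to
#' the realized total solute load (more solute displaces more water), unless
#' a fixed `beta` is supplied. Uses the current RNG state.
#'
#' @param grid Wavenumber grid.
#' @param bands List of `band_model`s (at least one).
#' @param water `spectrum`: water reference on `grid`.
#' @param noise_sd Additive Gaussian noise SD in AU.
#' @param water_deficit_mean Mean of `beta` for a person with average solute.
#' @param water_deficit_sd SD of the log-normal multiplicative scatter of
#'   `beta` around its solute-coupled mean.
#' @param beta Optional fixed water deficit (overrides the random draw).
#' @param band_scale Optional numeric vector, one multiplier per band, applied
#'   on top of the biological log-normal draw (used for covariate coupling).
#' @return List: `spectrum` (a `spectrum`), `beta` (true water deficit),
#'   `solute` (realized total solute load, sum of band amplitudes).
#' @export
sample_person_spectrum <- function(grid, bands, water,
                                   noise_sd = 0.002,
                                   water_deficit_mean = 0.15,
                                   water_deficit_sd = 0.05,
                                   beta = NULL,
                                   band_scale = NULL) {
  if (length(bands) < 1L) stop("at least one band model is required")
  assert_grid(grid)
  if (is.null(band_scale)) band_scale <- rep(1, length(bands))
  stopifnot(length(band_scale) == length(bands))

  amps <- vapply(seq_along(bands), function(i) {
    b <- bands[[i]]
    if (b$concentration_cv > 0) {
      sdlog <- sqrt(log(1 + b$concentration_cv^2))
      lf <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      lf <- 1
    }
    b$amplitude * lf * band_scale[i]
  }, numeric(1))

  solute <- sum(amps)
  expected_solute <- sum(vapply(bands, `[[`, numeric(1), "amplitude"))

  if (is.null(beta)) {
    if (water_deficit_sd > 0 && water_deficit_mean > 0) {
      cv <- water_deficit_sd / water_deficit_mean
      sdlog <- sqrt(log(1 + cv^2))
      scatter <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      scatter <- 1
    }
    beta <- water_deficit_mean * (solute / expected_solute) * scatter
  }

  a <- numeric(length(grid))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    a <- a + amps[i] * gaussian_band(grid, b$center, b$width)
  }
  a <- a - beta * water$absorbance
  if (noise_sd > 0) a <- a + stats::rnorm(length(grid), sd = noise_sd)

  list(spectrum = spectrum(grid, a), beta = beta, solute = solute)
}

#' Disease signature with stage-scaled amplitude
#'
#' A disease signature is a unit-L2-norm differential absorbance shape on the
#' grid plus one nonnegative amplitude per tumour T class; the spectrum of a
#' case with class `T` receives `amplitude_per_stage[T] * signature` before
#' measurement noise is added. The default shape lives largely in the span of
#' the biological band variation (amide II up, amide I down, carbohydrate up),
#' so detectability is limited by between-person variability rather than by
#' instrument noise, and the default amplitudes grow with T class, emulating
#' larger tumour load leaving a larger compositional footprint.
#'
#' @param grid Wavenumber grid.
#' @param shape Optional numeric vector on `grid`; will be L2-normalized.
#' @param amplitude_per_stage Named nonnegative vector over `T1..T4`, in AU;
#'   must be nondecreasing in T by default semantics. The defaults are
#'   calibrated against the between-person variability along the signature
#'   direction so the stage ladder spans weak-to-strong detectability
#'   (cross-validated AUC roughly 0.6 to 0.95).
#' @return List of class `"disease_signature"`.
#' @export
disease_signature <- function(grid,
                              shape = NULL,
                              amplitude_per_stage = c(T1 = 0.10, T2 = 0.15,
                                                      T3 = 0.22, T4 = 0.30)) {
  assert_grid(grid)
  if (is.null(shape)) {
    shape <- gaussian_band(grid, 1545, 22) -
             0.7 * gaussian_band(grid, 1652, 25) +
             0.5 * gaussian_band(grid, 1080, 40) +
             0.3 * gaussian_band(grid, 2930, 35)
  }
  stopifnot(length(shape) == length(grid))
  nrm <- sqrt(sum(shape^2))
  if (nrm <= 0) stop("signature shape must be nonzero")
  if (any(amplitude_per_stage < 0)) stop("stage amplitudes must be >= 0")
  structure(list(shape = shape / nrm,
                 amplitude_per_stage = amplitude_per_stage),
            class = "disease_signature")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Counts, noise level,
#' water-deficit distribution, covariate confounding strength and artifact
#' fraction; see `generate_cohort()` for their meaning.
#'
#' @param n_cases,n_refs Group sizes.
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @param grid Wavenumber grid.
#' @param bands Band set (list of `band_model`).
#' @param noise_sd Measurement noise SD, AU.
#' @param water_deficit_mean,water_deficit_sd Water-deficit distribution.
#' @param covariate_confounding Scalar in `[0, inf)`: scales the case-vs-
#'   reference shift of the age/sex/BMI distributions (0 = identically
#'   distributed covariates).
#' @param outlier_fraction Fraction of spectra replaced by artifacts.
#' @param n_sites Number of clinical sites (labels only).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_cases = 100, n_refs = 100, seed = 1,
                       grid = wavenumber_grid(),
                       bands = serum_bands(),
                       noise_sd = 0.002,
                       water_deficit_mean = 0.15,
                       water_deficit_sd = 0.05,
                       covariate_confounding = 0,
                       outlier_fraction = 0,
                       n_sites = 3) {
  stopifnot(n_cases >= 0, n_refs >= 0, noise_sd >= 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            covariate_confounding >= 0, n_sites >= 1)
  structure(list(n_cases = n_cases, n_refs = n_refs, seed = as.integer(seed),
                 grid = grid, bands = bands, noise_sd = noise_sd,
                 water_deficit_mean = water_deficit_mean,
                 water_deficit_sd = water_deficit_sd,
                 covariate_confounding = covariate_confounding,
                 outlier_fraction = outlier_fraction, n_sites = n_sites),
            class = "sim_config")
}

#' Load a simulation configuration from YAML
#'
#' Reads the scalar fields of [sim_config()] from a YAML file; unspecified
#' fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("n_cases", "n_refs", "seed", "noise_sd", "water_deficit_mean",
               "water_deficit_sd", "covariate_confounding", "outlier_fraction",
               "n_sites")
  do.call(sim_config, y[intersect(names(y), allowed)])
}

# age/BMI coupling into band amplitudes: fixed physiological coefficients.
# amide II scales weakly with age, the lipid ester band with BMI.
covariate_band_scale <- function(bands, age, bmi) {
  s <- rep(1, length(bands))
  nm <- names(bands)
  s[nm == "amide_II"] <- 1 + 0.003 * (age - 60)
  s[nm == "lipid_ester"] <- 1 + 0.010 * (bmi - 26)
  pmax(s, 0.1)
}

#' Generate a synthetic case/reference cohort with ground truth
#'
#' Simulates a full study cohort: reference individuals draw covariates from
#' the population distributions (age ~ N(60, 10), sex ~ Bernoulli(0.5),
#' BMI ~ N(26, 4)); cases are shifted by `covariate_confounding` times
#' (+5 y age, +0.10 sex probability, +1.5 BMI) to exercise statistical
#' matching. Age and BMI scale two absorption bands with fixed coefficients,
#' so covariate imbalance leaks into the spectra. Each case is assigned a
#' tumour T class (probabilities 0.30/0.30/0.25/0.15 for T1..T4) and receives
#' the stage-scaled disease signature before measurement noise. If
#' `outlier_fraction > 0` that fraction of spectra is replaced by artifacts
#' (see [inject_artifacts()]).
#'
#' @param config A `sim_config`.
#' @param signature A `disease_signature`, or `NULL` for no disease effect.
#' @return List: `cohort` (a `cohort` with metadata columns `sample_id`,
#'   `group`, `age`, `sex`, `bmi`, `site`, `t_class`, `grade`), and
#'   `ground_truth` (per-sample `beta`, `delta` actually added, labels, and
#'   `artifact_ids`).
#' @export
generate_cohort <- function(config, signature = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grid <- config$grid
  water <- water_reference_spectrum(grid)
  n <- config$n_cases + config$n_refs
  group <- c(rep("case", config$n_cases), rep("reference", config$n_refs))
  cf <- config$covariate_confounding

  age <- stats::rnorm(n, 60, 10) + ifelse(group == "case", 5 * cf, 0)
  age <- pmin(pmax(age, 20), 95)
  sex <- stats::rbinom(n, 1, pmin(pmax(0.5 + ifelse(group == "case", 0.10 * cf, 0),
                                       0.01), 0.99))
  bmi <- stats::rnorm(n, 26, 4) + ifelse(group == "case", 1.5 * cf, 0)
  bmi <- pmin(pmax(bmi, 15), 50)
  site <- sample(paste0("site", seq_len(config$n_sites)), n, replace = TRUE)

  t_class <- rep(NA_character_, n)
  if (config$n_cases > 0) {
    t_class[group == "case"] <- sample(c("T1", "T2", "T3", "T4"),
                                       config$n_cases, replace = TRUE,
                                       prob = c(0.30, 0.30, 0.25, 0.15))
  }
  grade <- rep(NA_integer_, n)
  grade[group == "case"] <- sample(1:3, config$n_cases, replace = TRUE)

  delta <- numeric(n)
  if (!is.null(signature)) {
    stopifnot(inherits(signature, "disease_signature"))
    idx <- which(group == "case")
    delta[idx] <- signature$amplitude_per_stage[t_class[idx]]
  }

  X <- matrix(0, n, length(grid))
  beta_true <- numeric(n)
  for (i in seq_len(n)) {
    bs <- covariate_band_scale(config$bands, age[i], bmi[i])
    clean <- sample_person_spectrum(grid, config$bands, water,
                                    noise_sd = 0,
                                    water_deficit_mean = config$water_deficit_mean,
                                    water_deficit_sd = config$water_deficit_sd,
                                    band_scale = bs)
    a <- clean$spectrum$absorbance
    if (delta[i] > 0) a <- a + delta[i] * signature$shape
    if (config$noise_sd > 0) a <- a + stats::rnorm(length(grid), sd = config$noise_sd)
    X[i, ] <- a
    beta_true[i] <- clean$beta
  }

  meta <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                     group = group, age = age, sex = sex, bmi = bmi,
                     site = site, t_class = t_class, grade = grade,
                     stringsAsFactors = FALSE)
  co <- cohort(X, grid, meta, water = water,
               provenance = list(generator = "generate_cohort",
                                 seed = config$seed))

  artifact_ids <- character(0)
  if (config$outlier_fraction > 0) {
    inj <- inject_artifacts(co, config$outlier_fraction)
    co <- inj$cohort
    artifact_ids <- inj$artifact_ids
  }

  list(cohort = co,
       ground_truth = list(beta = stats::setNames(beta_true, meta$sample_id),
                           delta = stats::setNames(delta, meta$sample_id),
                           group = stats::setNames(group, meta$sample_id),
                           t_class = stats::setNames(t_class, meta$sample_id),
                           artifact_ids = artifact_ids))
}

#' Write the generator's ground truth as JSON
#'
#' @param ground_truth The `ground_truth` element of [generate_cohort()].
#' @param path Output path.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Inject spectral artifacts into a cohort
#'
#' Replaces a chosen fraction of spectra with one of the two anomaly types
#' the quality-control stage must catch: globally scaled-down absorbance
#' (x 0.2, mimicking abnormally low absorbance) or an added spurious narrow
#' contamination band (Gaussian, sigma 8 cm^-1, amplitude half the spectrum
#' maximum, centered inside the analysed windows 1000-1750 or 2800-3000
#' cm^-1 -- a band confined to the discarded silent region would not be an
#' anomaly in the analysed data). Uses the current RNG state.
#'
#' @param x A `cohort`.
#' @param fraction Fraction of samples to corrupt, in `[0, 1)`; the count is
#'   `round(fraction * n)`.
#' @return List: `cohort` (modified) and `artifact_ids` (character).
#' @export
inject_artifacts <- function(x, fraction) {
  stopifnot(inherits(x, "cohort"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n <- nrow(x$spectra)
  m <- round(fraction * n)
  if (m == 0) return(list(cohort = x, artifact_ids = character(0)))
  idx <- sample.int(n, m)
  grid <- x$wavenumbers
  for (i in idx) {
    if (stats::runif(1) < 0.5) {
      x$spectra[i, ] <- 0.2 * x$spectra[i, ]
    } else {
      center <- if (stats::runif(1) < 0.75) {
        stats::runif(1, 1000, 1750)
      } else {
        stats::runif(1, 2800, 3000)
      }
      amp <- 0.5 * max(abs(x$spectra[i, ]))
      x$spectra[i, ] <- x$spectra[i, ] + amp * gaussian_band(grid, center, 8)
    }
  }
  list(cohort = x, artifact_ids = x$meta$sample_id[sort(idx)])
}
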