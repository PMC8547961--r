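#' Differential fingerprint
#'
#' Elementwise difference between the mean spectrum of the cases and the mean
#' spectrum of the references, together with the reference-group standard
#' deviation (ddof = 1) used as the visual/statistical yardstick.
#'
#' @param cases,refs Numeric matrices (rows = samples) on the same grid.
#' @return List: `delta` (AU), `sd_ref` (AU).
#' @export
differential_fingerprint <- function(cases, refs) {
  cases <- as.matrix(cases); refs <- as.matrix(refs)
  if (ncol(cases) != ncol(refs)) stop("case and reference grids differ")
  if (nrow(cases) < 2 || nrow(refs) < 2) stop("both groups need >= 2 samples")
  list(delta = colMeans(cases) - colMeans(refs),
       sd_ref = apply(refs, 2, stats::sd))
}

#' Per-wavenumber two-sample Student t-test
#'
#' Classical pooled-variance two-sample t, two-tailed p-values from the t
#' distribution with `n1 + n2 - 2` degrees of freedom, vectorized over
#' wavenumber columns. At a wavenumber with zero pooled variance the p-value
#' is 1 when the group means are equal and 0 otherwise (flagging a degenerate
#' perfect separation). A Welch variant is available behind `welch = TRUE`.
#'
#' @param cases,refs Numeric matrices (rows = samples) on the same grid.
#' @param welch Use the Welch (unequal-variance) statistic instead.
#' @return Numeric vector of two-tailed p-values, one per column.
#' @export
pointwise_ttest <- function(cases, refs, welch = FALSE) {
  cases <- as.matrix(cases); refs <- as.matrix(refs)
  if (ncol(cases) != ncol(refs)) stop("case and reference grids differ")
  n1 <- nrow(cases); n2 <- nrow(refs)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 samples")
  m1 <- colMeans(cases); m2 <- colMeans(refs)
  v1 <- colSums(sweep(cases, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(refs, 2, m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  }
  p <- numeric(length(se2))
  zero <- se2 <= 0
  if (any(zero)) p[zero] <- ifelse(abs(m1[zero] - m2[zero]) == 0, 1, 0)
  if (any(!zero)) {
    t <- (m1[!zero] - m2[!zero]) / sqrt(se2[!zero])
    p[!zero] <- 2 * stats::pt(-abs(t), df[!zero])
  }
  p
}

#' Per-wavenumber Mann-Whitney AUC
#'
#' Exact U-statistic estimate of `P(case > reference)` per wavenumber:
#' `U = #\{case_i > ref_j\} + 0.5 * #\{ties\}` and `AUC = U / (n1 * n2)`.
#' Computed via midranks (no normal approximation), oriented with the cases as
#' the positive class (values > 0.5 mean cases tend to be higher).
#'
#' @param cases,refs Numeric matrices (rows = samples) on the same grid.
#' @return Numeric vector of AUC values in `[0, 1]`, one per column.
#' @export
#' @examples
#' pointwise_auc(matrix(c(3, 5)), matrix(c(1, 2, 4))) # 5/6
pointwise_auc <- function(cases, refs) {
  cases <- as.matrix(cases); refs <- as.matrix(refs)
  if (ncol(cases) != ncol(refs)) stop("case and reference grids differ")
  n1 <- nrow(cases); n2 <- nrow(refs)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  both <- rbind(cases, refs)
  r <- apply(both, 2, rank) # midranks
  if (is.null(dim(r))) r <- matrix(r, ncol = ncol(both))
  u <- colSums(r[seq_len(n1), , drop = FALSE]) - n1 * (n1 + 1) / 2
  as.numeric(u / (n1 * n2))
}

#' Standardized effect-size curve
#'
#' The differential fingerprint standardized by the reference-group SD,
#' `effect = delta / sd_ref`. For Gaussian equal-variance groups this relates
#' to the per-wavenumber AUC through the binormal form
#' `AUC = Phi(effect / sqrt(2))`.
#'
#' @param delta,sd_ref Aligned numeric vectors (see
#'   [differential_fingerprint()]); all `sd_ref > 0`.
#' @return Numeric vector of standardized effects.
#' @export
effect_size_curve <- function(delta, sd_ref) {
  if (length(delta) != length(sd_ref)) stop("delta and sd_ref lengths differ")
  if (any(sd_ref <= 0)) stop("sd_ref must be positive at every wavenumber")
  delta / sd_ref
}

#' Area under the absolute differential fingerprint
#'
#' Trapezoidal integral of `|delta|` over each contiguous retained grid
#' segment, summed; the integration never bridges the silent-region gap.
#' Units: AU * cm^-1.
#'
#' @param delta Differential fingerprint values.
#' @param wavenumbers Matching (possibly gapped) grid.
#' @return Scalar area.
#' @export
area_abs_diff <- function(delta, wavenumbers) {
  if (length(delta) != length(wavenumbers)) stop("length mismatch")
  total <- 0
  for (idx in contiguous_segments(wavenumbers)) {
    if (length(idx) < 2) next
    y <- abs(delta[idx]); x <- wavenumbers[idx]
    total <- total + sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  }
  total
}

#' Full per-wavenumber statistics table
#'
#' Differential fingerprint, reference SD, pooled-t p-value, Mann-Whitney AUC
#' and standardized effect size for every retained wavenumber of a cohort.
#'
#' @param x A (preprocessed) `cohort` with a binary `group` column.
#' @return `data.frame` of class `"wavenumber_stats"`: `wavenumber`, `delta`,
#'   `sd_ref`, `p_t`, `auc_w`, `effect`; attributes `n1`, `n2`,
#'   `area_abs_diff`.
#' @export
wavenumber_stats <- function(x) {
  stopifnot(inherits(x, "cohort"))
  is_case <- x$meta$group == "case"
  cases <- x$spectra[is_case, , drop = FALSE]
  refs <- x$spectra[!is_case, , drop = FALSE]
  df <- differential_fingerprint(cases, refs)
  out <- data.frame(wavenumber = x$wavenumbers,
                    delta = df$delta,
                    sd_ref = df$sd_ref,
                    p_t = pointwise_ttest(cases, refs),
                    auc_w = pointwise_auc(cases, refs))
  out$effect <- ifelse(out$sd_ref > 0, out$delta / out$sd_ref, NA_real_)
  attr(out, "n1") <- nrow(cases)
  attr(out, "n2") <- nrow(refs)
  attr(out, "area_abs_diff") <- area_abs_diff(df$delta, x$wavenumbers)
  class(out) <- c("wavenumber_stats", "data.frame")
  out
}

#' Write the per-wavenumber statistics table
#'
#' @param stats A `wavenumber_stats` table.
#' @param path Output CSV path.
#' @export
write_stats_csv <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}

#' PCA check for clinical-site clustering
#'
#' Principal component analysis of the (centered) spectra of one diagnosis
#' group, retaining the smallest number of components reaching at least the
#' target cumulative explained variance (default 95%). Between-site separation
#' in that subspace is quantified as the site-size-weighted sum of squared
#' distances of site centroids from the grand centroid, with a label-
#' permutation p-value.
#'
#' @param X Numeric spectra matrix for a single diagnosis group.
#' @param site Site labels (>= 2 sites, >= 3 samples each).
#' @param var_target Cumulative explained-variance target.
#' @param n_perm Number of label permutations (default 999).
#' @return List: `explained` (all PC variance fractions), `n_pc`,
#'   `statistic` (observed between-site separation), `p_value`,
#'   `site_means` (site centroids in the retained subspace).
#' @export
pca_site_check <- function(X, site, var_target = 0.95, n_perm = 999) {
  X <- as.matrix(X)
  site <- factor(site)
  if (nlevels(site) < 2) stop("at least two sites are required")
  if (min(table(site)) < 3) stop("every site needs at least 3 samples")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- which(cumsum(explained) >= var_target)[1]
  if (is.na(n_pc)) n_pc <- length(explained)
  S <- pc$x[, seq_len(n_pc), drop = FALSE]

  between_stat <- function(scores, lab) {
    g <- rowsum(scores, lab)
    n <- as.numeric(table(lab))
    cent <- sweep(g, 1, n, "/")
    grand <- colMeans(scores)
    sum(n * rowSums(sweep(cent, 2, grand)^2))
  }
  obs <- between_stat(S, site)
  perm <- replicate(n_perm, between_stat(S, sample(site)))
  list(explained = explained,
       n_pc = n_pc,
       statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       site_means = rowsum(S, site) / as.numeric(table(site)))
}
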