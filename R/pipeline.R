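#' Study configuration
#'
#' Bundles the stage parameters of an end-to-end study run: simulation
#' (optional, for synthetic studies), preprocessing, outlier QC, matching and
#' cross-validation. One global seed drives every stochastic stage.
#'
#' @param sim A `sim_config`, or `NULL` when a measured cohort is supplied.
#' @param signature A `disease_signature` or `NULL`.
#' @param preprocess A `preprocess_config`.
#' @param qc_k LOF neighbour count; `NA` skips the QC stage.
#' @param qc_cutoff LOF flagging cutoff.
#' @param caliper_sd_mult,match_k Matching parameters (see
#'   [optimal_multi_ref_match()]); `caliper_sd_mult = NA` skips matching.
#' @param folds,repeats Cross-validation geometry.
#' @param C SVM regularization parameter.
#' @param seed Global integer seed.
#' @return List of class `"study_config"`.
#' @export
study_config <- function(sim = NULL, signature = NULL,
                         preprocess = preprocess_config(),
                         qc_k = 20, qc_cutoff = 1.5,
                         caliper_sd_mult = 0.2, match_k = 1,
                         folds = 10, repeats = 10, C = 1, seed = 1) {
  structure(list(sim = sim, signature = signature, preprocess = preprocess,
                 qc_k = qc_k, qc_cutoff = qc_cutoff,
                 caliper_sd_mult = caliper_sd_mult, match_k = match_k,
                 folds = folds, repeats = repeats, C = C,
                 seed = as.integer(seed)),
            class = "study_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

# QC features: water-corrected and masked but NOT normalized, so that
# globally scaled-down (abnormally low-absorbance) spectra remain visible --
# L2 normalization would map them back onto the inliers.
qc_flagged_ids <- function(cohort, config) {
  qc_cfg <- config$preprocess
  qc_cfg$do_normalize <- FALSE
  qc_cfg$do_second_derivative <- FALSE
  feats <- apply_pipeline(cohort, qc_cfg)
  qc <- qc_cohort(feats, k = config$qc_k, cutoff = config$qc_cutoff)
  qc$flagged
}

prepare_study_cohort <- function(config, cohort = NULL) {
  if (is.null(cohort)) {
    if (is.null(config$sim)) stop("either a cohort or a sim config is required")
    cohort <- with_stage("simulate",
                         generate_cohort(config$sim, config$signature)$cohort)
  }
  n_raw <- nrow(cohort$spectra)
  flagged <- character(0)
  if (!is.na(config$qc_k) && n_raw > config$qc_k) {
    flagged <- with_stage("qc", qc_flagged_ids(cohort, config))
    if (length(flagged) > 0) {
      cohort <- cohort_subset(cohort, !(cohort$meta$sample_id %in% flagged))
    }
  }
  pp <- with_stage("preprocess", apply_pipeline(cohort, config$preprocess))
  balance <- NULL
  match <- NULL
  if (!is.na(config$caliper_sd_mult)) {
    m <- with_stage("match", match_cohort(pp,
                                          caliper_sd_mult = config$caliper_sd_mult,
                                          k = config$match_k))
    pp <- m$cohort
    balance <- m$balance
    match <- m$match
  }
  list(cohort = pp, n_raw = n_raw, flagged = flagged,
       balance = balance, match = match)
}

#' Run a binary case/reference study end to end
#'
#' Fixed stage order: (simulate, when `config$sim` is set) -> LOF quality
#' control on water-corrected, masked, unnormalized features -> full
#' preprocessing -> covariate matching -> repeated stratified cross-validated
#' linear-SVM evaluation -> per-wavenumber statistics. QC runs before matching
#' so that removed spectra never consume references; matching happens once,
#' before cross-validation, as it uses only covariates and never the spectra.
#'
#' @param config A `study_config`.
#' @param cohort Optional measured `cohort` (otherwise simulated from
#'   `config$sim`).
#' @return List of class `"study_report"`: cohort sizes before/after QC and
#'   matching, `balance`, `evaluation` (a `cv_evaluation`), `stats` (a
#'   `wavenumber_stats` table), `config`.
#' @export
run_binary_study <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "study_config"))
  prep <- prepare_study_cohort(config, cohort)
  co <- prep$cohort
  ev <- with_stage("evaluate",
                   cv_evaluate(co$spectra, co$meta$group, positive = "case",
                               folds = config$folds, repeats = config$repeats,
                               seed = config$seed, C = config$C))
  st <- with_stage("stats", wavenumber_stats(co))
  structure(list(n_raw = prep$n_raw,
                 n_after_qc = prep$n_raw - length(prep$flagged),
                 n_analysed = nrow(co$spectra),
                 flagged = prep$flagged,
                 balance = prep$balance,
                 evaluation = ev,
                 stats = st,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d -> %d (QC) -> %d (matched) samples\n",
              x$n_raw, x$n_after_qc, x$n_analysed))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}

#' Run a multiclass study end to end
#'
#' As [run_binary_study()] but for three or more diagnosis groups, evaluated
#' with one-vs-one linear SVMs ([multiclass_cv()]). The matching and
#' differential-fingerprint stages are skipped (they are defined for binary
#' case/reference contrasts); QC still precedes evaluation.
#'
#' @param config A `study_config` (matching fields ignored).
#' @param cohort A `cohort` whose `meta$group` has >= 3 levels.
#' @return List of class `"study_report_multiclass"` with the confusion
#'   summary.
#' @export
run_multiclass_study <- function(config, cohort) {
  stopifnot(inherits(config, "study_config"), inherits(cohort, "cohort"))
  if (length(unique(cohort$meta$group)) < 3) {
    stop("multiclass study requires at least 3 groups")
  }
  n_raw <- nrow(cohort$spectra)
  flagged <- character(0)
  if (!is.na(config$qc_k) && n_raw > config$qc_k) {
    flagged <- with_stage("qc", qc_flagged_ids(cohort, config))
    if (length(flagged) > 0) {
      cohort <- cohort_subset(cohort, !(cohort$meta$sample_id %in% flagged))
    }
  }
  pp <- with_stage("preprocess", apply_pipeline(cohort, config$preprocess))
  ev <- with_stage("evaluate",
                   multiclass_cv(pp$spectra, pp$meta$group,
                                 folds = config$folds,
                                 repeats = config$repeats,
                                 seed = config$seed, C = config$C))
  structure(list(n_raw = n_raw,
                 n_analysed = nrow(pp$spectra),
                 flagged = flagged,
                 evaluation = ev,
                 config = config),
            class = "study_report_multiclass")
}

#' @export
print.study_report_multiclass <- function(x, ...) {
  cat(sprintf("<study_report_multiclass> %d -> %d samples\n",
              x$n_raw, x$n_analysed))
  print(x$evaluation)
  invisible(x)
}

#' Stage-stratified or variant comparison runs
#'
#' Runs one binary evaluation per stratum of a metadata variable (e.g. tumour
#' T class: the cases of each stratum against the full reference pool,
#' re-matched per stratum), or one evaluation per preprocessing variant on the
#' same cohort. Strata with fewer cases than the fold count are skipped with a
#' warning. Emits a comparison table.
#'
#' @param config A `study_config`.
#' @param cohort A `cohort` (simulated from `config$sim` when `NULL`).
#' @param stratify_by Metadata column defining case strata (default
#'   `"t_class"`), or `NULL` when `variants` is given.
#' @param variants Optional named list of `preprocess_config`s to compare
#'   instead of stratifying.
#' @return `data.frame`: `stratum`, `n_cases`, `n_refs`, `auc_mean`,
#'   `auc_sd`, `area_abs_diff`; attribute `reports` holds the full
#'   `study_report` objects.
#' @export
run_stage_comparison <- function(config, cohort = NULL,
                                 stratify_by = "t_class", variants = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(cohort)) {
    if (is.null(config$sim)) stop("either a cohort or a sim config is required")
    cohort <- generate_cohort(config$sim, config$signature)$cohort
  }
  rows <- list()
  reports <- list()

  if (!is.null(variants)) {
    for (nm in names(variants)) {
      cfg <- config
      cfg$preprocess <- variants[[nm]]
      rep <- run_binary_study(cfg, cohort)
      rows[[nm]] <- data.frame(stratum = nm,
                               n_cases = attr(rep$stats, "n1"),
                               n_refs = attr(rep$stats, "n2"),
                               auc_mean = rep$evaluation$auc_mean,
                               auc_sd = rep$evaluation$auc_sd,
                               area_abs_diff = attr(rep$stats, "area_abs_diff"))
      reports[[nm]] <- rep
    }
  } else {
    if (!stratify_by %in% names(cohort$meta)) {
      stop("stratifying variable '", stratify_by, "' not in metadata")
    }
    strata <- sort(unique(stats::na.omit(
      cohort$meta[[stratify_by]][cohort$meta$group == "case"])))
    for (sv in strata) {
      keep <- cohort$meta$group == "reference" |
        (cohort$meta$group == "case" &
           !is.na(cohort$meta[[stratify_by]]) &
           cohort$meta[[stratify_by]] == sv)
      sub <- cohort_subset(cohort, keep)
      n_case <- sum(sub$meta$group == "case")
      if (n_case < config$folds) {
        warning(sprintf("stratum '%s' has %d cases (< %d folds); skipped",
                        sv, n_case, config$folds))
        next
      }
      rep <- run_binary_study(config, sub)
      rows[[as.character(sv)]] <-
        data.frame(stratum = as.character(sv),
                   n_cases = attr(rep$stats, "n1"),
                   n_refs = attr(rep$stats, "n2"),
                   auc_mean = rep$evaluation$auc_mean,
                   auc_sd = rep$evaluation$auc_sd,
                   area_abs_diff = attr(rep$stats, "area_abs_diff"))
      reports[[as.character(sv)]] <- rep
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Write a study report as JSON
#'
#' Serializes the headline numbers of a study report (cohort sizes, balance
#' table, AUC statistics, operating points, area under the absolute
#' differential fingerprint) for downstream consumption.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  ev <- report$evaluation
  out <- list(n_raw = report$n_raw,
              n_after_qc = report$n_after_qc,
              n_analysed = report$n_analysed,
              auc_mean = ev$auc_mean,
              auc_sd = ev$auc_sd,
              pooled_auc = ev$pooled_auc,
              sensitivity = ev$operating_point$sensitivity,
              specificity = ev$operating_point$specificity,
              sens_at_95spec = ev$sens_at_95spec,
              area_abs_diff = attr(report$stats, "area_abs_diff"),
              balance = report$balance,
              seed = report$config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
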