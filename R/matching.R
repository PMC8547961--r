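#' Propensity-score model for case/reference membership
#'
#' Logistic regression of group membership (case = 1) on age, sex and BMI,
#' fitted by maximum likelihood. The fitted probabilities ("propensity
#' scores") and their logits are used to define matching calipers.
#'
#' @param meta `data.frame` with columns `group` ("case"/"reference"), `age`,
#'   `sex` (0/1), `bmi`.
#' @param covariates Character vector of covariate column names.
#' @return List: `propensity` (in (0,1)), `logit`, `model` (the `glm` fit),
#'   all aligned with the rows of `meta`.
#' @export
fit_propensity <- function(meta, covariates = c("age", "sex", "bmi")) {
  stopifnot(all(covariates %in% names(meta)), "group" %in% names(meta))
  y <- as.integer(meta$group == "case")
  if (length(unique(y)) < 2) stop("both groups must be present")
  X <- meta[, covariates, drop = FALSE]
  if (any(!is.finite(as.matrix(X)))) stop("covariates must be finite")
  dat <- cbind(data.frame(.y = y), X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::reformulate(covariates, ".y"), data = dat,
               family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  p <- stats::fitted(fit)
  if (sep || any(p < 1e-10) || any(p > 1 - 1e-10)) {
    stop("propensity model is (quasi-)separated; covariates predict group ",
         "membership perfectly - consider matching without calipers")
  }
  list(propensity = as.numeric(p),
       logit = as.numeric(stats::qlogis(p)),
       model = fit)
}

#' Case-by-reference Mahalanobis distance matrix
#'
#' `D[i, j] = sqrt((x_i - x_j)' S^-1 (x_i - x_j))` with `S` the pooled
#' within-group covariance of the covariates.
#'
#' @inheritParams fit_propensity
#' @return Numeric matrix, rows = cases, columns = references, dimnames set to
#'   sample ids when available.
#' @export
mahalanobis_matrix <- function(meta, covariates = c("age", "sex", "bmi")) {
  is_case <- meta$group == "case"
  Xc <- as.matrix(meta[is_case, covariates, drop = FALSE])
  Xr <- as.matrix(meta[!is_case, covariates, drop = FALSE])
  if (nrow(Xc) == 0 || nrow(Xr) == 0) stop("both groups must be non-empty")
  n1 <- nrow(Xc); n2 <- nrow(Xr)
  S <- ((n1 - 1) * stats::cov(Xc) + (n2 - 1) * stats::cov(Xr)) / (n1 + n2 - 2)
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop("pooled covariance is singular; drop a constant covariate ",
         "before matching")
  })
  # d^2 = qc_i + qr_j - 2 * Xc Sinv Xr'
  qc <- rowSums((Xc %*% Sinv) * Xc)
  qr <- rowSums((Xr %*% Sinv) * Xr)
  cross <- Xc %*% Sinv %*% t(Xr)
  d2 <- outer(qc, qr, "+") - 2 * cross
  d2[d2 < 0] <- 0 # numerical guard
  D <- sqrt(d2)
  if (!is.null(meta$sample_id)) {
    dimnames(D) <- list(meta$sample_id[is_case], meta$sample_id[!is_case])
  }
  D
}

# Rectangular min-cost assignment (rows <= columns) by shortest augmenting
# paths with potentials (Jonker-Volgenant style, O(n^2 m)). Returns for each
# row the assigned column index.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n >= 1, n <= m, all(is.finite(cost)))
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)       # p[j]: row assigned to column j, 0 = free
  way <- integer(m)
  virt <- m + 1L
  for (i in seq_len(n)) {
    p[virt] <- i
    j0 <- virt
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(m)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        fi <- free[upd]
        minv[fi] <- cur[upd]
        way[fi] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      uj <- which(used)
      u[p[uj]] <- u[p[uj]] + delta
      v[uj] <- v[uj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == virt) break
    }
    p[virt] <- 0L
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

#' Optimal 1:1 pair matching within propensity-score calipers
#'
#' Among all one-to-one case/reference assignments using only pairs whose
#' logit-propensity difference does not exceed the caliper, returns an
#' assignment of maximum cardinality minimizing the total Mahalanobis
#' distance. Solved as a rectangular assignment problem in which out-of-
#' caliper pairs carry a large finite penalty and each case has a dummy
#' "unmatched" column; penalized assignments are verified and stripped, so
#' every returned pair satisfies the caliper and each reference is used at
#' most once. Ties are broken deterministically by sample-id order.
#'
#' @param D Case-by-reference distance matrix (see [mahalanobis_matrix()]).
#' @param logit_case,logit_ref Logit propensities aligned with the rows /
#'   columns of `D`.
#' @param caliper_sd_mult Caliper width as a multiple of the SD of the pooled
#'   logit propensity (default 0.2, the common observational-studies
#'   convention); `Inf` disables the caliper.
#' @return List of class `"match_result"`: `pairs` (`data.frame` with
#'   `case_id`, `ref_id`, `distance`), `total_distance`, `caliper` (absolute
#'   width on the logit scale), `unmatched` (case ids).
#' @export
optimal_pair_match <- function(D, logit_case, logit_ref, caliper_sd_mult = 0.2) {
  optimal_multi_ref_match(D, logit_case, logit_ref,
                          caliper_sd_mult = caliper_sd_mult, k = 1)
}

#' Optimal 1:k matching with multiple references
#'
#' Each matched case is assigned exactly `k` distinct references; solved by
#' replicating each case `k` times in the assignment problem. `k = 1` reduces
#' to [optimal_pair_match()]. Cases for which fewer than `k` admissible
#' references can be secured are reported unmatched.
#'
#' @inheritParams optimal_pair_match
#' @param k References per case.
#' @return A `match_result`; `pairs` holds `k` rows per matched case.
#' @export
optimal_multi_ref_match <- function(D, logit_case, logit_ref,
                                    caliper_sd_mult = 0.2, k = 1) {
  D <- as.matrix(D)
  nc <- nrow(D); nr <- ncol(D)
  stopifnot(length(logit_case) == nc, length(logit_ref) == nr, k >= 1)
  if (nr < k) stop("not enough references for 1:", k, " matching")
  case_ids <- rownames(D); ref_ids <- colnames(D)
  if (is.null(case_ids)) case_ids <- sprintf("case%03d", seq_len(nc))
  if (is.null(ref_ids)) ref_ids <- sprintf("ref%03d", seq_len(nr))
  # deterministic tie-break: order by sample id
  co <- order(case_ids); ro <- order(ref_ids)
  D <- D[co, ro, drop = FALSE]
  case_ids <- case_ids[co]; ref_ids <- ref_ids[ro]
  logit_case <- logit_case[co]; logit_ref <- logit_ref[ro]

  sd_logit <- stats::sd(c(logit_case, logit_ref))
  caliper <- if (is.finite(caliper_sd_mult)) caliper_sd_mult * sd_logit else Inf
  adm <- abs(outer(logit_case, logit_ref, "-")) <= caliper
  if (!any(adm)) stop("no admissible case/reference pair under the caliper")

  max_adm <- max(D[adm], 1)
  dummy_cost <- (max_adm + 1) * (nc * k + 1)
  forbid_cost <- 2 * dummy_cost * (nc * k + 1)

  cost_real <- D
  cost_real[!adm] <- forbid_cost
  rows <- matrix(rep(seq_len(nc), each = k), ncol = 1)[, 1]
  big <- cbind(cost_real[rows, , drop = FALSE],
               matrix(dummy_cost, nc * k, nc * k))
  assign <- solve_assignment(big)

  pairs <- data.frame(case_id = character(0), ref_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  unmatched <- character(0)
  for (ci in seq_len(nc)) {
    reps <- which(rows == ci)
    cols <- assign[reps]
    ok <- cols <= nr & vapply(cols, function(j) j <= nr && adm[ci, j], logical(1))
    if (all(ok)) {
      pairs <- rbind(pairs, data.frame(case_id = case_ids[ci],
                                       ref_id = ref_ids[cols],
                                       distance = D[ci, cols],
                                       stringsAsFactors = FALSE))
    } else {
      unmatched <- c(unmatched, case_ids[ci])
    }
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 total_distance = sum(pairs$distance),
                 caliper = caliper,
                 k = k,
                 unmatched = unmatched),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs (1:%d), total distance %.4g, caliper %.4g; %d unmatched\n",
              nrow(x$pairs), x$k, x$total_distance, x$caliper,
              length(x$unmatched)))
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference (SMD) per covariate:
#' `(mean_case - mean_ref) / pooled SD`, with the pooled SD
#' `sqrt((var_case + var_ref) / 2)` taken from the full (pre-match) sample for
#' both columns, the usual convention for balance diagnostics.
#'
#' @inheritParams fit_propensity
#' @param match A `match_result`.
#' @return `data.frame`: `covariate`, `smd_before`, `smd_after`.
#' @export
balance_table <- function(meta, match, covariates = c("age", "sex", "bmi")) {
  stopifnot(inherits(match, "match_result"))
  if (nrow(match$pairs) == 0) stop("match result is empty")
  is_case <- meta$group == "case"
  mc <- match(match$pairs$case_id, meta$sample_id)
  mr <- match(match$pairs$ref_id, meta$sample_id)
  out <- data.frame(covariate = covariates,
                    smd_before = NA_real_, smd_after = NA_real_)
  for (i in seq_along(covariates)) {
    v <- meta[[covariates[i]]]
    sd_pool <- sqrt((stats::var(v[is_case]) + stats::var(v[!is_case])) / 2)
    db <- mean(v[is_case]) - mean(v[!is_case])
    da <- mean(v[mc]) - mean(v[mr])
    if (sd_pool == 0) {
      if (abs(db) > 0 || abs(da) > 0) {
        stop("zero pooled SD with unequal means for covariate ", covariates[i])
      }
      out$smd_before[i] <- 0
      out$smd_after[i] <- 0
    } else {
      out$smd_before[i] <- db / sd_pool
      out$smd_after[i] <- da / sd_pool
    }
  }
  out
}

#' Match a cohort on its metadata covariates
#'
#' Full matching stage: fits the propensity model, builds the Mahalanobis
#' distance matrix, solves the optimal 1:k matching under the caliper, and
#' returns the balanced sub-cohort (matched cases + their references).
#'
#' @param x A `cohort` whose metadata has `group`, `age`, `sex`, `bmi`.
#' @param caliper_sd_mult Caliper width multiplier (see
#'   [optimal_pair_match()]).
#' @param k References per case.
#' @param covariates Covariate columns used for both the propensity model and
#'   the Mahalanobis distance.
#' @return List: `cohort` (matched samples only), `match` (`match_result`),
#'   `balance` (from [balance_table()]).
#' @export
match_cohort <- function(x, caliper_sd_mult = 0.2, k = 1,
                         covariates = c("age", "sex", "bmi")) {
  stopifnot(inherits(x, "cohort"))
  prop <- fit_propensity(x$meta, covariates)
  D <- mahalanobis_matrix(x$meta, covariates)
  is_case <- x$meta$group == "case"
  res <- optimal_multi_ref_match(D, prop$logit[is_case], prop$logit[!is_case],
                                 caliper_sd_mult = caliper_sd_mult, k = k)
  bal <- balance_table(x$meta, res, covariates)
  keep <- x$meta$sample_id %in% c(res$pairs$case_id, res$pairs$ref_id)
  list(cohort = cohort_subset(x, keep), match = res, balance = bal)
}

#' Write matched pairs to CSV
#'
#' @param match A `match_result`.
#' @param path Output CSV path (`case_id, ref_id, distance`).
#' @export
write_pairs_csv <- function(match, path) {
  utils::write.csv(match$pairs, path, row.names = FALSE)
  invisible(path)
}
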