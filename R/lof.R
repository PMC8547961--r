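#' Local outlier factor scores
#'
#' Classical LOF (density-ratio anomaly score based on k-nearest-neighbour
#' reachability distances): for each point, the k-distance is the distance to
#' its k-th nearest neighbour; the neighbourhood N_k contains every other
#' point not farther than the k-distance (so distance ties at the k-th
#' neighbour are all included); the reachability distance from p to o is
#' `max(k_distance(o), d(p, o))`; the local reachability density (lrd) is the
#' reciprocal mean reachability distance over N_k; and the LOF score is the
#' mean ratio of the neighbours' lrd to the point's own lrd. Scores near 1
#' indicate inliers.
#'
#' Zero distances (duplicated points) are handled by the reachability-distance
#' construction itself; in the degenerate case of more than k exact copies
#' (infinite lrd), the ratio of two infinite densities is taken as 1 so all
#' scores stay finite.
#'
#' @param X Numeric matrix, one row per sample (Euclidean metric on rows);
#'   typically the preprocessed (water-corrected, masked, normalized) spectra.
#' @param k Neighbour count, default 20; requires `nrow(X) >= k + 1`.
#' @return List of class `"lof_result"`: `scores` (named by rownames of `X`
#'   when present), `k`.
#' @export
lof_scores <- function(X, k = 20) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= k) stop("LOF requires more samples than neighbours (n > k)")
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf

  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    ds <- D[i, ]
    kdist[i] <- sort(ds, partial = k)[k]
    nbrs[[i]] <- which(ds <= kdist[i])
  }

  lrd <- numeric(n)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    reach <- pmax(kdist[nb], D[i, nb])
    m <- mean(reach)
    lrd[i] <- if (m > 0) 1 / m else Inf
  }

  scores <- numeric(n)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    if (is.infinite(lrd[i])) {
      # own density infinite: neighbours with infinite density tie at ratio 1,
      # finite-density neighbours contribute ratio 0
      scores[i] <- mean(ifelse(is.infinite(lrd[nb]), 1, 0))
    } else {
      scores[i] <- mean(lrd[nb]) / lrd[i]
    }
  }
  names(scores) <- rownames(X)
  structure(list(scores = scores, k = k), class = "lof_result")
}

#' Flag outliers from LOF scores
#'
#' Exactly one rule must be chosen: a fixed score cutoff (`cutoff`, flagging
#' `score > cutoff`) or a top-fraction rule (`top_fraction`, flagging the
#' `round(q * n)` highest scores, ties broken by sample id). When neither is
#' given the default cutoff 1.5 is used.
#'
#' @param result A `lof_result`.
#' @param cutoff Fixed score threshold.
#' @param top_fraction Fraction `q` in `[0, 1)` of samples to flag.
#' @return List: `flagged` (character ids, or integer indices when `X` had no
#'   rownames) and `rule` (human-readable provenance string).
#' @export
flag_outliers <- function(result, cutoff = NULL, top_fraction = NULL) {
  stopifnot(inherits(result, "lof_result"))
  if (!is.null(cutoff) && !is.null(top_fraction)) {
    stop("specify either cutoff or top_fraction, not both")
  }
  scores <- result$scores
  ids <- if (is.null(names(scores))) as.character(seq_along(scores)) else names(scores)
  if (!is.null(top_fraction)) {
    stopifnot(top_fraction >= 0, top_fraction < 1)
    m <- round(top_fraction * length(scores))
    ord <- order(-scores, ids)
    flagged <- ids[ord[seq_len(m)]]
    rule <- sprintf("top_fraction=%g (m=%d)", top_fraction, m)
  } else {
    if (is.null(cutoff)) cutoff <- 1.5
    flagged <- ids[scores > cutoff]
    rule <- sprintf("score > %g", cutoff)
  }
  list(flagged = flagged, rule = rule)
}

#' Run spectral QC on a cohort
#'
#' Convenience wrapper: LOF scores on the cohort's (typically preprocessed)
#' spectra, flagging, and removal.
#'
#' @param x A `cohort`.
#' @param k LOF neighbour count.
#' @param cutoff,top_fraction Flagging rule, see [flag_outliers()].
#' @return List: `cohort` (flagged samples removed), `scores`, `flagged`,
#'   `rule`.
#' @export
qc_cohort <- function(x, k = 20, cutoff = NULL, top_fraction = NULL) {
  stopifnot(inherits(x, "cohort"))
  res <- lof_scores(x$spectra, k = k)
  fl <- flag_outliers(res, cutoff = cutoff, top_fraction = top_fraction)
  keep <- !(x$meta$sample_id %in% fl$flagged)
  list(cohort = cohort_subset(x, keep), scores = res$scores,
       flagged = fl$flagged, rule = fl$rule)
}

#' Write QC scores to CSV
#'
#' @param qc Output of [qc_cohort()].
#' @param path Output CSV path (`sample_id, lof, flagged`).
#' @export
write_qc_csv <- function(qc, path) {
  utils::write.csv(data.frame(sample_id = names(qc$scores),
                              lof = as.numeric(qc$scores),
                              flagged = names(qc$scores) %in% qc$flagged),
                   path, row.names = FALSE)
  invisible(path)
}
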