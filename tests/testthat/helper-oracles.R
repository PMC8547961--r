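# Independent brute-force oracles, coded directly from the definitions.

# LOF by direct definition: explicit per-point scans, no shared code with the
# package implementation.
lof_oracle <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- d(i, j)
  kdist <- numeric(n)
  for (i in 1:n) {
    others <- sort(D[i, -i])
    kdist[i] <- others[k]
  }
  neigh <- function(i) setdiff(which(D[i, ] <= kdist[i]), i)
  lrd <- numeric(n)
  for (i in 1:n) {
    nb <- neigh(i)
    total <- 0
    for (o in nb) total <- total + max(kdist[o], D[i, o])
    lrd[i] <- if (total > 0) length(nb) / total else Inf
  }
  scores <- numeric(n)
  for (i in 1:n) {
    nb <- neigh(i)
    if (is.infinite(lrd[i])) {
      scores[i] <- mean(ifelse(is.infinite(lrd[nb]), 1, 0))
    } else {
      scores[i] <- mean(lrd[nb]) / lrd[i]
    }
  }
  scores
}

# Mann-Whitney AUC by explicit enumeration of all case/reference pairs.
auc_pair_oracle <- function(cases, refs) {
  u <- 0
  for (x in cases) for (y in refs) {
    if (x > y) u <- u + 1 else if (x == y) u <- u + 0.5
  }
  u / (length(cases) * length(refs))
}

# Maximum-cardinality, then minimum-total-distance matching by exhaustive
# search over admissible case->reference injections.
match_oracle <- function(D, adm) {
  nc <- nrow(D); nr <- ncol(D)
  best_size <- -1L
  best_dist <- Inf
  used <- rep(FALSE, nr)
  rec <- function(ci, size, dist) {
    if (size + (nc - ci + 1) < best_size) return()
    if (ci > nc) {
      if (size > best_size ||
          (size == best_size && dist < best_dist - 1e-12)) {
        best_size <<- size
        best_dist <<- dist
      }
      return()
    }
    for (j in seq_len(nr)) {
      if (!used[j] && adm[ci, j]) {
        used[j] <<- TRUE
        rec(ci + 1L, size + 1L, dist + D[ci, j])
        used[j] <<- FALSE
      }
    }
    rec(ci + 1L, size, dist) # case ci left unmatched
  }
  rec(1L, 0L, 0)
  list(size = best_size, dist = best_dist)
}

# 1:k matching oracle: every case gets exactly k distinct references or is
# unmatched; maximize matched cases, then minimize total distance.
multi_match_oracle <- function(D, adm, k) {
  nc <- nrow(D); nr <- ncol(D)
  best_size <- -1L
  best_dist <- Inf
  combos <- function(v, k) if (k == 0) list(integer(0)) else utils::combn(v, k, simplify = FALSE)
  rec <- function(ci, used, size, dist) {
    if (ci > nc) {
      if (size > best_size ||
          (size == best_size && dist < best_dist - 1e-12)) {
        best_size <<- size
        best_dist <<- dist
      }
      return()
    }
    ok <- setdiff(which(adm[ci, ]), used)
    if (length(ok) >= k) {
      for (cmb in combos(ok, k)) {
        rec(ci + 1L, c(used, cmb), size + 1L, dist + sum(D[ci, cmb]))
      }
    }
    rec(ci + 1L, used, size, dist)
  }
  rec(1L, integer(0), 0L, 0)
  list(size = best_size, dist = best_dist)
}

# Greedy nearest-neighbour matching (sequential, cases in row order).
greedy_match <- function(D, adm) {
  nr <- ncol(D)
  used <- rep(FALSE, nr)
  total <- 0
  for (i in seq_len(nrow(D))) {
    cand <- which(adm[i, ] & !used)
    if (length(cand) == 0) next
    j <- cand[which.min(D[i, cand])]
    used[j] <- TRUE
    total <- total + D[i, j]
  }
  total
}

# Exhaustive search over all score thresholds for ROC operating points.
exhaustive_operating_points <- function(scores, labels, positive) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- labels == positive
  res <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(sens = sum(pred & pos) / sum(pos),
      spec = sum(!pred & !pos) / sum(!pos))
  }, c(sens = 0, spec = 0)))
  data.frame(threshold = thr, sens = res[, 1], spec = res[, 2])
}

# Small deterministic test cohort built from the generator.
make_test_cohort <- function(n_cases = 30, n_refs = 30, seed = 42,
                             signature = NULL, confounding = 0, ...) {
  cfg <- sim_config(n_cases = n_cases, n_refs = n_refs, seed = seed,
                    covariate_confounding = confounding, ...)
  generate_cohort(cfg, signature)
}
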