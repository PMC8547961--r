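make_meta <- function(n_case, n_ref, seed = 1, age_shift = 0, sex_shift = 0,
                      bmi_shift = 0) {
  set.seed(seed)
  n <- n_case + n_ref
  grp <- c(rep("case", n_case), rep("reference", n_ref))
  data.frame(sample_id = sprintf("m%03d", 1:n),
             group = grp,
             age = stats::rnorm(n, 60, 10) + ifelse(grp == "case", age_shift, 0),
             sex = stats::rbinom(n, 1, pmin(0.95, 0.5 + ifelse(grp == "case", sex_shift, 0))),
             bmi = stats::rnorm(n, 26, 4) + ifelse(grp == "case", bmi_shift, 0),
             stringsAsFactors = FALSE)
}

test_that("propensity model matches an independent Newton-Raphson logistic fit", {
  # identical covariate distributions: propensities collapse to the case fraction
  meta <- make_meta(40, 60, seed = 2)
  p <- fit_propensity(meta)
  expect_true(all(p$propensity > 0 & p$propensity < 1))
  expect_equal(mean(p$propensity), 0.4, tolerance = 0.02)
  expect_equal(p$logit, stats::qlogis(p$propensity), tolerance = 1e-10)

  # worked 6-sample table with a strong (but overlapping) age shift
  meta6 <- data.frame(sample_id = paste0("s", 1:6),
                      group = rep(c("case", "reference"), each = 3),
                      age = c(70, 62, 55, 50, 58, 66),
                      sex = c(1, 0, 1, 1, 0, 0),
                      bmi = c(27, 29, 25, 26, 24, 28))
  p6 <- fit_propensity(meta6, covariates = "age")
  expect_true(all(diff(p6$propensity[order(meta6$age)]) > 0)) # monotone in age

  # independent Newton-Raphson oracle for the age-only logistic model
  X <- cbind(1, meta6$age)
  y <- as.integer(meta6$group == "case")
  b <- c(0, 0)
  for (it in 1:50) {
    eta <- X %*% b
    mu <- 1 / (1 + exp(-eta))
    W <- diag(as.numeric(mu * (1 - mu)))
    b <- b + solve(t(X) %*% W %*% X, t(X) %*% (y - mu))
  }
  expect_equal(unname(stats::coef(p6$model)), as.numeric(b), tolerance = 1e-6)

  # determinism
  p6b <- fit_propensity(meta6, covariates = "age")
  expect_equal(stats::coef(p6$model), stats::coef(p6b$model), tolerance = 1e-8)

  # perfect separation is reported, not silently fitted
  sep <- data.frame(sample_id = paste0("s", 1:8),
                    group = rep(c("case", "reference"), each = 4),
                    age = c(80, 81, 82, 83, 40, 41, 42, 43),
                    sex = rep(0:1, 4), bmi = rep(25, 8))
  expect_error(fit_propensity(sep), "separated")
})

test_that("Mahalanobis distances match a direct solve-based oracle", {
  meta <- make_meta(4, 4, seed = 3)
  D <- mahalanobis_matrix(meta)
  cov_cols <- c("age", "sex", "bmi")
  Xc <- as.matrix(meta[meta$group == "case", cov_cols])
  Xr <- as.matrix(meta[meta$group == "reference", cov_cols])
  S <- (3 * stats::cov(Xc) + 3 * stats::cov(Xr)) / 6
  for (i in 1:4) for (j in 1:4) {
    d <- Xc[i, ] - Xr[j, ]
    expect_equal(D[i, j], sqrt(sum(d * solve(S, d))), tolerance = 1e-10)
  }
  # identical covariates give zero distance
  meta$age[5] <- meta$age[1]; meta$sex[5] <- meta$sex[1]; meta$bmi[5] <- meta$bmi[1]
  D2 <- mahalanobis_matrix(meta)
  expect_equal(D2[1, 1], 0, tolerance = 1e-8)

  const <- make_meta(4, 4, seed = 3)
  const$bmi <- 25
  expect_error(mahalanobis_matrix(const), "singular")
})

test_that("identity-covariance sanity check for the Mahalanobis form", {
  # x = (1,0,0) vs origin with S = I gives distance 1; construct a reference
  # group whose covariance is the identity by explicit whitening, plus two
  # cases whose within-group covariance contribution is negligible
  set.seed(6)
  Z <- matrix(stats::rnorm(200 * 3), ncol = 3)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  W <- chol(solve(stats::cov(Z)))
  Zw <- Z %*% t(W) # cov(Zw) = I
  meta <- data.frame(sample_id = sprintf("w%03d", 1:203),
                     group = c("case", "case", "reference", rep("reference", 200)),
                     age = c(1, 1 + 1e-6, 0, Zw[, 1]),
                     sex = c(0, 0, 0, Zw[, 2]),
                     bmi = c(0, 0, 0, Zw[, 3]))
  D <- mahalanobis_matrix(meta)
  expect_equal(unname(D[1, 1]), 1, tolerance = 0.05)
})

test_that("optimal matching equals exhaustive search on small instances", {
  set.seed(10)
  for (trial in 1:25) {
    nc <- sample(2:7, 1)
    nr <- sample(nc:7, 1)
    D <- matrix(stats::runif(nc * nr, 0, 10), nc, nr,
                dimnames = list(sprintf("c%02d", 1:nc), sprintf("r%02d", 1:nr)))
    lc <- stats::rnorm(nc); lr <- stats::rnorm(nr)
    mult <- sample(c(0.5, 1, Inf), 1)
    res <- tryCatch(optimal_pair_match(D, lc, lr, caliper_sd_mult = mult),
                    error = function(e) NULL)
    adm <- abs(outer(lc, lr, "-")) <=
      (if (is.finite(mult)) mult * stats::sd(c(lc, lr)) else Inf)
    if (is.null(res)) {
      expect_false(any(adm))
      next
    }
    oracle <- match_oracle(D, adm)
    expect_equal(nrow(res$pairs), oracle$size)
    expect_equal(res$total_distance, oracle$dist, tolerance = 1e-9)
    # feasibility: caliper satisfied, references unique, cases unique
    ci <- match(res$pairs$case_id, rownames(D))
    ri <- match(res$pairs$ref_id, colnames(D))
    expect_true(all(adm[cbind(ci, ri)]))
    expect_false(any(duplicated(ri)))
    expect_false(any(duplicated(ci)))
  }
})

test_that("exact covariate twins are matched at zero distance", {
  meta <- make_meta(3, 6, seed = 12)
  meta[meta$group == "reference", c("age", "sex", "bmi")][1:3, ] <-
    meta[meta$group == "case", c("age", "sex", "bmi")]
  prop <- fit_propensity(meta)
  D <- mahalanobis_matrix(meta)
  res <- optimal_pair_match(D, prop$logit[meta$group == "case"],
                            prop$logit[meta$group == "reference"])
  expect_equal(nrow(res$pairs), 3)
  expect_equal(res$total_distance, 0, tolerance = 1e-8)
})

test_that("optimal matching never exceeds greedy nearest-neighbour cost", {
  set.seed(14)
  for (trial in 1:50) {
    nc <- sample(3:6, 1); nr <- nc + sample(1:3, 1)
    D <- matrix(stats::runif(nc * nr, 0, 10), nc, nr)
    lc <- stats::rnorm(nc); lr <- stats::rnorm(nr)
    res <- optimal_pair_match(D, lc, lr, caliper_sd_mult = Inf)
    adm <- matrix(TRUE, nc, nr)
    expect_lte(res$total_distance, greedy_match(D, adm) + 1e-9)
  }
})

test_that("multi-reference matching reduces to pairs at k=1 and matches its oracle", {
  set.seed(16)
  D <- matrix(stats::runif(2 * 5, 0, 10), 2, 5)
  lc <- stats::rnorm(2); lr <- stats::rnorm(5)
  r1 <- optimal_pair_match(D, lc, lr, caliper_sd_mult = Inf)
  rk <- optimal_multi_ref_match(D, lc, lr, caliper_sd_mult = Inf, k = 1)
  expect_equal(r1$pairs, rk$pairs)
  expect_equal(r1$total_distance, rk$total_distance)

  r2 <- optimal_multi_ref_match(D, lc, lr, caliper_sd_mult = Inf, k = 2)
  oracle <- multi_match_oracle(D, matrix(TRUE, 2, 5), 2)
  expect_equal(nrow(r2$pairs), 4)
  expect_equal(r2$total_distance, oracle$dist, tolerance = 1e-9)
  expect_false(any(duplicated(r2$pairs$ref_id)))

  # degenerate tie: all distances equal, total is forced
  De <- matrix(2, 2, 5)
  re <- optimal_multi_ref_match(De, rep(0, 2), rep(0, 5),
                                caliper_sd_mult = Inf, k = 2)
  expect_equal(re$total_distance, 2 * 2 * 2)
  expect_error(optimal_multi_ref_match(D, lc, lr, k = 6), "not enough")
})

test_that("balance diagnostics: twins give zero SMD, swap flips sign, matching improves balance", {
  meta <- make_meta(20, 40, seed = 18)
  meta[meta$group == "reference", c("age", "sex", "bmi")][1:20, ] <-
    meta[meta$group == "case", c("age", "sex", "bmi")]
  prop <- fit_propensity(meta)
  D <- mahalanobis_matrix(meta)
  res <- optimal_pair_match(D, prop$logit[meta$group == "case"],
                            prop$logit[meta$group == "reference"])
  bal <- balance_table(meta, res)
  expect_equal(bal$smd_after, rep(0, 3), tolerance = 1e-12)

  # antisymmetry under group swap (balance can only change when there is a
  # surplus of references to choose from, hence 30 cases vs 60 references)
  meta2 <- make_meta(30, 60, seed = 19, age_shift = 5)
  swap <- meta2
  swap$group <- ifelse(meta2$group == "case", "reference", "case")
  p2 <- fit_propensity(meta2)
  D2 <- mahalanobis_matrix(meta2)
  r2 <- optimal_pair_match(D2, p2$logit[meta2$group == "case"],
                           p2$logit[meta2$group == "reference"])
  b2 <- balance_table(meta2, r2)
  ps <- fit_propensity(swap)
  Ds <- mahalanobis_matrix(swap)
  rs <- optimal_multi_ref_match(Ds, ps$logit[swap$group == "case"],
                                ps$logit[swap$group == "reference"],
                                caliper_sd_mult = Inf, k = 1)
  bs <- balance_table(swap, rs)
  expect_equal(bs$smd_before, -b2$smd_before, tolerance = 1e-10)

  # confounded cohort: matching shrinks the age imbalance
  expect_lt(abs(b2$smd_after[b2$covariate == "age"]),
            abs(b2$smd_before[b2$covariate == "age"]))
})

test_that("matching improves mean covariate balance across many confounded cohorts", {
  set.seed(20)
  improved <- logical(40)
  for (i in seq_along(improved)) {
    meta <- make_meta(40, 80, seed = 100 + i, age_shift = 5,
                      sex_shift = 0.1, bmi_shift = 1.5)
    prop <- fit_propensity(meta)
    D <- mahalanobis_matrix(meta)
    res <- optimal_pair_match(D, prop$logit[meta$group == "case"],
                              prop$logit[meta$group == "reference"])
    bal <- balance_table(meta, res)
    improved[i] <- mean(abs(bal$smd_after)) < mean(abs(bal$smd_before))
  }
  # sign test: under no effect, P(improved) = 0.5; observing >= 35/40
  # successes has p < 1e-6
  expect_gte(sum(improved), 35)
})
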