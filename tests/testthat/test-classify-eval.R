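test_that("linear SVM separates separable data and cannot solve XOR", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(-1, -1, -1, 1, 1, 1)
  m <- train_linear_svm(X, y)
  expect_equal(mean(predict_labels(m, X) == factor(y)), 1.0)

  Xx <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  yx <- c(0, 1, 1, 0)
  mx <- train_linear_svm(Xx, yx, C = 10)
  expect_lte(mean(predict_labels(mx, Xx) == factor(yx)), 0.75)

  expect_error(train_linear_svm(X, rep(1, 6)), "two classes")
  expect_error(train_linear_svm(matrix(c(1, NA), 2, 1), c(0, 1)), "finite")
})

test_that("SVM decision boundary matches a direct QP solve of the dual", {
  # tiny separable instance; hard-margin solution is attained at large C
  X <- matrix(c(0, 0, 1, 1,
                0, 1, 0, 1), ncol = 2)
  y <- c(-1, -1, 1, 1) # separated by x1 = 0.5
  C <- 1000
  m <- train_linear_svm(X, factor(y, levels = c("1", "-1")), C = C)
  wb <- svm_weights(m, positive = "1")

  # dual: max sum(a) - 0.5 a' (yy' * XX') a, 0 <= a <= C, y'a = 0
  Q <- (y %*% t(y)) * (X %*% t(X))
  qp <- kernlab::ipop(c = rep(-1, 4), H = Q,
                      A = matrix(y, 1), b = 0, r = 0,
                      l = rep(0, 4), u = rep(C, 4))
  a <- kernlab::primal(qp)
  w_qp <- colSums(a * y * X)
  sv <- which(a > 1e-6 & a < C - 1e-6)
  b_qp <- mean(y[sv] - X[sv, , drop = FALSE] %*% w_qp)
  expect_equal(wb$w, w_qp, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(wb$b, b_qp, tolerance = 1e-4)
})

test_that("ROC/AUC equals pair counting, handles ties, and is monotone-invariant", {
  got <- roc_and_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = 1)
  expect_equal(got$auc, 0.75) # 3 concordant of 4 case-control pairs

  expect_equal(roc_and_auc(c(1, 0), c(1, 0), 1)$auc, 1.0)
  expect_equal(roc_and_auc(rep(0.7, 10), rep(c(0, 1), 5), 1)$auc, 0.5)

  set.seed(23)
  s <- stats::rnorm(60)
  lab <- stats::rbinom(60, 1, 0.5)
  base <- roc_and_auc(s, lab, 1)$auc
  expect_equal(roc_and_auc(exp(2 * s) + 5, lab, 1)$auc, base) # strictly monotone map
  expect_equal(base, auc_pair_oracle(s[lab == 1], s[lab == 0]))

  # ROC vertices are monotone nondecreasing in both coordinates
  roc <- roc_and_auc(s, lab, 1)$roc
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_error(roc_and_auc(s, rep(1, 60), 1), "both classes")
})

test_that("operating points agree with exhaustive threshold search", {
  roc3 <- data.frame(fpr = c(0, 0.2, 1), tpr = c(0, 0.9, 1))
  op <- optimal_point(roc3)
  expect_equal(op$sensitivity, 0.9)
  expect_equal(op$specificity, 0.8)

  # duplicating ROC points changes nothing
  op_dup <- optimal_point(roc3[c(1, 1, 2, 2, 3), ])
  expect_equal(op_dup$sensitivity, op$sensitivity)

  # perfect classifier
  perfect <- roc_and_auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3), 1)
  opp <- optimal_point(perfect$roc)
  expect_equal(opp$sensitivity, 1.0)
  expect_equal(opp$specificity, 1.0)
  expect_equal(sensitivity_at_specificity(perfect$roc, 0.95), 1.0)

  # step convention walk-through
  roc4 <- data.frame(fpr = c(0, 0.04, 0.06, 1), tpr = c(0, 0.4, 0.5, 1))
  expect_equal(sensitivity_at_specificity(roc4, 0.95), 0.4)

  # random instance vs exhaustive search over all thresholds
  set.seed(24)
  s <- stats::rnorm(80); lab <- stats::rbinom(80, 1, 0.4)
  roc <- roc_and_auc(s, lab, 1)$roc
  ex <- exhaustive_operating_points(s, lab, 1)
  d <- sqrt((1 - ex$sens)^2 + (1 - ex$spec)^2)
  best <- ex[d == min(d), ]
  op2 <- optimal_point(roc)
  expect_equal(min(sqrt((1 - op2$sensitivity)^2 + (1 - op2$specificity)^2)),
               min(d), tolerance = 1e-12)
  expect_equal(op2$sensitivity, max(best$sens))
  expect_equal(sensitivity_at_specificity(roc, 0.95),
               max(ex$sens[ex$spec >= 0.95]))
})

test_that("cross-validation is deterministic, leak-free and calibrated under the null", {
  set.seed(25)
  # perfectly separable cohort
  Xs <- rbind(matrix(stats::rnorm(40 * 3, 0), ncol = 3),
              matrix(stats::rnorm(40 * 3, 8), ncol = 3))
  ys <- rep(c("reference", "case"), each = 40)
  ev <- cv_evaluate(Xs, ys, folds = 5, repeats = 2, seed = 1)
  expect_equal(ev$auc_mean, 1.0)
  expect_equal(ev$auc_sd, 0.0)

  # determinism
  ev2 <- cv_evaluate(Xs, ys, folds = 5, repeats = 2, seed = 1)
  expect_identical(ev$fold_aucs, ev2$fold_aucs)

  # leakage canary: wide pure-noise data (p > n) is memorizable by a model
  # that sees its test fold, so held-out AUC near 0.5 certifies no leak
  set.seed(26)
  Xn <- matrix(stats::rnorm(60 * 120), ncol = 120)
  yn <- rep(c("case", "reference"), each = 30)
  mfit <- train_linear_svm(Xn, yn, C = 100)
  expect_equal(mean(predict_labels(mfit, Xn) == yn), 1.0) # can interpolate
  evn <- cv_evaluate(Xn, yn, folds = 5, repeats = 4, seed = 3, C = 100)
  expect_gt(evn$auc_mean, 0.25)
  expect_lt(evn$auc_mean, 0.75)
  # seed changes re-randomize the folds
  evn2 <- cv_evaluate(Xn, yn, folds = 5, repeats = 4, seed = 4, C = 100)
  expect_false(identical(evn$fold_aucs, evn2$fold_aucs))

  # null calibration at the study scale: permuted labels, mean over 3 seeds
  # (a single fixed labeling has irreducible dataset-level AUC spread ~0.03)
  set.seed(27)
  Xp <- matrix(stats::rnorm(400 * 20), ncol = 20)
  yp <- rep(c("case", "reference"), each = 200)
  null_aucs <- vapply(1:3, function(sd) {
    evp <- cv_evaluate(Xp, sample(yp), folds = 10, repeats = 3, seed = sd)
    expect_gt(evp$auc_mean, 0.38)
    expect_lt(evp$auc_mean, 0.62)
    evp$auc_mean
  }, numeric(1))
  expect_gt(mean(null_aucs), 0.45)
  expect_lt(mean(null_aucs), 0.55)

  tiny <- c(1:4, 31:34) # 4 per class, fewer than the 5 folds
  expect_error(cv_evaluate(Xn[tiny, ], yn[tiny], folds = 5), "fewer samples")
})

test_that("multiclass one-vs-one evaluation separates classes and normalizes rows", {
  set.seed(28)
  X <- rbind(matrix(stats::rnorm(30 * 2, 0), ncol = 2),
             matrix(stats::rnorm(30 * 2, 6), ncol = 2),
             matrix(cbind(stats::rnorm(30, 0), stats::rnorm(30, 6)), ncol = 2))
  y <- rep(c("A", "B", "C"), each = 30)
  mc <- multiclass_cv(X, y, folds = 5, repeats = 2, seed = 4)
  expect_true(all(mc$per_class_accuracy > 0.95))
  expect_equal(rowSums(mc$confusion_norm), rep(1, 3), ignore_attr = TRUE)
  expect_gt(mc$overall_accuracy_mean, 0.95)

  # determinism
  mc2 <- multiclass_cv(X, y, folds = 5, repeats = 2, seed = 4)
  expect_identical(mc$fold_accuracies, mc2$fold_accuracies)
})

test_that("binary model serializes to reusable JSON weights", {
  set.seed(29)
  X <- matrix(stats::rnorm(40 * 3), ncol = 3)
  y <- rep(c("case", "reference"), each = 20)
  m <- train_linear_svm(X, y)
  path <- tempfile(fileext = ".json")
  write_svm_json(m, path, positive = "case")
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- decision_scores(m, X, positive = "case")
  expect_equal(as.numeric(X %*% js$w + js$b), sc, tolerance = 1e-10)
})
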