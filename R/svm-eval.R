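#' Train a soft-margin linear SVM
#'
#' Thin wrapper around the libsvm solver (via e1071) with a linear kernel and
#' no internal feature scaling; exposes continuous decision scores (the
#' "disease likelihood") rather than only hard labels.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Class labels (factor or coercible); at least two classes.
#' @param C Soft-margin regularization parameter (default 1).
#' @return Object of class `"linear_svm"`.
#' @export
train_linear_svm <- function(X, y, C = 1) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("features must be finite")
  y <- factor(y)
  if (nlevels(y) < 2) stop("at least two classes are required")
  if (any(table(y) == 0)) y <- droplevels(y)
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = C, scale = FALSE)
  structure(list(fit = fit, levels = levels(y), C = C), class = "linear_svm")
}

#' Linear SVM weight vector and intercept (binary models)
#'
#' The decision function is `f(x) = w'x + b`, positive values favouring the
#' positive class.
#'
#' @param model A binary `linear_svm`.
#' @param positive Level treated as positive.
#' @return List: `w` (numeric vector), `b` (intercept).
#' @export
svm_weights <- function(model, positive = model$levels[1]) {
  stopifnot(inherits(model, "linear_svm"), length(model$levels) == 2)
  w <- drop(t(model$fit$coefs) %*% model$fit$SV)
  b <- -model$fit$rho
  # libsvm orients the raw decision by training-data label order, recorded in
  # fit$labels, not by factor level order
  favoured <- model$fit$levels[model$fit$labels[1]]
  if (favoured != positive) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

#' Continuous decision scores for a binary linear SVM
#'
#' @param model A binary `linear_svm`.
#' @param X Feature matrix.
#' @param positive Level for which higher scores mean higher likelihood.
#' @return Numeric vector of decision values.
#' @export
decision_scores <- function(model, X, positive = model$levels[1]) {
  stopifnot(inherits(model, "linear_svm"), length(model$levels) == 2)
  pr <- stats::predict(model$fit, as.matrix(X), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # raw decision values favour the class libsvm saw first (fit$labels[1])
  favoured <- model$fit$levels[model$fit$labels[1]]
  s <- as.numeric(dv[, 1])
  if (favoured != positive) s <- -s
  s
}

#' Predicted labels
#'
#' @param model A `linear_svm`.
#' @param X Feature matrix.
#' @return Factor of predicted classes.
#' @export
predict_labels <- function(model, X) {
  stats::predict(model$fit, as.matrix(X))
}

#' ROC curve and AUC from continuous scores
#'
#' The ROC is built by a threshold sweep over the unique scores (predicting
#' positive for `score >= threshold`), prefixed with the (0, 0) vertex. The
#' AUC is the Mann-Whitney probability estimate with ties counted one half,
#' which equals the trapezoidal area under this ROC exactly.
#'
#' @param scores Numeric decision scores.
#' @param labels Class labels.
#' @param positive The positive class label.
#' @return List: `roc` (`data.frame` with `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
#' @examples
#' roc_and_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = 1)$auc # 0.75
roc_and_auc <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  tp <- cumsum(p); fp <- cumsum(!p)
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  roc <- data.frame(fpr = c(0, fp[last_of_tie] / n2),
                    tpr = c(0, tp[last_of_tie] / n1),
                    threshold = c(Inf, s[last_of_tie]))
  r <- rank(scores) # midranks handle ties with weight 1/2
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  list(roc = roc, auc = u / (n1 * n2))
}

#' Optimal ROC operating point (upper-left corner)
#'
#' Among the realized ROC vertices, returns the one minimizing the Euclidean
#' distance to the upper-left corner (FPR 0, TPR 1); ties are broken toward
#' higher sensitivity.
#'
#' @param roc `data.frame` with `fpr`, `tpr` and optionally `threshold`.
#' @return List: `sensitivity`, `specificity`, `threshold`.
#' @export
optimal_point <- function(roc) {
  stopifnot(nrow(roc) >= 1)
  d <- sqrt((1 - roc$tpr)^2 + roc$fpr^2)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.max(roc$tpr[best])]
  list(sensitivity = roc$tpr[best],
       specificity = 1 - roc$fpr[best],
       threshold = if (!is.null(roc$threshold)) roc$threshold[best] else NA_real_)
}

#' Sensitivity at a fixed specificity
#'
#' Conservative step convention (no interpolation): the sensitivity of the
#' highest-sensitivity realized ROC vertex whose specificity is at least the
#' target.
#'
#' @param roc ROC `data.frame` (`fpr`, `tpr`).
#' @param specificity Target specificity (default 0.95).
#' @return Sensitivity value.
#' @export
sensitivity_at_specificity <- function(roc, specificity = 0.95) {
  ok <- (1 - roc$fpr) >= specificity
  if (!any(ok)) stop("requested specificity is not reached by the ROC")
  max(roc$tpr[ok])
}

stratified_folds <- function(y, k) {
  y <- factor(y)
  if (min(table(y)) < k) stop("smallest class has fewer samples than folds")
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Repeated stratified cross-validated binary SVM evaluation
#'
#' Stratified k-fold assignment is re-randomized on each repeat from the seed;
#' the model is fitted on the training folds only and scored on the held-out
#' fold. Reports the AUC of every fold x repeat, their mean and SD, and the
#' pooled ROC built from the concatenated held-out decision scores.
#'
#' @param X Feature matrix (already preprocessed per sample).
#' @param y Binary labels.
#' @param positive Positive class (default "case").
#' @param folds,repeats Cross-validation geometry (default 10 x 10).
#' @param seed Integer seed controlling all fold randomization.
#' @param C SVM regularization parameter.
#' @return Object of class `"cv_evaluation"`: `fold_aucs` (length
#'   `folds*repeats`), `auc_mean`, `auc_sd`, `pooled_roc`, `pooled_auc`,
#'   `operating_point`, `sens_at_95spec`, `folds`, `repeats`, `seed`.
#' @export
cv_evaluate <- function(X, y, positive = "case", folds = 10, repeats = 10,
                        seed = 1, C = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  stopifnot(nlevels(y) == 2, positive %in% levels(y))
  set.seed(seed)
  fold_aucs <- numeric(0)
  all_scores <- numeric(0)
  all_labels <- character(0)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      test <- fold == f
      model <- train_linear_svm(X[!test, , drop = FALSE], y[!test], C = C)
      sc <- decision_scores(model, X[test, , drop = FALSE], positive = positive)
      fold_aucs <- c(fold_aucs, roc_and_auc(sc, y[test], positive)$auc)
      all_scores <- c(all_scores, sc)
      all_labels <- c(all_labels, as.character(y[test]))
    }
  }
  pooled <- roc_and_auc(all_scores, all_labels, positive)
  structure(list(fold_aucs = fold_aucs,
                 auc_mean = mean(fold_aucs),
                 auc_sd = stats::sd(fold_aucs),
                 pooled_roc = pooled$roc,
                 pooled_auc = pooled$auc,
                 operating_point = optimal_point(pooled$roc),
                 sens_at_95spec = sensitivity_at_specificity(pooled$roc, 0.95),
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_evaluation")
}

#' @export
print.cv_evaluation <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf("<cv_evaluation> AUC %.3f +/- %.3f (%d x %d CV); optimal sens/spec %.2f/%.2f; sens@95%%spec %.2f\n",
              x$auc_mean, x$auc_sd, x$folds, x$repeats,
              op$sensitivity, op$specificity, x$sens_at_95spec))
  invisible(x)
}

# one-vs-one linear SVM committee with majority vote; ties broken by the
# aggregate signed decision score
ovo_predict <- function(X_train, y_train, X_test, C = 1) {
  lv <- levels(y_train)
  votes <- matrix(0L, nrow(X_test), length(lv), dimnames = list(NULL, lv))
  agg <- matrix(0, nrow(X_test), length(lv), dimnames = list(NULL, lv))
  for (a in seq_along(lv)) for (b in seq_along(lv)) {
    if (a >= b) next
    sub <- y_train %in% lv[c(a, b)]
    model <- train_linear_svm(X_train[sub, , drop = FALSE],
                              droplevels(y_train[sub]), C = C)
    sc <- decision_scores(model, X_test, positive = lv[a])
    votes[, a] <- votes[, a] + (sc > 0)
    votes[, b] <- votes[, b] + (sc <= 0)
    agg[, a] <- agg[, a] + sc
    agg[, b] <- agg[, b] - sc
  }
  pred <- character(nrow(X_test))
  for (i in seq_len(nrow(X_test))) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) top <- top[which.max(agg[i, top])]
    pred[i] <- lv[top]
  }
  factor(pred, levels = lv)
}

#' Repeated stratified cross-validated multiclass SVM evaluation
#'
#' One-vs-one linear SVMs with majority vote (vote ties broken by the
#' aggregate decision score). Confusion counts are accumulated over all
#' held-out folds and repeats; per-class accuracy is the class recall; the
#' overall accuracy is reported as mean +/- SD over the fold accuracies.
#'
#' @inheritParams cv_evaluate
#' @param y Labels with >= 3 classes (every class at least `folds` samples).
#' @return Object of class `"cv_multiclass"`: `confusion` (counts, rows =
#'   true class), `confusion_norm` (rows sum to 1), `per_class_accuracy`,
#'   `fold_accuracies`, `overall_accuracy_mean`, `overall_accuracy_sd`,
#'   `folds`, `repeats`, `seed`.
#' @export
multiclass_cv <- function(X, y, folds = 10, repeats = 10, seed = 1, C = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  stopifnot(nlevels(y) >= 2)
  set.seed(seed)
  lv <- levels(y)
  conf <- matrix(0L, length(lv), length(lv), dimnames = list(true = lv, pred = lv))
  fold_acc <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      test <- fold == f
      pred <- ovo_predict(X[!test, , drop = FALSE], y[!test],
                          X[test, , drop = FALSE], C = C)
      conf <- conf + table(factor(y[test], levels = lv),
                           factor(pred, levels = lv))
      fold_acc <- c(fold_acc, mean(pred == y[test]))
    }
  }
  conf <- unclass(conf)
  structure(list(confusion = conf,
                 confusion_norm = conf / rowSums(conf),
                 per_class_accuracy = diag(conf) / rowSums(conf),
                 fold_accuracies = fold_acc,
                 overall_accuracy_mean = mean(fold_acc),
                 overall_accuracy_sd = stats::sd(fold_acc),
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_multiclass")
}

#' @export
print.cv_multiclass <- function(x, ...) {
  cat(sprintf("<cv_multiclass> overall accuracy %.2f +/- %.2f (%d x %d CV)\n",
              x$overall_accuracy_mean, x$overall_accuracy_sd,
              x$folds, x$repeats))
  print(round(x$confusion_norm, 3))
  invisible(x)
}

#' Serialize a binary linear SVM to portable JSON
#'
#' Writes the weight vector, intercept, class levels and regularization
#' parameter, sufficient to recompute decision scores anywhere.
#'
#' @param model A binary `linear_svm`.
#' @param path Output path.
#' @param positive Positive class orientation of the stored weights.
#' @export
write_svm_json <- function(model, path, positive = model$levels[1]) {
  wb <- svm_weights(model, positive)
  jsonlite::write_json(list(w = wb$w, b = wb$b, positive = positive,
                            levels = model$levels, C = model$C),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
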