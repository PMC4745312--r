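#' Classification error rate and sensitivity
#'
#' Error is the number of misclassified objects over the total; sensitivity
#' is suitable-cell recall (true positives over actual positives, with
#' `suitable` the positive class); specificity the analogue on negatives.
#'
#' @param predicted,truth factors/characters of equal length with levels
#'   `suitable`/`unsuitable`.
#' @param positive the positive class (default `"suitable"`).
#' @return A single proportion in `[0, 1]`.
#' @export
error_rate <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth)) stopf("length mismatch")
  mean(predicted != truth)
}

#' @rdname error_rate
#' @export
sensitivity <- function(predicted, truth, positive = "suitable") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth)) stopf("length mismatch")
  pos <- truth == positive
  if (!any(pos)) stopf("sensitivity undefined: no positive objects present")
  mean(predicted[pos] == positive)
}

#' @rdname error_rate
#' @export
specificity <- function(predicted, truth, positive = "suitable") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  neg <- truth != positive
  if (!any(neg)) stopf("specificity undefined: no negative objects present")
  mean(predicted[neg] != positive)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores; the curve starts at
#' `(0, 0)` and ends at `(1, 1)` and is monotone in both coordinates. AUC is
#' the trapezoid area, equal to the probability that a random positive
#' outranks a random negative with ties counted 1/2 (the c-statistic).
#'
#' @param scores numeric decision scores, higher = more suitable.
#' @param truth labels; both classes must be present.
#' @param positive the positive class.
#' @return `roc_curve`: data.frame with `threshold`, `fpr`, `tpr`;
#'   `auc`: scalar in `[0, 1]`.
#' @export
roc_curve <- function(scores, truth, positive = "suitable") {
  truth <- as.character(truth)
  pos <- truth == positive
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # cumulative counts at each unique threshold
  last <- !duplicated(s, fromLast = TRUE) # last occurrence of each value
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp / sum(!pos)),
             tpr = c(0, tp / sum(pos)))
}

#' @rdname roc_curve
#' @export
auc <- function(scores, truth, positive = "suitable") {
  r <- roc_curve(scores, truth, positive)
  sum(diff(r$fpr) * (head(r$tpr, -1) + r$tpr[-1]) / 2)
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples objects with replacement within each class (so neither class
#' can vanish from a resample), recomputes the metric, and returns the 5th
#' and 95th percentiles.
#'
#' @param metric_fn function of `(scores, truth)` returning a scalar, e.g.
#'   [auc()] or a thresholded error.
#' @param scores,truth as in [roc_curve()].
#' @param B number of resamples (>= 100).
#' @param seed integer seed.
#' @param probs interval percentiles (default `c(0.05, 0.95)`).
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(metric_fn, scores, truth, B = 1000, seed = 1L,
                         probs = c(0.05, 0.95)) {
  if (B < 100) stopf("B must be >= 100")
  truth <- as.character(truth)
  idx_by_class <- split(seq_along(truth), truth)
  stats <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- unlist(lapply(idx_by_class, function(i)
      i[sample.int(length(i), replace = TRUE)]), use.names = FALSE)
    metric_fn(scores[idx], truth[idx])
  }, numeric(1)))
  q <- quantile(stats, probs, names = FALSE)
  c(low = q[1], high = q[2])
}

#' Effect size: mean difference over root-sum variance
#'
#' `(mean(a) - mean(b)) / sqrt(var(a) + var(b))`; scale-invariant.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @return Scalar effect size.
#' @export
effect_size <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("each group needs >= 2 values")
  v <- var(group_a) + var(group_b)
  if (v == 0) stopf("effect size undefined: both variances zero")
  (mean(group_a) - mean(group_b)) / sqrt(v)
}

#' Evaluate a trained classifier on a labeled test table
#'
#' @param model a `cell_classifier`.
#' @param test a [feature_table()] with labels.
#' @param B bootstrap resamples for the confidence intervals.
#' @param seed integer seed for the bootstrap.
#' @return An `eval_report`: error rate, sensitivity, specificity, ROC
#'   points, AUC, and 5%/95% bootstrap CIs per metric.
#' @export
evaluate_classifier <- function(model, test, B = 1000, seed = 1L) {
  stopifnot(inherits(test, "feature_table"))
  if (is.null(test$labels)) stopf("test table must carry labels")
  scores <- decision_scores(model, test)
  pred <- predict_labels(model, test)
  truth <- as.character(test$labels)
  thr <- if (model$method == "svm") 0 else 0.5
  report <- list(
    error_rate = error_rate(pred, truth),
    sensitivity = sensitivity(pred, truth),
    specificity = specificity(pred, truth),
    roc = roc_curve(scores, truth),
    auc = auc(scores, truth),
    n = length(truth),
    n_bootstrap = B,
    ci = list(
      auc = bootstrap_ci(auc, scores, truth, B, seed),
      error_rate = bootstrap_ci(function(s, t)
        error_rate(ifelse(s > thr, "suitable", "unsuitable"), t),
        scores, truth, B, seed),
      sensitivity = bootstrap_ci(function(s, t)
        sensitivity(ifelse(s > thr, "suitable", "unsuitable"), t),
        scores, truth, B, seed)))
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  error rate : %.4f [%.4f, %.4f]\n", x$error_rate,
              x$ci$error_rate[1], x$ci$error_rate[2]))
  cat(sprintf("  sensitivity: %.4f [%.4f, %.4f]\n", x$sensitivity,
              x$ci$sensitivity[1], x$ci$sensitivity[2]))
  cat(sprintf("  specificity: %.4f\n", x$specificity))
  cat(sprintf("  AUC        : %.4f [%.4f, %.4f] (n = %d, B = %d)\n",
              x$auc, x$ci$auc[1], x$ci$auc[2], x$n, x$n_bootstrap))
  invisible(x)
}

# leave-one-out cross-validated error with fixed hyperparameters
.loocv_error <- function(table, method, kernel, tuned, k = 3, seed = 1L) {
  x <- table$values
  y <- droplevels(table$labels)
  n <- nrow(x)
  std <- .standardizer(x)
  xs <- std$apply(x)
  wrong <- vapply(seq_len(n), function(i) {
    if (method == "svm") {
      fit <- .fit_svm(xs[-i, , drop = FALSE], y[-i], kernel,
                      tuned$C, tuned$gamma, tuned$degree %||% 3)
      as.character(predict(fit, xs[i, , drop = FALSE])) != as.character(y[i])
    } else if (method == "knn") {
      pred <- class::knn(xs[-i, , drop = FALSE], xs[i, , drop = FALSE],
                         y[-i], k = k, use.all = TRUE)
      as.character(pred) != as.character(y[i])
    } else {
      fit <- with_seed(seed, randomForest::randomForest(
        xs[-i, , drop = FALSE], y[-i],
        ntree = tuned$ntree, mtry = tuned$mtry))
      as.character(predict(fit, xs[i, , drop = FALSE])) != as.character(y[i])
    }
  }, logical(1))
  mean(wrong)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Performance versus number of selected features, with overtraining audit
#'
#' For `k = 1..max_features` takes the first `k` features of the selection
#' trace, trains the classifier on the training table, and records training
#' error, test error, leave-one-out cross-validated (LOOCV) training error,
#' sensitivity, and AUC with bootstrap CIs. The overtraining audit reports
#' the error-gap sequence (test minus LOOCV error per `k`) and its Kendall
#' rank correlation with `k`: a significant positive trend (one-sided
#' p < 0.05) flags overtraining.
#'
#' @param train,test labeled [feature_table()]s over the same features.
#' @param max_features largest subset size to evaluate.
#' @param trace optional [stepwise_select()] trace; computed from `train`
#'   when absent.
#' @param method,kernel,folds,seed passed to [train_classifier()].
#' @param B bootstrap resamples per point.
#' @param loocv compute the LOOCV curve (default `TRUE`).
#' @return A `feature_sweep`: data.frame `curves` (one row per `k`), the
#'   `gap` sequence, Kendall `tau`, one-sided `p_value`, and `overtrained`
#'   flag.
#' @export
feature_count_sweep <- function(train, test, max_features, trace = NULL,
                                method = "svm", kernel = "rbf", folds = 10,
                                B = 200, seed = 1L, loocv = TRUE) {
  if (is.null(trace)) trace <- stepwise_select(train, max_features)
  if (length(trace$selected) < max_features)
    stopf("selection trace has %d < %d features", length(trace$selected),
          max_features)
  rows <- lapply(seq_len(max_features), function(k) {
    feats <- trace$selected[seq_len(k)]
    tr_k <- subset_features(train, features = feats)
    te_k <- subset_features(test, features = feats)
    model <- train_classifier(tr_k, method = method, kernel = kernel,
                              folds = folds, seed = seed)
    scores <- decision_scores(model, te_k)
    pred <- predict_labels(model, te_k)
    truth <- as.character(te_k$labels)
    ci <- bootstrap_ci(auc, scores, truth, max(B, 100), seed)
    data.frame(
      k = k,
      train_error = error_rate(predict_labels(model, tr_k), tr_k$labels),
      test_error = error_rate(pred, truth),
      loocv_error = if (loocv)
        .loocv_error(tr_k, method, kernel, model$tuned, seed = seed)
        else NA_real_,
      sensitivity = sensitivity(pred, truth),
      auc = auc(scores, truth),
      auc_ci_low = ci[1], auc_ci_high = ci[2])
  })
  curves <- do.call(rbind, rows)
  gap <- if (loocv) curves$test_error - curves$loocv_error
         else curves$test_error - curves$train_error
  kt <- suppressWarnings(cor.test(seq_len(max_features), gap,
                                  method = "kendall",
                                  alternative = "greater"))
  structure(list(curves = curves, gap = gap,
                 tau = unname(kt$estimate), p_value = kt$p.value,
                 overtrained = kt$p.value < 0.05),
            class = "feature_sweep")
}

#' @export
print.feature_sweep <- function(x, ...) {
  cat("<feature_sweep>\n")
  print(x$curves, row.names = FALSE, digits = 4)
  cat(sprintf("  gap trend: Kendall tau = %.3f, one-sided p = %.3f (%s)\n",
              x$tau, x$p_value,
              if (x$overtrained) "overtraining flagged" else "no overtraining"))
  invisible(x)
}
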