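#' SVM kernel functions
#'
#' The three kernels compared for the suitability classifier: linear
#' `<u, v>`, polynomial `(<u, v> + a)^d`, and Gaussian radial basis
#' `exp(-||u - v||^2 / (2 sigma^2))`.
#'
#' @param u,v numeric vectors of equal length.
#' @param kernel `"linear"`, `"polynomial"` or `"rbf"`.
#' @param sigma RBF scale (`> 0`).
#' @param degree,offset polynomial degree `d` and offset `a`.
#' @return Scalar kernel value.
#' @export
svm_kernel <- function(u, v, kernel = c("rbf", "linear", "polynomial"),
                       sigma = 1, degree = 3, offset = 1) {
  kernel <- match.arg(kernel)
  if (length(u) != length(v)) stopf("dimension mismatch: %d vs %d",
                                    length(u), length(v))
  switch(kernel,
         linear = sum(u * v),
         polynomial = (sum(u * v) + offset)^degree,
         rbf = {
           if (sigma <= 0) stopf("sigma must be > 0")
           exp(-sum((u - v)^2) / (2 * sigma^2))
         })
}

# deterministic stratified fold assignment
.fold_ids <- function(labels, folds, seed) {
  ids <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      i <- which(labels == lv)
      ids[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
  })
  ids
}

.standardizer <- function(x) {
  mu <- colMeans(x)
  sig <- apply(x, 2, sd)
  sig[sig == 0] <- 1
  list(mu = mu, sig = sig,
       apply = function(m) sweep(sweep(m, 2, mu), 2, sig, "/"))
}

.fit_svm <- function(x, y, kernel, C, gamma, degree = 3, offset = 1) {
  args <- list(x = x, y = y, scale = FALSE, cost = C,
               kernel = switch(kernel, rbf = "radial", linear = "linear",
                               polynomial = "polynomial"))
  if (kernel == "rbf") args$gamma <- gamma
  if (kernel == "polynomial") {
    args$gamma <- 1; args$coef0 <- offset; args$degree <- degree
  }
  do.call(e1071::svm, args)
}

#' Train a suitability classifier
#'
#' SVM hyperparameters are tuned by stratified k-fold cross-validation over
#' a log grid (penalty `C` in `2^seq(-5, 15, 2)`; RBF `gamma` in
#' `2^seq(-15, 3, 2)`, i.e. scale `sigma = sqrt(1/(2 gamma))`; polynomial
#' degree in `{2, 3}` with offset 1), with deterministic fold assignment
#' from `seed`. kNN defaults to `k = 3`; random forest to 500 trees with
#' `mtry = round(sqrt(p))`. Features are z-scored with parameters frozen
#' from the training data, so test-time leakage is structurally impossible.
#'
#' @param table a [feature_table()] with labels (both classes present).
#' @param method `"svm"`, `"knn"` or `"rf"`.
#' @param kernel SVM kernel: `"rbf"`, `"linear"` or `"polynomial"`.
#' @param folds cross-validation folds for tuning (default 10).
#' @param grid optional named list overriding the tuning grid
#'   (`C`, `gamma`, `degree`).
#' @param k kNN neighbour count.
#' @param ntree,mtry random-forest parameters (defaults 500 and
#'   `round(sqrt(p))`).
#' @param seed integer seed controlling fold assignment and the forest.
#' @return A `cell_classifier` with the frozen standardizer, tuned
#'   hyperparameters and the fold-assignment audit (`cv$fold_ids`).
#' @export
train_classifier <- function(table, method = c("svm", "knn", "rf"),
                             kernel = c("rbf", "linear", "polynomial"),
                             folds = 10, grid = NULL, k = 3,
                             ntree = 500, mtry = NULL, seed = 1L) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stopf("training table must carry labels")
  y <- droplevels(table$labels)
  if (nlevels(y) != 2) stopf("both classes must be present")
  std <- .standardizer(table$values)
  x <- std$apply(table$values)
  model <- list(method = method, kernel = kernel,
                features = colnames(table$values),
                standardize = list(mu = std$mu, sig = std$sig),
                seed = as.integer(seed))

  if (method == "svm") {
    if (min(table(y)) < folds)
      stopf("each class needs >= %d samples for %d-fold tuning", folds, folds)
    g <- list(C = 2^seq(-5, 15, 2), gamma = 2^seq(-15, 3, 2), degree = 2:3)
    g[names(grid)] <- grid
    combos <- switch(kernel,
      linear = expand.grid(C = g$C, gamma = NA, degree = NA),
      rbf = expand.grid(C = g$C, gamma = g$gamma, degree = NA),
      polynomial = expand.grid(C = g$C, gamma = NA, degree = g$degree))
    fold_ids <- .fold_ids(y, folds, seed)
    cv_err <- if (nrow(combos) == 1) NA_real_ # nothing to tune
    else vapply(seq_len(nrow(combos)), function(ci) {
      errs <- vapply(seq_len(folds), function(f) {
        tr <- fold_ids != f; te <- !tr
        fit <- .fit_svm(x[tr, , drop = FALSE], y[tr], kernel,
                        combos$C[ci], combos$gamma[ci],
                        degree = combos$degree[ci])
        mean(predict(fit, x[te, , drop = FALSE]) != y[te])
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    best <- if (nrow(combos) == 1) 1L
            else which.min(cv_err) # first minimum: deterministic tie-break
    model$tuned <- list(C = combos$C[best], gamma = combos$gamma[best],
                        degree = combos$degree[best], offset = 1,
                        sigma = if (kernel == "rbf")
                          sqrt(1 / (2 * combos$gamma[best])) else NA,
                        cv_error = cv_err[best])
    model$cv <- list(fold_ids = fold_ids, folds = folds,
                     grid_errors = cbind(combos, error = cv_err))
    model$fit <- .fit_svm(x, y, kernel, combos$C[best], combos$gamma[best],
                          degree = combos$degree[best])
  } else if (method == "knn") {
    model$tuned <- list(k = k)
    model$train_x <- x
    model$train_y <- y
  } else {
    if (is.null(mtry)) mtry <- max(1, round(sqrt(ncol(x))))
    model$tuned <- list(ntree = ntree, mtry = mtry)
    model$fit <- with_seed(seed,
      randomForest::randomForest(x, y, ntree = ntree, mtry = mtry))
  }
  structure(model, class = "cell_classifier")
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat(sprintf("<cell_classifier> %s%s on %d features\n", x$method,
              if (x$method == "svm") paste0("/", x$kernel) else "",
              length(x$features)))
  if (!is.null(x$tuned))
    cat("  tuned:", paste(sprintf("%s=%.4g", names(x$tuned),
        vapply(x$tuned, function(v) as.numeric(v)[1], numeric(1))),
        collapse = ", "), "\n")
  invisible(x)
}

.model_matrix <- function(model, table) {
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  missing <- setdiff(model$features, colnames(x))
  extra <- setdiff(colnames(x), model$features)
  if (length(missing))
    stopf("feature mismatch; missing: %s%s",
          paste(missing, collapse = ", "),
          if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", "))
          else "")
  x <- x[, model$features, drop = FALSE]
  sweep(sweep(x, 2, model$standardize$mu), 2, model$standardize$sig, "/")
}

#' Decision scores: higher means more suitable
#'
#' SVM: signed decision value; kNN: fraction of the `k` nearest neighbours
#' labeled suitable; RF: suitable vote fraction.
#'
#' @param model a `cell_classifier`.
#' @param table a [feature_table()] or matrix with the training features.
#' @return Numeric score per object, oriented so higher = more suitable.
#' @export
decision_scores <- function(model, table) {
  stopifnot(inherits(model, "cell_classifier"))
  x <- .model_matrix(model, table)
  if (model$method == "svm") {
    dv <- attr(predict(model$fit, x, decision.values = TRUE),
               "decision.values")
    s <- dv[, 1]
    # orient: e1071 labels the decision column "level1/level2"
    if (!grepl("^suitable", colnames(dv)[1])) s <- -s
    unname(s)
  } else if (model$method == "knn") {
    pred <- class::knn(model$train_x, x, model$train_y, k = model$tuned$k,
                       prob = TRUE, use.all = TRUE)
    p <- attr(pred, "prob") # proportion of votes for the winning class
    unname(ifelse(pred == "suitable", p, 1 - p))
  } else {
    unname(predict(model$fit, x, type = "prob")[, "suitable"])
  }
}

#' Predict suitability labels
#'
#' Thresholds [decision_scores()] at the method's default decision boundary
#' (0 for SVM, majority for kNN and RF), so `label == suitable` iff
#' `score > threshold` for every threshold choice.
#'
#' @inheritParams decision_scores
#' @param threshold decision threshold on the score scale (default: 0 for
#'   SVM, 0.5 for kNN/RF).
#' @return Factor of `suitable`/`unsuitable`.
#' @export
predict_labels <- function(model, table, threshold = NULL) {
  if (is.null(threshold))
    threshold <- if (model$method == "svm") 0 else 0.5
  s <- decision_scores(model, table)
  factor(ifelse(s > threshold, "suitable", "unsuitable"),
         levels = c("suitable", "unsuitable"))
}
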