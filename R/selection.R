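#' Nonparametric scatter-matrix feature selection
#'
#' A nonparametric variant of Fisher's criterion for two classes: every
#' sample is compared against an inverse-distance-weighted mean of the
#' other class (between-class scatter) or of its own class excluding itself
#' (within-class scatter), each outer product weighted by an
#' inverse-distance scatter weight. No distributional assumptions are made.
#' The criterion `F = trace(Sw^-1 Sb)` drives a floating stepwise search:
#' forward additions with conditional backward exclusions.
#'
#' @name feature_selection
NULL

.inv_dist_weights_vec <- function(d, tol = 1e-12) {
  zero <- d < tol
  if (any(zero)) {
    w <- numeric(length(d))
    w[zero] <- 1 / sum(zero) # coincident points tie-share the full mass
    w
  } else {
    w <- 1 / d
    w / sum(w)
  }
}

#' Inverse-distance weights of a sample against a reference class
#'
#' Weight of reference sample `l` is proportional to the reciprocal
#' Euclidean distance `d(x, x_l)^-1`, normalized to sum 1. If `x` coincides
#' with one or more reference samples, the full mass is shared equally among
#' the coincident points (the limit of inverse-distance weighting).
#'
#' @param x numeric vector (one sample).
#' @param class_samples numeric matrix, one reference sample per row.
#' @return Weight vector summing to 1.
#' @export
inverse_distance_weights <- function(x, class_samples) {
  class_samples <- rbind(class_samples)
  if (nrow(class_samples) < 1) stopf("empty reference class")
  d <- sqrt(colSums((t(class_samples) - x)^2))
  .inv_dist_weights_vec(d)
}

#' Inverse-distance weighted mean of a reference class, seen from a sample
#'
#' @inheritParams inverse_distance_weights
#' @return Numeric vector: the weighted mean point.
#' @export
weighted_class_mean <- function(x, class_samples) {
  class_samples <- rbind(class_samples)
  w <- inverse_distance_weights(x, class_samples)
  colSums(class_samples * w)
}

#' Scatter weights of a class against its per-sample weighted means
#'
#' Weight of sample `k` is proportional to the reciprocal distance between
#' the sample and its weighted mean `M_j(x_k)`, normalized over the class to
#' sum 1; samples coinciding with their weighted mean tie-share the full
#' mass (logged via warning).
#'
#' @param class_samples numeric matrix, one sample per row.
#' @param weighted_means numeric matrix of the same shape: row `k` is
#'   `M_j(x_k)`.
#' @return Lambda vector summing to 1.
#' @export
scatter_weights <- function(class_samples, weighted_means) {
  class_samples <- rbind(class_samples)
  weighted_means <- rbind(weighted_means)
  stopifnot(identical(dim(class_samples), dim(weighted_means)))
  d <- sqrt(rowSums((class_samples - weighted_means)^2))
  if (any(d < 1e-12))
    warning("sample(s) coincide with their weighted mean; tie-shared mass")
  .inv_dist_weights_vec(d)
}

# inverse-distance weighted means of every row of Xi against reference Xj;
# `exclude_self = TRUE` drops column k for row k (classes identical)
.pairwise_weighted_means <- function(Xi, Xj, exclude_self = FALSE) {
  ni <- nrow(Xi)
  if (as.double(ni) * nrow(Xj) * ncol(Xi) > 2e6) {
    # large problems: BLAS-backed expanded form (|a|^2 + |b|^2 - 2ab);
    # the ~1e-8 relative distance error is irrelevant at this scale
    D2 <- outer(rowSums(Xi^2), rep(1, nrow(Xj))) +
          outer(rep(1, ni), rowSums(Xj^2)) - 2 * tcrossprod(Xi, Xj)
    D2 <- pmax(D2, 0)
  } else {
    # per-dimension explicit differencing: full precision for nearby points
    D2 <- matrix(0, ni, nrow(Xj))
    for (k in seq_len(ncol(Xi))) D2 <- D2 + outer(Xi[, k], Xj[, k], "-")^2
  }
  D <- sqrt(D2)
  if (exclude_self) diag(D) <- Inf
  tol <- 1e-12
  W <- 1 / pmax(D, tol)
  W[D == Inf] <- 0
  zero_rows <- which(apply(D, 1, function(r) any(r < tol & is.finite(r))))
  for (r in zero_rows) {
    z <- D[r, ] < tol & is.finite(D[r, ])
    W[r, ] <- 0
    W[r, z] <- 1 / sum(z)
  }
  W <- W / rowSums(W)
  W %*% Xj
}

#' Nonparametric between- and within-class scatter matrices
#'
#' Two-class form. For each sample `x_k` of class `i`, the between-class
#' term uses the inverse-distance weighted mean of the other class; the
#' within-class term uses the weighted mean of its own class excluding the
#' sample itself (the printed self-inclusive form collapses to zero). Each
#' outer product carries the scatter weight `lambda_k / n_i` and the class
#' prior `P_i` (empirical proportions).
#'
#' @param x numeric matrix (samples x features) or a [feature_table()].
#' @param labels two-level factor/character (ignored if `x` is a
#'   `feature_table` with labels).
#' @param features optional feature-name subset.
#' @return List of class `scatter_pair`: `Sb`, `Sw` (symmetric PSD),
#'   `priors`, `n`.
#' @export
np_scatter_matrices <- function(x, labels = NULL, features = NULL) {
  if (inherits(x, "feature_table")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$values
  }
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stopf("exactly two classes required")
  ns <- table(labels)
  if (any(ns < 2)) stopf("each class needs >= 2 samples")
  d <- ncol(x)
  P <- as.numeric(ns) / sum(ns)
  Sb <- Sw <- matrix(0, d, d)
  X <- split.data.frame(x, labels)
  for (i in 1:2) {
    Xi <- X[[i]]; Xj <- X[[3 - i]]
    ni <- nrow(Xi)
    # between-class: weighted means in the other class
    Mb <- .pairwise_weighted_means(Xi, Xj)
    Db <- Xi - Mb
    lamb <- .inv_dist_weights_vec(sqrt(rowSums(Db^2)))
    Sb <- Sb + P[i] * crossprod(Db, Db * (lamb / ni))
    # within-class: weighted means in the own class, self excluded
    Mw <- .pairwise_weighted_means(Xi, Xi, exclude_self = TRUE)
    Dw <- Xi - Mw
    lamw <- .inv_dist_weights_vec(sqrt(rowSums(Dw^2)))
    Sw <- Sw + P[i] * crossprod(Dw, Dw * (lamw / ni))
  }
  dimnames(Sb) <- dimnames(Sw) <- list(colnames(x), colnames(x))
  structure(list(Sb = Sb, Sw = Sw, priors = P, n = as.numeric(ns)),
            class = "scatter_pair")
}

#' Class-separability criterion from a scatter pair
#'
#' The scalarized ratio of between- to within-class scatter:
#' `trace(Sw^-1 Sb)` (default) or `det(Sb)/det(Sw)`. A ridge
#' `eps * I` with `eps = 1e-8 * trace(Sw)/d` is added when `Sw` is poorly
#' conditioned (duplicate or collinear features).
#'
#' @param scatter a `scatter_pair` from [np_scatter_matrices()].
#' @param method `"trace"` or `"det"`.
#' @return Nonnegative scalar; larger means better separated classes.
#' @export
separability_criterion <- function(scatter, method = c("trace", "det")) {
  method <- match.arg(method)
  Sw <- scatter$Sw; Sb <- scatter$Sb
  d <- nrow(Sw)
  tr <- sum(diag(Sw))
  if (tr <= 0) stopf("within-class scatter is numerically zero")
  if (rcond(Sw) < 1e-10) Sw <- Sw + diag(1e-8 * tr / d, d)
  if (method == "trace") sum(diag(solve(Sw, Sb)))
  else det(Sb) / det(Sw)
}

#' Criterion value of a feature subset
#'
#' @param x matrix or [feature_table()] with labels.
#' @param labels class labels (if `x` is a matrix).
#' @param features feature-name subset.
#' @param method see [separability_criterion()].
#' @return Scalar criterion value.
#' @export
subset_criterion <- function(x, labels = NULL, features = NULL,
                             method = "trace") {
  separability_criterion(np_scatter_matrices(x, labels, features), method)
}

#' Floating stepwise feature selection
#'
#' Sequential floating forward search driven by the nonparametric
#' separability criterion: at each step the feature whose addition maximizes
#' the criterion joins the subset; then, while excluding some single feature
#' (other than the one just added) strictly improves the criterion, the best
#' such exclusion is applied. Stops when the subset reaches `n_target`
#' features. Ties break by column order; the search is deterministic.
#'
#' Features are z-scored (per feature, over the supplied table) before any
#' distance computation by default, so heterogeneous units cannot dominate
#' the Euclidean metric.
#'
#' @param table a [feature_table()] with labels.
#' @param n_target requested subset size.
#' @param standardize z-score features first (default `TRUE`).
#' @param method criterion scalarization, see [separability_criterion()].
#' @param floating allow conditional exclusions (default `TRUE`); `FALSE`
#'   gives plain forward selection.
#' @return A `selection_trace`: list with `selected` (ordered names),
#'   `criterion` (value after each completed addition step), and `log`
#'   (data.frame of add/remove actions with criterion values).
#' @export
stepwise_select <- function(table, n_target, standardize = TRUE,
                            method = "trace", floating = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stopf("feature table must carry labels")
  x <- table$values
  p <- ncol(x)
  if (p < 2) stopf("need at least 2 features")
  if (n_target < 1 || n_target > p)
    stopf("n_target must be in [1, %d]", p)
  if (standardize) {
    mu <- colMeans(x)
    sig <- apply(x, 2, sd)
    sig[sig == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sig, "/")
  }
  labels <- table$labels
  # degenerate subsets (all-constant within classes: Sw numerically zero)
  # carry no usable signal and score 0 rather than aborting the search
  crit <- function(subset) tryCatch(
    subset_criterion(x, labels, subset, method),
    error = function(e) 0)

  selected <- character()
  log <- data.frame(step = integer(), action = character(),
                    feature = character(), criterion = numeric(),
                    stringsAsFactors = FALSE)
  crit_path <- numeric()
  step <- 0L
  tol <- 1e-10
  best_at_size <- rep(-Inf, p) # floating-search guard: best F per subset size
  while (length(selected) < n_target) {
    step <- step + 1L
    candidates <- setdiff(colnames(x), selected)
    fs <- vapply(candidates, function(f) crit(c(selected, f)), numeric(1))
    best <- candidates[which.max(fs)] # which.max: first max, column order
    selected <- c(selected, best)
    f_now <- max(fs)
    best_at_size[length(selected)] <- max(best_at_size[length(selected)], f_now)
    log <- rbind(log, data.frame(step = step, action = "add", feature = best,
                                 criterion = f_now))
    # conditional exclusion: drop any feature (not the newcomer) whose
    # removal strictly improves on the best subset seen at the smaller size
    while (floating && length(selected) > 2) {
      removable <- setdiff(selected, best)
      fr <- vapply(removable, function(f) crit(setdiff(selected, f)),
                   numeric(1))
      if (max(fr) > f_now + tol &&
          max(fr) > best_at_size[length(selected) - 1] + tol) {
        worst <- removable[which.max(fr)]
        selected <- setdiff(selected, worst)
        f_now <- max(fr)
        best_at_size[length(selected)] <- f_now
        log <- rbind(log, data.frame(step = step, action = "remove",
                                     feature = worst, criterion = f_now))
      } else break
    }
    crit_path <- c(crit_path, f_now)
  }
  structure(list(selected = selected, criterion = crit_path, log = log,
                 n_target = n_target, method = method,
                 standardize = standardize),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d features selected (criterion %s)\n",
              length(x$selected), x$method))
  for (i in seq_along(x$selected))
    cat(sprintf("  %2d. %-24s F = %.4g\n", i, x$selected[i],
                x$criterion[min(i, length(x$criterion))]))
  invisible(x)
}
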