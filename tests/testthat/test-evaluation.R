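test_that("error rate and sensitivity follow their definitions", {
  truth <- rep(c("suitable", "unsuitable"), c(20, 80))
  perfect <- truth
  expect_equal(error_rate(perfect, truth), 0)
  expect_equal(sensitivity(perfect, truth), 1)
  wrong7 <- perfect; wrong7[c(3, 25, 40, 55, 70, 85, 99)] <-
    ifelse(truth[c(3, 25, 40, 55, 70, 85, 99)] == "suitable",
           "unsuitable", "suitable")
  expect_equal(error_rate(wrong7, truth), 0.07)
  miss1 <- perfect; miss1[20] <- "unsuitable"
  expect_equal(sensitivity(miss1, truth), 19 / 20)
  # error + accuracy = 1
  expect_equal(error_rate(wrong7, truth) + mean(wrong7 == truth), 1)
  expect_error(sensitivity(rep("unsuitable", 3), rep("unsuitable", 3)),
               "no positive")
})

test_that("ROC curves are anchored, monotone, and AUC equals concordance", {
  truth <- c(rep("suitable", 4), rep("unsuitable", 4))
  sep <- c(4, 3.5, 3, 2.5, 2, 1, 0.5, 0)
  expect_equal(auc(sep, truth), 1)
  expect_equal(auc(rep(1, 8), truth), 0.5)
  r <- roc_curve(sep, truth)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  # exhaustive-concordance equality on random small instances (with ties)
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    truth <- sample(rep(c("suitable", "unsuitable"), c(2, n - 2)))
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(auc(scores, truth), oracle_auc(scores, truth),
                 tolerance = 1e-12)
    rr <- roc_curve(scores, truth)
    expect_true(all(diff(rr$fpr) >= 0))
    expect_true(all(diff(rr$tpr) >= 0))
  }
  # independent library cross-check
  set.seed(23)
  sc <- rnorm(60)
  tr <- sample(rep(c("suitable", "unsuitable"), 30))
  p <- pROC::roc(response = tr, predictor = sc, levels = c("unsuitable", "suitable"),
                 direction = "<", quiet = TRUE)
  expect_equal(auc(sc, tr), as.numeric(pROC::auc(p)), tolerance = 1e-12)
  expect_error(auc(sc, rep("suitable", 60)), "both classes")
})

test_that("stratified bootstrap intervals are sane, reproducible, and stable in B", {
  truth <- rep(c("suitable", "unsuitable"), each = 40)
  set.seed(24)
  scores <- c(rnorm(40, 1.2), rnorm(40))
  ci <- bootstrap_ci(auc, scores, truth, B = 500, seed = 7)
  expect_lte(ci[["low"]], auc(scores, truth))
  expect_gte(ci[["high"]], auc(scores, truth))
  expect_true(all(ci >= 0 & ci <= 1))
  expect_identical(bootstrap_ci(auc, scores, truth, B = 500, seed = 7), ci)
  # constant metric: zero-width interval
  flat <- bootstrap_ci(function(s, t) 0.42, scores, truth, B = 100, seed = 1)
  expect_equal(unname(diff(flat)), 0)
  # endpoints stabilize as B grows
  c1 <- bootstrap_ci(auc, scores, truth, B = 1000, seed = 11)
  c2 <- bootstrap_ci(auc, scores, truth, B = 2000, seed = 12)
  expect_lt(max(abs(c1 - c2)), 0.01)
  expect_error(bootstrap_ci(auc, scores, truth, B = 50), "B must")
})

test_that("bootstrap interval coverage of the true AUC is near nominal", {
  # Gaussian two-class model with known AUC = pnorm(delta / sqrt(2))
  delta <- 1
  true_auc <- pnorm(delta / sqrt(2))
  truth <- rep(c("suitable", "unsuitable"), each = 40)
  hits <- vapply(1:200, function(r) {
    scores <- with_seed(1000 + r, c(rnorm(40, delta), rnorm(40)))
    ci <- bootstrap_ci(auc, scores, truth, B = 200, seed = r)
    ci[["low"]] <= true_auc && true_auc <= ci[["high"]]
  }, logical(1))
  expect_equal(mean(hits), 0.9, tolerance = 0.045)
})

test_that("effect size follows its closed form and is scale-invariant", {
  a <- c(0.5, 1.5); b <- c(-0.5, 0.5) # means 1, 0; variances 0.5, 0.5
  expect_equal(effect_size(a, b), 1)
  expect_equal(effect_size(c(0, 2), c(-1, 1)), 1 / 2)
  expect_equal(effect_size(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(25)
  g1 <- rnorm(30, 2); g2 <- rnorm(30)
  expect_equal(effect_size(g1 * 3.7, g2 * 3.7), effect_size(g1, g2))
  expect_error(effect_size(c(1, 1), c(2, 2)), "variances zero")
})

test_that("evaluate_classifier assembles a coherent report", {
  tab <- generate_feature_dataset(40, 3, 2, 2.5, seed = 31)
  test <- generate_feature_dataset(30, 3, 2, 2.5, seed = 32)
  model <- train_classifier(tab, "knn")
  rep_ <- evaluate_classifier(model, test, B = 200, seed = 5)
  expect_s3_class(rep_, "eval_report")
  expect_true(rep_$auc >= 0 && rep_$auc <= 1)
  expect_lte(rep_$ci$auc[["low"]], rep_$auc)
  expect_gte(rep_$ci$auc[["high"]], rep_$auc)
  expect_equal(rep_$n, 60)
})

test_that("the feature-count sweep produces full curves and a gap statistic", {
  train <- generate_feature_dataset(30, 3, 3, 2, seed = 41)
  test <- generate_feature_dataset(25, 3, 3, 2, seed = 42)
  sw <- feature_count_sweep(train, test, max_features = 3,
                            method = "knn", B = 100, seed = 2)
  expect_equal(nrow(sw$curves), 3)
  expect_true(all(is.finite(sw$curves$test_error)))
  expect_true(all(is.finite(sw$curves$loocv_error)))
  expect_true(all(is.finite(sw$curves$auc)))
  expect_length(sw$gap, 3)
  expect_true(is.finite(sw$p_value))
})
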