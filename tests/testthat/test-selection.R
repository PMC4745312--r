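test_that("inverse-distance weights and weighted means match hand values", {
  # two equidistant reference points share the mass
  expect_equal(inverse_distance_weights(c(0, 0), rbind(c(1, 0), c(-1, 0))),
               c(0.5, 0.5))
  # singleton class takes all mass; weighted mean is the point itself
  expect_equal(inverse_distance_weights(c(3, 4), rbind(c(7, 7))), 1)
  expect_equal(weighted_class_mean(c(3, 4), rbind(c(7, 7))), c(7, 7))
  # 1-D: x = 0 against {1, 3} gives weights 0.75 / 0.25
  expect_equal(inverse_distance_weights(0, rbind(1, 3)), c(0.75, 0.25))
  expect_equal(weighted_class_mean(0, rbind(1, 3)), 1.5)
  # equidistant two-point class {0, 2} has weighted mean 1
  expect_equal(weighted_class_mean(1, rbind(0, 2)), 1)
  # coincident reference points tie-share the full mass
  expect_equal(inverse_distance_weights(c(1, 1), rbind(c(1, 1), c(1, 1), c(5, 5))),
               c(0.5, 0.5, 0))
  expect_error(inverse_distance_weights(1, matrix(0, 0, 1)), "empty")
  # random 2-D instances match the loop oracle to 1e-12
  set.seed(14)
  for (rep in 1:10) {
    x <- rnorm(2)
    R <- matrix(rnorm(12), 6, 2)
    expect_equal(weighted_class_mean(x, R), oracle_wmean(x, R),
                 tolerance = 1e-12)
  }
})

test_that("scatter weights normalize to one and tie-share degenerate mass", {
  X <- rbind(c(0, 0), c(2, 0), c(0, 2))
  M <- rbind(c(1, 0), c(1, 0), c(0, 1)) # all at distance 1
  expect_equal(scatter_weights(X, M), rep(1 / 3, 3))
  set.seed(15)
  for (rep in 1:5) {
    Xi <- matrix(rnorm(10), 5, 2)
    Mi <- matrix(rnorm(10), 5, 2)
    expect_equal(sum(scatter_weights(Xi, Mi)), 1)
  }
  expect_warning(scatter_weights(rbind(c(1, 1), c(0, 0)),
                                 rbind(c(1, 1), c(3, 3))), "coincide")
})

test_that("scatter matrices equal the literal loop transcription", {
  # the worked 1-D instance
  X1 <- matrix(c(0, 1), 2, 1); X2 <- matrix(c(2, 3), 2, 1)
  want <- oracle_scatter(X1, X2)
  got <- np_scatter_matrices(rbind(X1, X2),
                             rep(c("suitable", "unsuitable"), each = 2))
  expect_equal(unname(got$Sb), want$Sb, tolerance = 1e-12)
  expect_equal(unname(got$Sw), want$Sw, tolerance = 1e-12)
  # random instances, n <= 10, d <= 3
  set.seed(16)
  for (rep in 1:25) {
    d <- sample(1:3, 1)
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    X1 <- matrix(rnorm(n1 * d), n1, d)
    X2 <- matrix(rnorm(n2 * d, 1), n2, d)
    want <- oracle_scatter(X1, X2)
    got <- np_scatter_matrices(rbind(X1, X2),
                               c(rep("suitable", n1), rep("unsuitable", n2)))
    expect_equal(unname(got$Sb), want$Sb, tolerance = 1e-12)
    expect_equal(unname(got$Sw), want$Sw, tolerance = 1e-12)
    # symmetry and positive semidefiniteness
    expect_equal(got$Sb, t(got$Sb))
    expect_gte(min(eigen(got$Sw, symmetric = TRUE)$values), -1e-8)
    expect_gte(min(eigen(got$Sb, symmetric = TRUE)$values), -1e-8)
  }
  expect_error(np_scatter_matrices(matrix(rnorm(6), 3, 2),
                                   c("suitable", "suitable", "unsuitable")),
               ">= 2 samples")
})

test_that("the criterion ranks separated above overlapping classes and grows with separation", {
  set.seed(17)
  n <- 200
  f_of <- function(delta, seed) {
    tab <- generate_feature_dataset(n, 1, 0, delta, seed = seed)
    subset_criterion(tab$values, tab$labels)
  }
  fs <- vapply(c(0, 1, 2, 4), f_of, numeric(1), seed = 23)
  expect_true(all(diff(fs) > 0))
  # duplicated identical classes: negligible separability
  x <- matrix(rnorm(60), 30, 2)
  dup <- rbind(x, x)
  sc <- np_scatter_matrices(dup, rep(c("suitable", "unsuitable"), each = 30))
  expect_lt(sum(diag(sc$Sb)), sum(diag(sc$Sw)) * 0.05)
  # permutation invariance
  tab <- generate_feature_dataset(30, 2, 1, 2, seed = 3)
  perm <- sample(nrow(tab$values))
  expect_equal(subset_criterion(tab$values, tab$labels),
               subset_criterion(tab$values[perm, ], tab$labels[perm]),
               tolerance = 1e-9)
})

test_that("the criterion is exactly invariant under similarity transforms", {
  set.seed(18)
  x <- rbind(matrix(rnorm(60), 20, 3), matrix(rnorm(60, 1.5), 20, 3))
  y <- rep(c("suitable", "unsuitable"), each = 20)
  F0 <- subset_criterion(x, y)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3))) * 1.7 # orthogonal x scale
  expect_equal(subset_criterion(x %*% Q, y), F0, tolerance = 1e-6)
  shifted <- sweep(x, 2, c(5, -3, 100), "+")
  expect_equal(subset_criterion(shifted, y), F0, tolerance = 1e-6)
})

test_that("floating stepwise search finds planted features and handles edge cases", {
  tab <- generate_feature_dataset(100, 2, 8, 3, seed = 44)
  tr <- stepwise_select(tab, 3)
  expect_true(all(c("inf_01", "inf_02") %in% tr$selected))
  expect_length(tr$criterion, 3)
  expect_equal(nrow(tr$log[tr$log$action == "add", ]) -
               nrow(tr$log[tr$log$action == "remove", ]), 3)
  # n_target = p selects everything
  small <- generate_feature_dataset(20, 2, 1, 1, seed = 2)
  expect_setequal(stepwise_select(small, 3)$selected,
                  colnames(small$values))
  expect_error(stepwise_select(small, 9), "n_target")
  # an exact duplicate of a selected feature contributes nothing to the
  # criterion (the ridge renders the redundant direction inert)
  f1 <- subset_criterion(scale(tab$values), tab$labels, "inf_01")
  dup_vals <- cbind(tab$values[, "inf_01", drop = FALSE],
                    inf_dup = tab$values[, "inf_01"])
  f_dup <- subset_criterion(scale(dup_vals), tab$labels)
  expect_equal(f_dup, f1, tolerance = 1e-3)
  # forward-only never beats floating at equal subset size
  fl <- stepwise_select(tab, 4, floating = TRUE)
  fw <- stepwise_select(tab, 4, floating = FALSE)
  expect_gte(tail(fl$criterion, 1), tail(fw$criterion, 1) - 1e-9)
  # determinism
  expect_identical(stepwise_select(tab, 3)$selected, tr$selected)
})
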