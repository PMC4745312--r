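test_that("eccentricity matches closed forms and the moment oracle", {
  expect_lt(feat_eccentricity(disk_mask(61, 31, 31, 25)), 0.02)
  # a = 2b ellipse: sqrt(3)/2
  ell <- ellipse_mask_test(81, 30, 15)
  expect_equal(feat_eccentricity(ell), sqrt(3) / 2, tolerance = 0.02)
  # arbitrary blobs agree with the explicit moment-eigenvalue oracle to 1e-6
  set.seed(21)
  for (rep in 1:6) {
    m <- ellipse_mask_test(41, runif(1, 6, 18), runif(1, 4, 12),
                           runif(1, 0, pi))
    m[sample(which(m), 10)] <- FALSE # roughen the shape
    expect_equal(feat_eccentricity(m), oracle_eccentricity(m),
                 tolerance = 1e-6)
  }
  expect_error(feat_eccentricity(matrix(FALSE, 5, 5)), "< 5 px")
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_warning(ecc <- feat_eccentricity(line), "degenerate")
  expect_gt(ecc, 0.999)
})

test_that("shape features are translation-invariant and rotation-tolerant", {
  base <- ellipse_mask_test(61, 20, 11)
  shifted <- matrix(FALSE, 75, 75)
  shifted[9:69, 5:65] <- base
  expect_equal(feat_eccentricity(base), feat_eccentricity(shifted))
  expect_equal(feat_solidity(base), feat_solidity(shifted))
  rot <- t(base)[, nrow(base):1] # 90 degree rotation
  expect_equal(feat_eccentricity(base), feat_eccentricity(rot),
               tolerance = 1e-6)
  expect_equal(feat_solidity(base), feat_solidity(rot), tolerance = 0.01)
})

test_that("solidity matches the hull oracle and decreases under carving", {
  rect <- matrix(FALSE, 14, 14); rect[3:12, 4:11] <- TRUE
  expect_equal(feat_solidity(rect), 1)
  plus <- matrix(FALSE, 15, 15)
  plus[7:9, 2:14] <- TRUE; plus[2:14, 7:9] <- TRUE
  expect_lt(feat_solidity(plus), 0.9)
  set.seed(31)
  for (rep in 1:5) {
    m <- ellipse_mask_test(31, runif(1, 5, 12), runif(1, 4, 9), runif(1, 0, pi))
    A <- sum(m)
    expect_equal(feat_solidity(m), A / oracle_hull_pixel_count(m))
  }
  # carving a concavity strictly decreases solidity
  m <- disk_mask(41, 21, 21, 15)
  carved <- m & !disk_mask(41, 21, 36, 8)
  expect_lt(feat_solidity(carved), feat_solidity(m))
})

test_that("normalized variance and kurtosis follow their moment definitions", {
  const <- matrix(100, 8, 8); all8 <- matrix(TRUE, 8, 8)
  expect_equal(feat_normalized_variance(const, all8), 0)
  two <- matrix(c(0, 2), 8, 8) # equal mix of 0 and 2
  expect_equal(feat_normalized_variance(two, all8), 1)
  expect_equal(feat_normalized_kurtosis(two, all8), 1)
  expect_error(feat_normalized_kurtosis(const, all8), "zero variance")
  expect_error(feat_normalized_variance(matrix(0, 4, 4), matrix(TRUE, 4, 4)),
               "mean")
  # large Gaussian sample: kurtosis 3
  set.seed(5)
  g <- matrix(rnorm(1e5, 100, 10), 250, 400)
  expect_equal(feat_normalized_kurtosis(g, matrix(TRUE, 250, 400)), 3,
               tolerance = 0.05)
})

test_that("entropy matches its histogram definition exactly", {
  all16 <- matrix(TRUE, 16, 16)
  expect_equal(feat_entropy(matrix(7, 16, 16), all16), 0)
  uniform <- matrix(0:255, 16, 16)
  expect_equal(feat_entropy(uniform, all16), 8)
  set.seed(6)
  crop <- matrix(runif(256, 0, 256), 16, 16)
  mask <- matrix(runif(256) < 0.8, 16, 16)
  expect_equal(feat_entropy(crop, mask), oracle_entropy(crop, mask),
               tolerance = 1e-9)
})

test_that("co-occurrence energy matches brute-force pair enumeration", {
  all8 <- matrix(TRUE, 8, 8)
  expect_equal(feat_glcm_energy(matrix(9, 8, 8), all8), 1)
  stripes <- matrix(c(40, 200), 8, 8)
  expect_lt(feat_glcm_energy(stripes, all8), 1)
  set.seed(7)
  for (rep in 1:4) {
    crop <- matrix(runif(64, 0, 256), 8, 8)
    mask <- matrix(runif(64) < 0.85, 8, 8)
    if (sum(mask) < 10) next
    expect_equal(feat_glcm_energy(crop, mask),
                 oracle_glcm_energy(crop, mask), tolerance = 1e-12)
  }
  expect_error(feat_glcm_energy(matrix(1, 3, 3), matrix(TRUE, 3, 3)),
               "pairs")
})

test_that("gabor response variance behaves like an oriented band-pass statistic", {
  all64 <- matrix(TRUE, 64, 64)
  expect_equal(feat_gabor_variance(matrix(50, 64, 64), all64), 0)
  # grating at frequency u along x: single-orientation response maximal at 0
  xx <- matrix(1:64, 64, 64, byrow = TRUE)
  grating <- 128 + 100 * cos(2 * pi * 0.1 * xx)
  vs <- vapply(c(0, 45, 90, 135) * pi / 180, function(th) {
    resp <- cellcull:::as_mat(EBImage::filter2(
      grating, cellcull:::gabor_kernel(theta = th), boundary = "replicate"))
    var(as.vector(resp))
  }, numeric(1))
  expect_equal(which.max(vs), 1L)
  # 4-orientation average is invariant to 90 degree rotation
  set.seed(8)
  tex <- matrix(runif(64 * 64, 0, 255), 64, 64)
  rot <- t(tex)[, 64:1]
  expect_equal(feat_gabor_variance(tex, all64),
               feat_gabor_variance(rot, all64), tolerance = 1e-6)
  expect_error(feat_gabor_variance(matrix(1, 10, 10), matrix(TRUE, 10, 10)),
               "kernel support")
})

test_that("masked features ignore pixels outside the mask", {
  cell <- render_cell("suitable", 30, 5, seed = 3)
  gray <- to_grayscale(cell$crop)
  gray2 <- gray
  gray2[!cell$mask] <- 13 # scribble on the background
  for (f in list(feat_normalized_variance, feat_normalized_kurtosis,
                 feat_entropy, feat_glcm_energy, feat_gabor_variance))
    expect_equal(f(gray, cell$mask), f(gray2, cell$mask))
})

test_that("feature vectors follow the registry and are deterministic", {
  cell <- render_cell("suitable", 35, 4, seed = 10)
  v7 <- compute_features(cell, feature_registry("core"))
  expect_length(v7, 7)
  expect_named(v7, c("eccentricity", "solidity", "normalized_variance",
                     "normalized_kurtosis", "entropy", "glcm_energy",
                     "gabor_variance"))
  expect_true(all(is.finite(v7)))
  expect_identical(compute_features(cell), compute_features(cell))
  expect_error(feature_registry(c("entropy", "bogus")), "unknown features")
})

test_that("suitable vs unsuitable feature differences point the documented way", {
  # mirrors the worked-example contrast: suitable cells are rounder,
  # more solid, smoother (lower variance/entropy, higher energy)
  pairs <- matched_pairs()
  cmp <- function(feat, dir) {
    wins <- vapply(pairs, function(p) {
      fs <- compute_features(p$suitable, feature_registry("core"))
      fu <- compute_features(p$folded, feature_registry("core"))
      if (dir == "lower") fs[[feat]] < fu[[feat]] else fs[[feat]] > fu[[feat]]
    }, logical(1))
    mean(wins)
  }
  expect_gte(cmp("eccentricity", "lower"), 5 / 6)
  expect_gte(cmp("solidity", "higher"), 5 / 6)
  expect_gte(cmp("entropy", "lower"), 5 / 6)
  expect_gte(cmp("normalized_variance", "lower"), 5 / 6)
  expect_gte(cmp("glcm_energy", "higher"), 5 / 6)
})

test_that("feature tables assemble labels and drop failing objects", {
  pairs <- matched_pairs()[1:3]
  objs <- unlist(lapply(pairs, function(p) {
    p$suitable$label <- "suitable"; p$folded$label <- "unsuitable"
    list(p$suitable, p$folded)
  }), recursive = FALSE)
  tab <- compute_feature_table(objs, feature_registry("core"))
  expect_identical(dim(tab), c(6L, 7L))
  expect_equal(as.vector(table(tab$labels)), c(3, 3))
  # CSV round-trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, f)
  back <- read_feature_csv(f)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_equal(as.character(back$labels), as.character(tab$labels))
})
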