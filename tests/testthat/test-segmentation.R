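test_that("bicubic downsampling halves dimensions and preserves smooth content", {
  big <- matrix(runif(1024 * 1280, 0, 255), 1024, 1280)
  expect_identical(dim(downsample_half(big)), c(512L, 640L))
  odd <- matrix(0, 11, 13)
  expect_identical(dim(downsample_half(odd)), c(6L, 7L))
  # constant in, constant out
  expect_equal(downsample_half(matrix(42, 16, 16)),
               matrix(42, 8, 8), tolerance = 1e-9)
  # down- then up-sampling a smooth ramp stays within 1 gray level
  ramp <- outer(seq(0, 120, length.out = 64), seq(0, 80, length.out = 64), "+")
  down <- downsample_half(ramp)
  up <- cellcull:::resize_bicubic_cpp(down, 64, 64)
  interior <- up[5:60, 5:60] - ramp[5:60, 5:60]
  expect_lt(max(abs(interior)), 1)
  expect_error(downsample_half(matrix(0, 1, 5)), "too small")
})

test_that("contrast flattening implements the H-transform definition", {
  profile <- matrix(10, 3, 40)
  profile[2, 15:20] <- 10 + 7  # bump of depth 7
  # zero depth: identity
  expect_equal(flatten_contrast(profile, 0, 0), profile)
  # bump shallower than h: flattened away
  flat <- flatten_contrast(profile, 0, 8 / 255)
  expect_equal(max(flat) - min(flat), 0)
  # bump deeper than h: preserved with depth d - h
  part <- flatten_contrast(profile, 0, 3 / 255)
  expect_equal(max(part) - min(part), 4)
  # dual behaviour for minima
  pit <- 20 - (profile - 10)
  filled <- flatten_contrast(pit, 8 / 255, 0)
  expect_equal(max(filled) - min(filled), 0)
  # output range never exceeds input range
  noisy <- matrix(runif(400, 0, 255), 20, 20)
  out <- flatten_contrast(noisy, 0.05, 0.05)
  expect_gte(min(out), min(noisy))
  expect_lte(max(out), max(noisy))
})

test_that("reconstruction matches an iterative-dilation oracle on small images", {
  set.seed(4)
  for (rep in 1:5) {
    mask <- matrix(runif(15 * 12, 0, 10), 15, 12)
    marker <- pmax(mask - runif(1, 1, 4), 0)
    got <- reconstruct_dilation(marker, mask)
    # oracle: dilate marker under mask until fixpoint (3x3 max filter)
    cur <- marker
    repeat {
      pad <- matrix(-Inf, 17, 14)
      pad[2:16, 2:13] <- cur
      dil <- cur
      for (dr in -1:1) for (dc in -1:1)
        dil <- pmax(dil, pad[2:16 + dr, 2:13 + dc])
      nxt <- pmin(dil, mask)
      if (identical(nxt, cur)) break
      cur <- nxt
    }
    expect_equal(got, cur, tolerance = 1e-12)
  }
})

test_that("edge detection fires on steps and circles, not on flat fields", {
  expect_false(any(edge_image(matrix(7, 30, 30))))
  # vertical step: edge pixels form a band at the step column
  step <- cbind(matrix(40, 30, 15), matrix(200, 30, 15))
  e <- edge_image(step)
  cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_true(all(abs(cols - 15.5) <= 3))
  expect_true(any(e))
  # synthetic disk: edges within 2 px of the analytic circle
  g <- matrix(200, 64, 64)
  g[disk_mask(64, 32, 32, 18)] <- 90
  ed <- which(edge_image(g), arr.ind = TRUE)
  rad <- sqrt((ed[, 1] - 32)^2 + (ed[, 2] - 32)^2)
  expect_true(all(abs(rad - 18) <= 2.5))
})

test_that("morphological cleanup closes, fills, and prunes like the naive oracle", {
  cfg <- seg_config(closing_radius = 2, min_object_area = 20,
                    border_policy = "keep")
  # circle outline becomes a filled disk
  ring <- disk_mask(40, 20, 20, 12) & !disk_mask(40, 20, 20, 9)
  out <- morphological_cleanup(ring, cfg)
  expect_true(all(out[disk_mask(40, 20, 20, 11)]))
  # sub-threshold specks disappear
  speck <- matrix(FALSE, 30, 30); speck[c(40, 300, 525)] <- TRUE
  expect_false(any(morphological_cleanup(speck, cfg)))
  # component count equals the brute-force oracle on random small inputs
  set.seed(12)
  for (rep in 1:4) {
    m <- matrix(runif(28 * 28) < 0.25, 28, 28)
    got <- max(EBImage::bwlabel(morphological_cleanup(m, cfg) * 1))
    want <- oracle_cleanup_count(m, 2, 20)
    expect_equal(got, want)
  }
})

test_that("object extraction yields ordered records whose boundaries match their masks", {
  rr <- matrix(1:70, 70, 90); cc <- matrix(1:90, 70, 90, byrow = TRUE)
  m <- (rr - 18)^2 + (cc - 22)^2 <= 12^2 | (rr - 50)^2 + (cc - 62)^2 <= 14^2
  img <- array(100, c(70, 90, 3))
  recs <- extract_objects(m, img)
  expect_length(recs, 2)
  # deterministic order by top-left bbox corner
  expect_lt(recs[[1]]$bbox[["row0"]], recs[[2]]$bbox[["row0"]])
  expect_identical(recs, extract_objects(m, img))
  for (r in recs) {
    # shoelace area of the boundary approximates mask area within 10%
    area <- abs(cellcull:::.shoelace(r$boundary))
    expect_lt(abs(area - sum(r$mask)) / sum(r$mask), 0.1)
    # crop matches bbox extent
    expect_identical(dim(r$mask),
                     c(r$bbox[["row1"]] - r$bbox[["row0"]] + 1L,
                       r$bbox[["col1"]] - r$bbox[["col0"]] + 1L))
  }
  expect_length(extract_objects(matrix(FALSE, 10, 10), array(0, c(10, 10, 3))), 0)
})

test_that("the full cascade finds planted cells and nothing on blank scenes", {
  sc <- small_scene()
  blank <- slide_map(sc$background, sc$spec$tile_grid, sc$spec$tile_shape)
  expect_length(segment_slidemap(blank, sc$background), 0)

  recs <- segment_slidemap(sc$map, sc$background)
  m <- match_truth_objects(recs, sc$truth, dim(sc$scene))
  expect_gte(mean(m$iou >= 0.7), 5 / 6) # small scene: allow one miss
  # deterministic
  recs2 <- segment_slidemap(sc$map, sc$background)
  expect_identical(recs, recs2)
  # masks disjoint and in bounds
  for (r in recs) {
    expect_gte(r$bbox[["row0"]], 1)
    expect_lte(r$bbox[["row1"]], nrow(sc$scene))
  }
})
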