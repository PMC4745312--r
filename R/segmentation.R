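#' Segmentation configuration
#'
#' Parameters of the object-detection cascade. Depths of the H-minima and
#' H-maxima flattening are fractions of the 0-255 dynamic range; the minimum
#' object area is in full-resolution pixels and is rescaled internally when
#' the mask is computed at reduced resolution.
#'
#' @param downsample_factor integer; 2 halves each dimension (bicubic).
#' @param h_minima_depth,h_maxima_depth flattening depths in `(0, 1)` of the
#'   dynamic range (0 disables).
#' @param log_sigma Laplacian-of-Gaussian scale, pixels.
#' @param closing_radius disk radius (pixels, at working resolution) used to
#'   close edge contours.
#' @param min_object_area minimum object area, full-resolution px^2.
#' @param border_policy `"drop"` discards components touching the frame
#'   border (they cannot be verified whole); `"keep"` retains them.
#' @param edge_combine `"or"` (inclusive union of Sobel and LoG edges,
#'   default) or `"and"`.
#' @return A `seg_config` list.
#' @export
seg_config <- function(downsample_factor = 2L,
                       h_minima_depth = 0.05,
                       h_maxima_depth = 0.05,
                       log_sigma = 2,
                       closing_radius = 4L,
                       min_object_area = 400,
                       border_policy = c("drop", "keep"),
                       edge_combine = c("or", "and")) {
  if (h_minima_depth < 0 || h_minima_depth >= 1 ||
      h_maxima_depth < 0 || h_maxima_depth >= 1)
    stopf("h depths must be in [0, 1) of dynamic range")
  if (min_object_area <= 0) stopf("min_object_area must be positive")
  structure(list(downsample_factor = as.integer(downsample_factor),
                 h_minima_depth = h_minima_depth,
                 h_maxima_depth = h_maxima_depth,
                 log_sigma = log_sigma,
                 closing_radius = as.integer(closing_radius),
                 min_object_area = min_object_area,
                 border_policy = match.arg(border_policy),
                 edge_combine = match.arg(edge_combine)),
            class = "seg_config")
}

#' Halve image resolution by bicubic interpolation
#'
#' Each output dimension is `ceiling(input / 2)`; resampling uses the
#' Catmull-Rom bicubic kernel with centre-aligned pixel mapping.
#'
#' @param image numeric matrix (grayscale).
#' @return Matrix of shape `ceiling(dim / 2)`.
#' @export
downsample_half <- function(image) {
  if (!is.matrix(image)) stopf("expected a grayscale matrix")
  if (nrow(image) < 2 || ncol(image) < 2) stopf("image too small to downsample")
  resize_bicubic_cpp(image, ceiling(nrow(image) / 2), ceiling(ncol(image) / 2))
}

#' Grayscale morphological reconstruction by dilation
#'
#' @param marker,mask numeric matrices with `marker <= mask`.
#' @return The reconstruction of `marker` under `mask` (8-connectivity).
#' @export
reconstruct_dilation <- function(marker, mask) recon_dilate_cpp(marker, mask)

#' H-minima / H-maxima contrast flattening
#'
#' Suppresses regional minima shallower than `h_min` and regional maxima
#' shallower than `h_max` (fractions of the dynamic range) via morphological
#' reconstruction, flattening low-contrast structure while preserving the
#' cell-background contrast. A depth of 0 is the identity.
#'
#' @param gray numeric matrix on the 0-255 scale.
#' @param h_min,h_max depths in `[0, 1)` of the dynamic range.
#' @param dynamic_range full-scale value (default 255).
#' @return Flattened matrix; range within the input range.
#' @export
flatten_contrast <- function(gray, h_min, h_max, dynamic_range = 255) {
  if (h_min < 0 || h_min >= 1 || h_max < 0 || h_max >= 1)
    stopf("h depths must be in [0, 1)")
  out <- gray
  if (h_min > 0) { # H-minima: reconstruction by erosion = inverted dilation
    h <- h_min * dynamic_range
    out <- -recon_dilate_cpp(-(out + h), -out)
  }
  if (h_max > 0) { # H-maxima
    h <- h_max * dynamic_range
    out <- recon_dilate_cpp(out - h, out)
  }
  out
}

# Otsu threshold on a 256-bin histogram of values scaled to [0, 1]
.otsu <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1] + 1) # constant: nothing above threshold
  h <- tabulate(pmin(255L, as.integer((x - rng[1]) / diff(rng) * 256)) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 1))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + (k / 256) * diff(rng)
}

.sobel_edges <- function(gray) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- as_mat(EBImage::filter2(gray, kx, boundary = "replicate"))
  gy <- as_mat(EBImage::filter2(gray, t(kx), boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  mag > .otsu(mag)
}

.log_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- matrix(-r:r, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  y <- t(x)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  k <- (x^2 + y^2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k) # zero-sum so flat regions respond exactly 0
}

.log_edges <- function(gray, sigma) {
  resp <- as_mat(EBImage::filter2(gray, .log_kernel(sigma), boundary = "replicate"))
  # floor guards against FFT round-off (~1e-14) on near-constant images
  thr <- max(0.75 * mean(abs(resp)), 1e-9 * max(abs(gray), 1))
  nr <- nrow(resp); nc <- ncol(resp)
  edge <- matrix(FALSE, nr, nc)
  # zero-crossings against the right and lower neighbour
  right <- resp[, -nc] * resp[, -1] < 0 & abs(resp[, -nc] - resp[, -1]) > thr
  down <- resp[-nr, ] * resp[-1, ] < 0 & abs(resp[-nr, ] - resp[-1, ]) > thr
  edge[, -nc] <- edge[, -nc] | right
  edge[-nr, ] <- edge[-nr, ] | down
  edge
}

#' Edge image from Sobel and Laplacian-of-Gaussian detectors
#'
#' Sobel gradient magnitude (auto-thresholded by Otsu's method) combined
#' with LoG zero-crossings (strength-thresholded at 0.75 of the mean
#' absolute response), union by default.
#'
#' @param gray numeric matrix.
#' @param log_sigma LoG scale in pixels.
#' @param combine `"or"` or `"and"`.
#' @return Logical matrix of edge pixels.
#' @export
edge_image <- function(gray, log_sigma = 2, combine = c("or", "and")) {
  combine <- match.arg(combine)
  if (!is.matrix(gray)) stopf("expected a grayscale matrix")
  s <- .sobel_edges(gray)
  l <- .log_edges(gray, log_sigma)
  if (combine == "or") s | l else s & l
}

#' Morphological cleanup of a binary edge image
#'
#' Closes edge contours with a disk, fills holes, and removes connected
#' components below the (resolution-rescaled) minimum area; optionally drops
#' components touching the frame border.
#'
#' @param binary logical matrix.
#' @param config a [seg_config()].
#' @param scale working-resolution scale factor (2 when the mask was
#'   computed at half resolution); areas are divided by `scale^2`.
#' @return Logical matrix of cleaned object pixels.
#' @export
morphological_cleanup <- function(binary, config = seg_config(), scale = 1) {
  stopifnot(is.logical(binary))
  m <- binary * 1
  if (config$closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * config$closing_radius + 1, shape = "disc")
    m <- as_mat(EBImage::closing(m, brush))
  }
  m <- as_mat(EBImage::fillHull(m))
  lab <- as_mat(EBImage::bwlabel(m > 0))
  min_area <- config$min_object_area / scale^2
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], max(lab))
    drop <- which(areas < min_area)
    if (config$border_policy == "drop") {
      at_border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      drop <- union(drop, setdiff(at_border, 0))
    }
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  lab > 0
}

#' Extract object records from a labeled mask
#'
#' One record per 8-connected component, ordered deterministically by the
#' top-left corner of the bounding box (row-major). Boundaries are traced
#' clockwise from the topmost-leftmost boundary pixel, in full-frame
#' coordinates.
#'
#' @param mask logical matrix aligned with `map`.
#' @param map a [slide_map()] or `h x w x 3` array, for the crops.
#' @return List of object records, each with `object_id`, `mask` (local,
#'   bbox-cropped), `bbox` (`row0, col0, row1, col1`, 1-based), `boundary`
#'   (n x 2 full-frame coordinates), `crop`, `gray_crop`, `label` (`NA`).
#' @export
extract_objects <- function(mask, map) {
  pixels <- if (inherits(map, "slide_map")) map$pixels else map
  if (!identical(dim(mask), dim(pixels)[1:2]))
    stopf("mask and map dimensions differ")
  lab <- as_mat(EBImage::bwlabel(mask * 1))
  n <- max(lab)
  if (n == 0) return(list())
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  r0 <- tapply(idx[, 1], ids, min); r1 <- tapply(idx[, 1], ids, max)
  c0 <- tapply(idx[, 2], ids, min); c1 <- tapply(idx[, 2], ids, max)
  ord <- order(r0, c0)
  records <- vector("list", n)
  for (k in seq_len(n)) {
    i <- ord[k]
    rows <- r0[[i]]:r1[[i]]; cols <- c0[[i]]:c1[[i]]
    local <- lab[rows, cols, drop = FALSE] == i
    bnd <- trace_boundary_cpp(local)
    bnd[, 1] <- bnd[, 1] + r0[[i]] - 1L
    bnd[, 2] <- bnd[, 2] + c0[[i]] - 1L
    records[[k]] <- list(object_id = k,
                         mask = local,
                         bbox = c(row0 = r0[[i]], col0 = c0[[i]],
                                  row1 = r1[[i]], col1 = c1[[i]]),
                         boundary = bnd,
                         crop = pixels[rows, cols, , drop = FALSE],
                         gray_crop = (pixels[rows, cols, 1] +
                                      pixels[rows, cols, 2] +
                                      pixels[rows, cols, 3]) / 3,
                         label = NA_character_)
  }
  records
}

#' Segment a slide-map into object records
#'
#' The full detection cascade: flat-field illumination correction, grayscale
#' conversion, bicubic downsampling to half resolution, H-minima/H-maxima
#' contrast flattening, Sobel + LoG edge detection, morphological cleanup,
#' nearest-neighbour upsampling of the mask back to the full frame, and
#' object extraction. Deterministic throughout.
#'
#' @param map a [slide_map()].
#' @param background blank background image for the flat-field step, or
#'   `NULL` to skip correction.
#' @param config a [seg_config()].
#' @return List of object records (see [extract_objects()]).
#' @export
segment_slidemap <- function(map, background = NULL, config = seg_config()) {
  stopifnot(inherits(map, "slide_map"))
  corrected <- if (is.null(background)) map
               else correct_illumination(map, background)
  gray <- to_grayscale(corrected)
  f <- config$downsample_factor
  work <- gray
  if (f >= 2) for (i in seq_len(round(log2(f)))) work <- downsample_half(work)
  flat <- flatten_contrast(work, config$h_minima_depth, config$h_maxima_depth)
  edges <- edge_image(flat, config$log_sigma, config$edge_combine)
  clean <- morphological_cleanup(edges, config, scale = f)
  # upsample mask to the full frame by nearest neighbour
  full <- clean[pmin(nrow(clean), ceiling(seq_len(nrow(gray)) / f)),
                pmin(ncol(clean), ceiling(seq_len(ncol(gray)) / f)),
                drop = FALSE]
  extract_objects(full, corrected)
}
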