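#' Object shape and texture features
#'
#' The feature bank quantifying each segmented object. The seven headline
#' features — eccentricity, solidity, normalized variance, normalized
#' kurtosis, histogram entropy, co-occurrence energy and Gabor-response
#' variance — are implemented exactly as defined below; a wider registry of
#' standard shape/histogram/color/texture/topology descriptors fills out the
#' feature categories. All gray-level features are computed over masked
#' pixels only, on the 0-255 scale.
#'
#' @name features
NULL

#' Eccentricity of the moment-equivalent ellipse
#'
#' `sqrt(1 - b^2/a^2)` where `a >= b` are the semi-axes of the ellipse with
#' the same second central moments as the mask (pixel centres as unit point
#' masses). 0 for a disk, approaching 1 for a line.
#'
#' @param mask logical matrix with at least 5 foreground pixels.
#' @return Eccentricity in `[0, 1)`; a degenerate (collinear) mask returns
#'   `1 - 1e-6` with a warning.
#' @export
feat_eccentricity <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 5) stopf("mask area %d < 5 px", nrow(pts))
  ctr <- sweep(pts, 2, colMeans(pts))
  C <- crossprod(ctr) / nrow(pts) # population second central moments
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] / max(ev[1], .Machine$double.eps) < 1e-12) {
    warning("degenerate (collinear) mask; eccentricity saturated")
    return(1 - 1e-6)
  }
  sqrt(1 - ev[2] / ev[1])
}

# signed polygon area (shoelace); vertices as (row, col) matrix
.shoelace <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 2] * p[j, 1] - p[j, 2] * p[, 1]) / 2
}

# number of lattice points (pixel centres) inside or on a convex polygon
.hull_pixel_count <- function(pts) {
  hull <- grDevices::chull(pts) # returns clockwise indices for (x=col, y=row)?
  v <- pts[hull, , drop = FALSE]
  if (.shoelace(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  rr <- min(pts[, 1]):max(pts[, 1])
  cc <- min(pts[, 2]):max(pts[, 2])
  gr <- matrix(rr, length(rr), length(cc))
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  inside <- matrix(TRUE, length(rr), length(cc))
  n <- nrow(v)
  tol <- 1e-9
  for (k in seq_len(n)) {
    a <- v[k, ]; b <- v[if (k == n) 1 else k + 1, ]
    # z-component of (b - a) x (p - a) in (x = col, y = row) coordinates;
    # nonnegative for interior points of a counter-clockwise polygon
    cross <- (b[2] - a[2]) * (gr - a[1]) - (b[1] - a[1]) * (gc - a[2])
    inside <- inside & (cross >= -tol)
  }
  sum(inside)
}

#' Solidity: mask area over convex-hull area
#'
#' Both areas are counted in pixels; the hull area is the number of pixel
#' centres inside or on the convex hull of the mask's pixel centres, so a
#' filled convex shape scores exactly 1.
#'
#' @param mask logical matrix with at least 3 foreground pixels.
#' @return Solidity in `(0, 1]`.
#' @export
feat_solidity <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) stopf("mask area %d < 3 px", nrow(pts))
  A <- nrow(pts)
  H <- tryCatch(.hull_pixel_count(pts), error = function(e) A)
  A / max(H, A)
}

#' Normalized variance and kurtosis of masked gray levels
#'
#' Population moments over masked pixels: normalized variance
#' `sigma^2 / mu^2`; normalized (non-excess) kurtosis
#' `E[(x - mu)^4] / sigma^4`, so a Gaussian scores 3.
#'
#' @param gray numeric matrix, 0-255 scale.
#' @param mask logical matrix, same shape, with at least 2 true pixels.
#' @return A single numeric value.
#' @export
feat_normalized_variance <- function(gray, mask) {
  x <- gray[mask]
  if (length(x) < 2) stopf("need >= 2 masked pixels")
  mu <- mean(x)
  if (mu <= 0) stopf("normalized variance undefined for mean <= 0")
  mean((x - mu)^2) / mu^2
}

#' @rdname feat_normalized_variance
#' @export
feat_normalized_kurtosis <- function(gray, mask) {
  x <- gray[mask]
  if (length(x) < 2) stopf("need >= 2 masked pixels")
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 == 0) stopf("kurtosis undefined for zero variance")
  mean((x - mu)^4) / s2^2
}

#' Histogram entropy of masked gray levels
#'
#' Shannon entropy in bits, `-sum(p * log2(p))`, over the normalized 256-bin
#' histogram of masked pixels; in `[0, 8]` for 8-bit data.
#'
#' @inheritParams feat_normalized_variance
#' @return Entropy in bits.
#' @export
feat_entropy <- function(gray, mask) {
  x <- gray[mask]
  if (length(x) < 1) stopf("empty mask")
  bins <- pmin(255L, pmax(0L, as.integer(floor(x))))
  p <- tabulate(bins + 1L, 256L) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Summed masked co-occurrence matrix: offset `offset` in the 8 compass
# directions, gray levels quantized to `levels` bins, normalized to sum 1.
glcm_matrix <- function(gray, mask = NULL, levels = 64L, offset = 5L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  q <- pmin(levels - 1L, pmax(0L, as.integer(floor(gray * levels / 256))))
  dim(q) <- dim(gray)
  nr <- nrow(gray); nc <- ncol(gray)
  counts <- numeric(levels * levels)
  offs <- rbind(c(0, offset), c(offset, offset), c(offset, 0), c(offset, -offset),
                c(0, -offset), c(-offset, -offset), c(-offset, 0), c(-offset, offset))
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    if (max(1, 1 - dr) > min(nr, nr - dr) ||
        max(1, 1 - dc) > min(nc, nc - dc)) next # offset exceeds the crop
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    sel <- mask[rs, cs, drop = FALSE] & mask[rs + dr, cs + dc, drop = FALSE]
    if (!any(sel)) next
    i <- q[rs, cs, drop = FALSE][sel]
    j <- q[rs + dr, cs + dc, drop = FALSE][sel]
    counts <- counts + tabulate(i * levels + j + 1L, levels * levels)
  }
  tot <- sum(counts)
  if (tot == 0) stopf("no valid in-mask pixel pairs at offset %d", offset)
  matrix(counts / tot, levels, levels)
}

#' Gray-level co-occurrence energy
#'
#' Gray levels are quantized to `levels` bins; co-occurrence matrices at a
#' 5-pixel offset in the eight compass directions, restricted to pixel pairs
#' both inside the mask, are summed and normalized; energy is the sum of
#' squared entries, in `(0, 1]` (1 for a constant region).
#'
#' @inheritParams feat_normalized_variance
#' @param levels quantization levels (default 64).
#' @param offset pair offset in pixels (default 5).
#' @return Energy in `(0, 1]`.
#' @export
feat_glcm_energy <- function(gray, mask = NULL, levels = 64L, offset = 5L) {
  M <- glcm_matrix(gray, mask, levels, offset)
  sum(M^2)
}

# Gabor kernel: gaussian envelope times a cosine carrier at orientation theta
gabor_kernel <- function(sigma_x = 4, sigma_y = 4, u = 0.1, theta = 0) {
  r <- ceiling(3 * max(sigma_x, sigma_y))
  x <- matrix(-r:r, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  y <- t(x)
  exp(-(x^2 / sigma_x^2 + y^2 / sigma_y^2) / 2) *
    cos(2 * pi * u * (x * cos(theta) + y * sin(theta)))
}

#' Variance of the Gabor-filtered image
#'
#' Convolves the crop with a Gabor kernel at orientations 0, 45, 90 and 135
#' degrees and returns the variance of the masked response averaged over the
#' four orientations. Pixels outside the mask are replaced by the masked
#' mean before convolution so the value does not depend on background
#' content.
#'
#' @inheritParams feat_normalized_variance
#' @param sigma_x,sigma_y Gaussian envelope scales, pixels.
#' @param u carrier frequency, cycles/pixel.
#' @return Mean masked response variance over the four orientations.
#' @export
feat_gabor_variance <- function(gray, mask = NULL, sigma_x = 4, sigma_y = 4,
                                u = 0.1) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  r <- ceiling(3 * max(sigma_x, sigma_y))
  if (nrow(gray) < 2 * r + 1 || ncol(gray) < 2 * r + 1)
    stopf("crop (%d x %d) smaller than the Gabor kernel support (%d)",
          nrow(gray), ncol(gray), 2 * r + 1)
  g <- gray
  g[!mask] <- mean(gray[mask])
  vs <- vapply(c(0, 45, 90, 135) * pi / 180, function(th) {
    resp <- as_mat(EBImage::filter2(g, gabor_kernel(sigma_x, sigma_y, u, th),
                                    boundary = "replicate"))
    x <- resp[mask]
    mean((x - mean(x))^2)
  }, numeric(1))
  mean(vs)
}

.perimeter_from_mask <- function(mask) {
  b <- trace_boundary_cpp(mask)
  if (nrow(b) < 2) return(1)
  d <- b - b[c(2:nrow(b), 1), ]
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# 8-connectivity Euler number by bit-quad counting
.euler_number <- function(mask) {
  m <- rbind(0, cbind(0, mask * 1, 0), 0)
  nr <- nrow(m); nc <- ncol(m)
  a <- m[-nr, -nc]; b <- m[-nr, -1]; c_ <- m[-1, -nc]; d <- m[-1, -1]
  s <- a + b + c_ + d
  q1 <- sum(s == 1)
  q3 <- sum(s == 3)
  qd <- sum(s == 2 & ((a == 1 & d == 1) | (b == 1 & c_ == 1)))
  (q1 - q3 - 2 * qd) / 4
}

# density of strict 3x3 local extrema of the lightly blurred masked crop
.extrema_density <- function(gray, mask) {
  g <- gauss_blur(gray, 1)
  nr <- nrow(g); nc <- ncol(g)
  if (nr < 3 || nc < 3) return(0)
  core <- g[2:(nr - 1), 2:(nc - 1)]
  ismax <- ismin <- matrix(TRUE, nr - 2, nc - 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- g[2:(nr - 1) + dr, 2:(nc - 1) + dc]
    ismax <- ismax & core > nb
    ismin <- ismin & core < nb
  }
  inmask <- mask[2:(nr - 1), 2:(nc - 1)]
  sum((ismax | ismin) & inmask) / max(sum(mask), 1)
}

# ---- registry ---------------------------------------------------------

core_features <- c("eccentricity", "solidity", "normalized_variance",
                     "normalized_kurtosis", "entropy", "glcm_energy",
                     "gabor_variance")

.feature_funs <- list(
  # headline seven
  eccentricity = function(ctx) feat_eccentricity(ctx$mask),
  solidity = function(ctx) feat_solidity(ctx$mask),
  normalized_variance = function(ctx) feat_normalized_variance(ctx$gray, ctx$mask),
  normalized_kurtosis = function(ctx) feat_normalized_kurtosis(ctx$gray, ctx$mask),
  entropy = function(ctx) feat_entropy(ctx$gray, ctx$mask),
  glcm_energy = function(ctx) sum(ctx$glcm()^2),
  gabor_variance = function(ctx) feat_gabor_variance(ctx$gray, ctx$mask),
  # size and shape
  area = function(ctx) sum(ctx$mask),
  perimeter = function(ctx) .perimeter_from_mask(ctx$mask),
  circularity = function(ctx) 4 * pi * sum(ctx$mask) / .perimeter_from_mask(ctx$mask)^2,
  major_axis_length = function(ctx) {
    pts <- which(ctx$mask, arr.ind = TRUE)
    ctr <- sweep(pts, 2, colMeans(pts))
    4 * sqrt(eigen(crossprod(ctr) / nrow(pts), symmetric = TRUE,
                   only.values = TRUE)$values[1])
  },
  minor_axis_length = function(ctx) {
    pts <- which(ctx$mask, arr.ind = TRUE)
    ctr <- sweep(pts, 2, colMeans(pts))
    4 * sqrt(max(eigen(crossprod(ctr) / nrow(pts), symmetric = TRUE,
                       only.values = TRUE)$values[2], 0))
  },
  extent = function(ctx) sum(ctx$mask) / prod(dim(ctx$mask)),
  # histogram
  gray_mean = function(ctx) mean(ctx$gray[ctx$mask]),
  gray_sd = function(ctx) sd(ctx$gray[ctx$mask]),
  gray_skewness = function(ctx) {
    x <- ctx$gray[ctx$mask]; mu <- mean(x); s <- sqrt(mean((x - mu)^2))
    if (s == 0) 0 else mean((x - mu)^3) / s^3
  },
  gray_p10 = function(ctx) unname(quantile(ctx$gray[ctx$mask], 0.1)),
  gray_p90 = function(ctx) unname(quantile(ctx$gray[ctx$mask], 0.9)),
  gray_mad = function(ctx) mad(ctx$gray[ctx$mask]),
  # color
  color_mean_r = function(ctx) mean(ctx$crop[, , 1][ctx$mask]),
  color_mean_g = function(ctx) mean(ctx$crop[, , 2][ctx$mask]),
  color_mean_b = function(ctx) mean(ctx$crop[, , 3][ctx$mask]),
  color_rb_ratio = function(ctx) {
    r <- mean(ctx$crop[, , 1][ctx$mask]); b <- mean(ctx$crop[, , 3][ctx$mask])
    (r - b) / max(r + b, .Machine$double.eps)
  },
  color_saturation = function(ctx) {
    r <- ctx$crop[, , 1][ctx$mask]; g <- ctx$crop[, , 2][ctx$mask]
    b <- ctx$crop[, , 3][ctx$mask]
    mx <- pmax(r, g, b)
    mean(ifelse(mx > 0, (mx - pmin(r, g, b)) / mx, 0))
  },
  # co-occurrence texture
  glcm_contrast = function(ctx) {
    M <- ctx$glcm(); L <- nrow(M)
    ii <- matrix(seq_len(L), L, L); jj <- t(ii)
    sum((ii - jj)^2 * M)
  },
  glcm_homogeneity = function(ctx) {
    M <- ctx$glcm(); L <- nrow(M)
    ii <- matrix(seq_len(L), L, L); jj <- t(ii)
    sum(M / (1 + abs(ii - jj)))
  },
  glcm_correlation = function(ctx) {
    M <- ctx$glcm(); L <- nrow(M)
    i <- seq_len(L)
    pi_ <- rowSums(M); pj <- colSums(M)
    mi <- sum(i * pi_); mj <- sum(i * pj)
    si <- sqrt(sum((i - mi)^2 * pi_)); sj <- sqrt(sum((i - mj)^2 * pj))
    if (si == 0 || sj == 0) return(0)
    ii <- matrix(i, L, L); jj <- t(ii)
    sum((ii - mi) * (jj - mj) * M) / (si * sj)
  },
  # Gabor / frequency-domain texture
  gabor_variance_lowfreq = function(ctx)
    feat_gabor_variance(ctx$gray, ctx$mask, u = 0.05),
  gabor_variance_highfreq = function(ctx)
    feat_gabor_variance(ctx$gray, ctx$mask, u = 0.2),
  gradient_energy = function(ctx) {
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    gx <- as_mat(EBImage::filter2(ctx$gray, kx, boundary = "replicate"))
    gy <- as_mat(EBImage::filter2(ctx$gray, t(kx), boundary = "replicate"))
    mean((gx^2 + gy^2)[ctx$mask])
  },
  # topology (non-canonical stand-ins; see vignette)
  euler_number = function(ctx) .euler_number(ctx$mask),
  extrema_density = function(ctx) .extrema_density(ctx$gray, ctx$mask)
)

#' Feature registry
#'
#' `"core"` is the headline seven-feature set; `"full"` adds the
#' documented standard descriptors per category (shape, histogram, color,
#' co-occurrence and Gabor texture, topology stand-ins).
#'
#' @param which `"full"` or `"core"`, or a character vector of feature
#'   names to validate and pass through.
#' @return Character vector of feature names.
#' @export
feature_registry <- function(which = c("full", "core")) {
  if (length(which) > 1 || !which[1] %in% c("full", "core")) {
    missing <- setdiff(which, names(.feature_funs))
    if (length(missing))
      stopf("unknown features: %s", paste(missing, collapse = ", "))
    return(which)
  }
  switch(match.arg(which),
         core = core_features,
         full = names(.feature_funs))
}

.make_ctx <- function(obj) {
  mask <- obj$mask
  crop <- obj$crop
  gray <- if (!is.null(obj$gray_crop)) obj$gray_crop else to_grayscale(crop)
  glcm_cache <- NULL
  ctx <- new.env(parent = emptyenv())
  ctx$mask <- mask; ctx$crop <- crop; ctx$gray <- gray
  ctx$glcm <- function() {
    if (is.null(glcm_cache)) glcm_cache <<- glcm_matrix(gray, mask)
    glcm_cache
  }
  ctx
}

#' Compute the registered features of one object
#'
#' @param obj an object record (from [extract_objects()] or
#'   [render_cell()]): needs `mask`, and `crop` and/or `gray_crop`.
#' @param registry feature names, see [feature_registry()].
#' @return Named numeric vector; features whose computation failed are `NA`
#'   with the messages in `attr(, "failures")`.
#' @export
compute_features <- function(obj, registry = feature_registry("full")) {
  registry <- feature_registry(registry)
  ctx <- .make_ctx(obj)
  failures <- character()
  vals <- vapply(registry, function(nm) {
    tryCatch(as.numeric(.feature_funs[[nm]](ctx)),
             error = function(e) {
               failures[[nm]] <<- conditionMessage(e)
               NA_real_
             })
  }, numeric(1))
  if (length(failures)) attr(vals, "failures") <- failures
  vals
}

#' Compute a feature table for a list of objects
#'
#' Objects for which any requested feature fails are dropped with a warning
#' (the spec of each feature states its preconditions); labels are taken
#' from the objects' `label` fields when present.
#'
#' @param objects list of object records.
#' @param registry feature names, see [feature_registry()].
#' @param labels optional labels overriding the objects' own.
#' @return A [feature_table()].
#' @export
compute_feature_table <- function(objects, registry = feature_registry("full"),
                                  labels = NULL) {
  registry <- feature_registry(registry)
  rows <- lapply(objects, compute_features, registry = registry)
  x <- do.call(rbind, rows)
  if (is.null(labels)) {
    labels <- vapply(objects, function(o)
      if (!is.null(o$label) && !is.na(o$label)) as.character(o$label)
      else NA_character_, character(1))
    if (all(is.na(labels))) labels <- NULL
  }
  ids <- vapply(seq_along(objects), function(i) {
    oid <- objects[[i]]$object_id
    if (is.null(oid)) i else as.integer(oid)
  }, integer(1))
  keep <- rowSums(is.na(x)) == 0
  if (!all(keep))
    warning(sprintf("%d object(s) dropped: feature computation failed",
                    sum(!keep)))
  feature_table(x[keep, , drop = FALSE],
                labels = if (!is.null(labels)) labels[keep],
                object_ids = ids[keep])
}
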