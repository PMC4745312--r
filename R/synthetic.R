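#' Scene specification for the synthetic smear generator
#'
#' Describes a synthetic slide scene: stained, roughly elliptical buccal
#' cells sitting darker than a bright transmission background, three
#' unsuitable-object phenotypes (debris-covered, folded, overlapping), a
#' smooth multiplicative illumination gradient across the scene, and mild
#' sensor noise. Tile size defaults to 1024 x 1280 pixels, the native frame
#' of a low-magnification slide-mapping camera.
#'
#' @param tile_shape integer (height, width) of one tile in pixels.
#' @param tile_grid integer (rows, cols) of the tile grid.
#' @param n_suitable,n_unsuitable object counts.
#' @param unsuitable_mix named proportions over
#'   `c("debris", "folded", "overlapping")`; must sum to 1.
#' @param cell_radius_range (min, max) nominal cell radius in pixels.
#' @param illumination_gradient_amplitude peak-to-trough gradient as a
#'   fraction of the background level, in `[0, 1)`.
#' @param texture_noise_sd_suitable,texture_noise_sd_unsuitable standard
#'   deviation (gray levels) of the smooth intra-cell texture field.
#' @param stain_color RGB triple (0-255) of the mean stain color.
#' @param background_level blank-background gray level (0-255).
#' @param sensor_noise_sd additive pixel noise sd in gray levels.
#' @param seed integer RNG seed; equal seeds give byte-identical scenes.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(tile_shape = c(1024L, 1280L),
                       tile_grid = c(2L, 2L),
                       n_suitable = 10L,
                       n_unsuitable = 10L,
                       unsuitable_mix = c(debris = 1/3, folded = 1/3,
                                          overlapping = 1/3),
                       cell_radius_range = c(30, 60),
                       illumination_gradient_amplitude = 0.3,
                       texture_noise_sd_suitable = 3,
                       texture_noise_sd_unsuitable = 15,
                       stain_color = c(150, 110, 160),
                       background_level = 220,
                       sensor_noise_sd = 1,
                       seed = 1L) {
  mix <- unsuitable_mix[c("debris", "folded", "overlapping")]
  if (anyNA(mix) || abs(sum(mix) - 1) > 1e-8 || any(mix < 0))
    stopf("unsuitable_mix must be nonnegative proportions over debris/folded/overlapping summing to 1")
  if (n_suitable < 0 || n_unsuitable < 0) stopf("object counts must be >= 0")
  if (any(cell_radius_range <= 0) || diff(cell_radius_range) < 0)
    stopf("cell_radius_range must be positive and increasing")
  if (illumination_gradient_amplitude < 0 || illumination_gradient_amplitude >= 1)
    stopf("illumination_gradient_amplitude must be in [0, 1)")
  structure(list(tile_shape = as.integer(tile_shape),
                 tile_grid = as.integer(tile_grid),
                 n_suitable = as.integer(n_suitable),
                 n_unsuitable = as.integer(n_unsuitable),
                 unsuitable_mix = mix,
                 cell_radius_range = cell_radius_range,
                 illumination_gradient_amplitude = illumination_gradient_amplitude,
                 texture_noise_sd_suitable = texture_noise_sd_suitable,
                 texture_noise_sd_unsuitable = texture_noise_sd_unsuitable,
                 stain_color = stain_color,
                 background_level = background_level,
                 sensor_noise_sd = sensor_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

cell_phenotypes <- c("suitable", "debris", "folded", "overlapping")

# canvas half-width per phenotype, as a multiple of the nominal radius
.canvas_factor <- c(suitable = 1.35, debris = 1.35, folded = 1.65,
                    overlapping = 2.1)

# smooth zero-mean texture field with sd `texture_sd`
.texture_field <- function(h, w, texture_sd, blur_sigma = 2.5) {
  if (texture_sd <= 0) return(matrix(0, h, w))
  t <- gauss_blur(matrix(rnorm(h * w), h, w), blur_sigma)
  t / sd(t) * texture_sd
}

.ellipse_mask <- function(h, w, cy, cx, a, b, phi) {
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  xr <- xx * cos(phi) + yy * sin(phi)
  yr <- -xx * sin(phi) + yy * cos(phi)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Render a single synthetic cell
#'
#' Draws one object of the requested phenotype onto a clean background-level
#' canvas. Suitable cells are near-circular, convex and smooth-textured;
#' folded cells are elongated with a dark crease band and an edge concavity;
#' debris-covered cells carry high-contrast speckle blobs; overlapping cells
#' are two intersecting ellipses forming one connected mask with a darker
#' intersection (double stain uptake).
#'
#' @param phenotype one of `"suitable"`, `"debris"`, `"folded"`,
#'   `"overlapping"`.
#' @param radius nominal radius in pixels (geometric mean of semi-axes);
#'   must be at least 5 so texture can be rendered.
#' @param texture_sd sd of the intra-cell texture field, gray levels.
#' @param stain_color,background_level see [scene_spec()].
#' @param seed optional integer; if given the render is reproducible and the
#'   global RNG state is untouched.
#' @return list with `crop` (h x w x 3 array, 0-255), `mask` (logical
#'   matrix), `phenotype`, `radius`.
#' @export
render_cell <- function(phenotype, radius, texture_sd,
                        stain_color = c(150, 110, 160),
                        background_level = 220, seed = NULL) {
  phenotype <- match.arg(phenotype, cell_phenotypes)
  if (radius < 5) stopf("radius %.1f too small to render texture (min 5 px)", radius)
  if (!is.null(seed))
    return(with_seed(seed, render_cell(phenotype, radius, texture_sd,
                                       stain_color, background_level)))
  half <- ceiling(radius * .canvas_factor[[phenotype]]) + 2L
  s <- 2L * half + 1L
  cy <- cx <- half + 1
  phi <- runif(1, 0, pi)
  shade <- matrix(0, s, s)  # gray-level modulation added inside the mask

  if (phenotype %in% c("suitable", "debris")) {
    q <- runif(1, 1.0, 1.25)
    mask <- .ellipse_mask(s, s, cy, cx, radius * sqrt(q), radius / sqrt(q), phi)
  } else if (phenotype == "folded") {
    q <- runif(1, 1.6, 2.2)
    a <- radius * sqrt(q); b <- radius / sqrt(q)
    mask <- .ellipse_mask(s, s, cy, cx, a, b, phi)
    # edge concavity where the cell folds over
    psi <- phi + sample(c(-1, 1), 1) * runif(1, 0.2, 0.6)
    bite <- .ellipse_mask(s, s, cy + 0.95 * a * sin(psi), cx + 0.95 * a * cos(psi),
                          0.45 * radius, 0.45 * radius, 0)
    mask <- mask & !bite
    # dark crease band along the fold line
    yy <- matrix(seq_len(s) - cy, s, s)
    xx <- matrix(seq_len(s) - cx, s, s, byrow = TRUE)
    off <- runif(1, -0.3, 0.3) * b
    dist_band <- abs(-xx * sin(phi) + yy * cos(phi) - off)
    shade <- shade - 45 * (dist_band < radius / 5)
  } else { # overlapping
    d <- 0.75 * radius
    q1 <- runif(1, 1.0, 1.2); q2 <- runif(1, 1.0, 1.2)
    r2 <- radius * runif(1, 0.85, 1.1)
    m1 <- .ellipse_mask(s, s, cy - d * sin(phi), cx - d * cos(phi),
                        radius * sqrt(q1), radius / sqrt(q1), phi + runif(1, -0.4, 0.4))
    m2 <- .ellipse_mask(s, s, cy + d * sin(phi), cx + d * cos(phi),
                        r2 * sqrt(q2), r2 / sqrt(q2), phi + runif(1, -0.4, 0.4))
    mask <- m1 | m2
    shade <- shade - 35 * (m1 & m2)
  }

  if (phenotype == "debris") {
    n_speck <- 5L + stats::rpois(1, 8)
    for (i in seq_len(n_speck)) {
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.8 * radius)
      sp <- .ellipse_mask(s, s, cy + rad * sin(ang), cx + rad * cos(ang),
                          runif(1, 1.5, 4), runif(1, 1.5, 4), 0)
      shade <- shade + sample(c(-1, 1), 1) * runif(1, 40, 80) * sp
    }
  }

  if (phenotype == "suitable") {
    # faint nucleus: slight central darkening
    yy <- matrix(seq_len(s) - cy, s, s)
    xx <- matrix(seq_len(s) - cx, s, s, byrow = TRUE)
    shade <- shade - 10 * exp(-(xx^2 + yy^2) / (0.45 * radius)^2)
  }

  tex <- .texture_field(s, s, texture_sd)
  crop <- array(background_level, c(s, s, 3))
  for (ch in 1:3) {
    plane <- crop[, , ch]
    plane[mask] <- stain_color[ch] + tex[mask] + shade[mask]
    crop[, , ch] <- plane
  }
  crop <- clamp(crop, 0, 255)
  list(crop = crop, mask = mask, phenotype = phenotype, radius = radius)
}

# split n into integer counts proportional to mix (largest remainder)
.apportion <- function(n, mix) {
  raw <- n * mix / sum(mix)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

# smooth multiplicative gradient field in [1 - amp, 1]
.gradient_field <- function(h, w, amp) {
  if (amp == 0) return(matrix(1, h, w))
  u <- matrix(seq_len(w) / w - 0.5, h, w, byrow = TRUE)
  v <- matrix(seq_len(h) / h - 0.5, h, w)
  cf <- runif(5, -1, 1)
  q <- cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * u^2 + cf[5] * v^2
  q <- (q - min(q)) / max(max(q) - min(q), .Machine$double.eps)
  1 - amp * q
}

#' Generate a complete synthetic slide scene
#'
#' Places the requested cells on a bright background without any overlap
#' between distinct objects (the overlapping phenotype is internally a
#' two-lobed single object), applies a smooth multiplicative illumination
#' gradient and additive sensor noise, and splits the scene into tiles.
#' Placement uses rejection sampling on bounding circles with a cap of 1000
#' attempts per object.
#'
#' @param spec a [scene_spec()].
#' @return list with `tiles` (row-major list of h x w x 3 arrays),
#'   `background` (blank gradient-only scene raster), `scene` (full raster),
#'   `truth` (list of objects: `object_id`, `label`, `phenotype`, `bbox`
#'   top-left `(row, col)`, local `mask`), and `spec`.
#' @export
generate_slide_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    th <- spec$tile_shape[1]; tw <- spec$tile_shape[2]
    H <- spec$tile_grid[1] * th; W <- spec$tile_grid[2] * tw

    counts <- .apportion(spec$n_unsuitable, spec$unsuitable_mix)
    phenos <- c(rep("suitable", spec$n_suitable),
                rep(names(counts), counts))
    n <- length(phenos)
    radii <- runif(n, spec$cell_radius_range[1], spec$cell_radius_range[2])
    obj_seeds <- if (n) sample.int(.Machine$integer.max - 1L, n) else integer()

    g <- .gradient_field(H, W, spec$illumination_gradient_amplitude)
    background <- array(spec$background_level * c(g), c(H, W, 3))

    # rejection-sample non-overlapping centres (bounding-circle test);
    # br matches the render canvas half-width so bboxes stay in bounds
    br <- ceiling(radii * .canvas_factor[phenos]) + 3
    cy <- cx <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (attempt in seq_len(1000)) {
        y <- runif(1, br[i] + 1, H - br[i])
        x <- runif(1, br[i] + 1, W - br[i])
        if (i == 1 || all((cy[seq_len(i - 1)] - y)^2 + (cx[seq_len(i - 1)] - x)^2 >
                          (br[seq_len(i - 1)] + br[i] + 4)^2)) {
          cy[i] <- y; cx[i] <- x; ok <- TRUE; break
        }
      }
      if (!ok)
        stopf(paste("placement failed after 1000 attempts for object %d:",
                    "scene density exceeds the non-overlap limit;",
                    "enlarge the scene or reduce counts/radii"), i)
    }

    scene <- array(spec$background_level, c(H, W, 3))
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      tsd <- if (phenos[i] == "suitable") spec$texture_noise_sd_suitable
             else spec$texture_noise_sd_unsuitable
      cell <- render_cell(phenos[i], radii[i], tsd, spec$stain_color,
                          spec$background_level, seed = obj_seeds[i])
      s <- nrow(cell$mask)
      r0 <- round(cy[i]) - (s - 1L) %/% 2L
      c0 <- round(cx[i]) - (s - 1L) %/% 2L
      rows <- r0:(r0 + s - 1L); cols <- c0:(c0 + s - 1L)
      for (ch in 1:3) {
        plane <- scene[rows, cols, ch]
        plane[cell$mask] <- cell$crop[, , ch][cell$mask]
        scene[rows, cols, ch] <- plane
      }
      truth[[i]] <- list(object_id = i,
                         label = if (phenos[i] == "suitable") "suitable" else "unsuitable",
                         phenotype = phenos[i],
                         bbox = c(row = r0, col = c0),
                         mask = cell$mask)
    }

    scene <- scene * c(g)
    if (spec$sensor_noise_sd > 0)
      scene <- scene + rnorm(length(scene), 0, spec$sensor_noise_sd)
    scene <- clamp(scene, 0, 255)

    tiles <- vector("list", spec$tile_grid[1] * spec$tile_grid[2])
    k <- 1L
    for (i in seq_len(spec$tile_grid[1]))
      for (j in seq_len(spec$tile_grid[2])) {
        tiles[[k]] <- scene[((i - 1) * th + 1):(i * th),
                            ((j - 1) * tw + 1):(j * tw), , drop = FALSE]
        k <- k + 1L
      }

    list(tiles = tiles, background = background, scene = scene,
         truth = truth, spec = spec)
  })
}

#' Generate a planted-signal feature dataset
#'
#' Two balanced classes; informative features are shifted between classes by
#' `separation` standard deviations, noise features are identically
#' distributed in both. Column names flag the planted features
#' (`inf_*` vs `noise_*`). Used to exercise the feature-selection and
#' classification stages with a known answer.
#'
#' @param n_per_class samples per class.
#' @param n_informative,n_noise feature counts.
#' @param separation standardized mean difference of informative features.
#' @param seed integer seed.
#' @return A [feature_table()] with labels; `suitable` is the shifted class.
#' @export
generate_feature_dataset <- function(n_per_class, n_informative, n_noise,
                                     separation, seed = 1L) {
  if (n_per_class < 1 || n_informative < 0 || n_noise < 0 ||
      n_informative + n_noise < 1)
    stopf("counts must be positive")
  if (separation < 0) stopf("separation must be >= 0")
  with_seed(seed, {
    p <- n_informative + n_noise
    x1 <- matrix(rnorm(n_per_class * p), n_per_class, p)
    x2 <- matrix(rnorm(n_per_class * p), n_per_class, p)
    if (n_informative > 0)
      x1[, seq_len(n_informative)] <- x1[, seq_len(n_informative)] + separation
    x <- rbind(x1, x2)
    colnames(x) <- c(if (n_informative) sprintf("inf_%02d", seq_len(n_informative)),
                     if (n_noise) sprintf("noise_%02d", seq_len(n_noise)))
    feature_table(x,
                  labels = rep(c("suitable", "unsuitable"), each = n_per_class),
                  provenance = sprintf("planted(sep=%g,seed=%d)", separation, seed))
  })
}
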