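#' Slide-map container
#'
#' A slide-map is the full image of a smear slide assembled from a raster
#' scan of low-magnification tiles. Stored as an `h x w x 3` numeric array
#' on the 0-255 scale with its tile-grid metadata; coordinates are 0-based
#' `(row, col)` from the top-left in all serialized records, 1-based inside
#' R as usual.
#'
#' @param pixels `h x w x 3` numeric array.
#' @param tile_grid integer `(rows, cols)`.
#' @param tile_shape integer `(h, w)` of one tile.
#' @return An object of class `slide_map`.
#' @export
slide_map <- function(pixels, tile_grid, tile_shape) {
  if (!is_rgb(pixels)) stopf("pixels must be an h x w x 3 array")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stopf("pixel values must be finite and non-negative")
  tile_grid <- as.integer(tile_grid); tile_shape <- as.integer(tile_shape)
  if (!identical(dim(pixels)[1:2],
                 c(tile_grid[1] * tile_shape[1], tile_grid[2] * tile_shape[2])))
    stopf("raster dimensions (%d x %d) != tile_grid * tile_shape",
          dim(pixels)[1], dim(pixels)[2])
  structure(list(pixels = pixels, tile_grid = tile_grid,
                 tile_shape = tile_shape), class = "slide_map")
}

#' @export
print.slide_map <- function(x, ...) {
  cat(sprintf("<slide_map> %d x %d px (%d x %d tiles of %d x %d)\n",
              dim(x$pixels)[1], dim(x$pixels)[2],
              x$tile_grid[1], x$tile_grid[2],
              x$tile_shape[1], x$tile_shape[2]))
  invisible(x)
}

#' Stitch tiles into a slide-map
#'
#' Tiles are placed on the grid in row-major order without blending: pixel
#' `(r, c)` of tile `(i, j)` lands at `(i*h + r, j*w + c)` (0-based).
#'
#' @param tiles list of equal-shaped `h x w x 3` arrays, row-major.
#' @param grid integer `(rows, cols)`; `length(tiles)` must equal the product.
#' @return A [slide_map()].
#' @export
stitch_tiles <- function(tiles, grid) {
  grid <- as.integer(grid)
  if (length(tiles) != prod(grid))
    stopf("expected %d tiles for a %dx%d grid, got %d",
          prod(grid), grid[1], grid[2], length(tiles))
  shapes <- vapply(tiles, function(t) dim(t)[1:2], integer(2))
  if (any(shapes != shapes[, 1]))
    stopf("all tiles must have the same shape")
  th <- shapes[1, 1]; tw <- shapes[2, 1]
  out <- array(0, c(grid[1] * th, grid[2] * tw, 3))
  k <- 1L
  for (i in seq_len(grid[1]))
    for (j in seq_len(grid[2])) {
      out[((i - 1) * th + 1):(i * th), ((j - 1) * tw + 1):(j * tw), ] <- tiles[[k]]
      k <- k + 1L
    }
  slide_map(out, grid, c(th, tw))
}

#' Split a slide-map back into its tiles
#'
#' Exact inverse of [stitch_tiles()].
#'
#' @param map a [slide_map()].
#' @return Row-major list of tile arrays.
#' @export
split_tiles <- function(map) {
  stopifnot(inherits(map, "slide_map"))
  th <- map$tile_shape[1]; tw <- map$tile_shape[2]
  tiles <- vector("list", prod(map$tile_grid))
  k <- 1L
  for (i in seq_len(map$tile_grid[1]))
    for (j in seq_len(map$tile_grid[2])) {
      tiles[[k]] <- map$pixels[((i - 1) * th + 1):(i * th),
                               ((j - 1) * tw + 1):(j * tw), , drop = FALSE]
      k <- k + 1L
    }
  tiles
}

#' Flat-field illumination correction
#'
#' Divides the slide-map channel-wise by a blank background image (the
#' multiplicative shading model of transmission imaging) and rescales so the
#' corrected background sits at a constant `target_level`. A background
#' supplied as a single tile is replicated across the grid. Background
#' pixels at or below an epsilon of the dynamic range are clamped, with a
#' warning.
#'
#' @param map a [slide_map()].
#' @param background `h x w x 3` array matching the map or one tile.
#' @param target_level corrected background gray level; defaults to the mean
#'   background level.
#' @return A corrected [slide_map()].
#' @export
correct_illumination <- function(map, background, target_level = NULL) {
  stopifnot(inherits(map, "slide_map"))
  if (!is_rgb(background)) stopf("background must be an h x w x 3 array")
  dmap <- dim(map$pixels)
  if (identical(dim(background)[1:2], map$tile_shape)) {
    background <- stitch_tiles(rep(list(background), prod(map$tile_grid)),
                               map$tile_grid)$pixels
  }
  if (!identical(dim(background), dmap))
    stopf("background shape (%s) matches neither the map nor one tile",
          paste(dim(background), collapse = "x"))
  eps <- 255 / 65535
  n_clamped <- sum(background <= eps)
  if (n_clamped > 0) {
    warning(sprintf("%d background pixels <= epsilon clamped", n_clamped))
    background <- pmax(background, eps)
  }
  if (is.null(target_level)) target_level <- mean(background)
  out <- map$pixels / background * target_level
  slide_map(out, map$tile_grid, map$tile_shape)
}

#' Convert an RGB image to grayscale
#'
#' Unweighted arithmetic mean of the three channels.
#'
#' @param image `h x w x 3` array or a [slide_map()].
#' @return Numeric matrix of the same spatial shape.
#' @export
to_grayscale <- function(image) {
  if (inherits(image, "slide_map")) image <- image$pixels
  if (!is_rgb(image)) stopf("expected a 3-channel image")
  g <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  if (!is.matrix(g)) g <- matrix(g, dim(image)[1], dim(image)[2])
  g
}

#' Read / write images (PNG, TIFF)
#'
#' Values are exchanged on the 0-255 scale regardless of on-disk bit depth.
#' TIFF is written at 16 bits per sample so the round-trip is lossless to
#' better than 0.004 gray levels; PNG is 8-bit.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param image matrix (gray) or `h x w x 3` array, values in `[0, 255]`.
#' @return `read_image` returns a matrix or array on the 0-255 scale.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stopf("unsupported image extension '%s'", ext))
  raw * 255
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  if (inherits(image, "slide_map")) image <- image$pixels
  ext <- tolower(tools::file_ext(path))
  scaled <- clamp(image / 255, 0, 1)
  switch(ext,
         png = png::writePNG(scaled, path),
         tif = ,
         tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 16L),
         stopf("unsupported image extension '%s'", ext))
  invisible(path)
}

#' Selection records: object boundaries plus suitability labels
#'
#' The interchange format for manually or automatically selected objects: a
#' JSON array of records, each with `object_id`, a closed polygon `boundary`
#' of 0-based `(row, col)` pixel coordinates (at least 3 vertices), and a
#' `label` among `suitable`, `unsuitable`, `unlabeled`.
#'
#' @param records list of records; each a list with fields `object_id`,
#'   `boundary` (n x 2 matrix), `label`.
#' @param path JSON file path.
#' @return `read_selection_records` returns the validated list of records.
#' @export
write_selection_records <- function(records, path) {
  lapply(records, .validate_selection_record)
  out <- lapply(records, function(r)
    list(object_id = r$object_id,
         label = r$label,
         boundary = unname(apply(r$boundary, 1, as.numeric, simplify = FALSE))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection_records
#' @export
read_selection_records <- function(path) {
  parsed <- tryCatch(jsonlite::read_json(path),
                     error = function(e) stopf("malformed JSON: %s", conditionMessage(e)))
  records <- lapply(parsed, function(r) {
    for (f in c("object_id", "label", "boundary"))
      if (is.null(r[[f]])) stopf("selection record missing field '%s'", f)
    b <- do.call(rbind, lapply(r$boundary, unlist))
    rec <- list(object_id = r$object_id, boundary = b, label = r$label)
    .validate_selection_record(rec)
    rec
  })
  records
}

.validate_selection_record <- function(r) {
  if (is.null(r$object_id)) stopf("selection record missing field 'object_id'")
  if (!r$label %in% c("suitable", "unsuitable", "unlabeled"))
    stopf("invalid label '%s' in record %s", r$label, r$object_id)
  if (!is.matrix(r$boundary) || ncol(r$boundary) != 2 || nrow(r$boundary) < 3)
    stopf("boundary of record %s must be an n x 2 matrix with n >= 3", r$object_id)
  invisible(r)
}
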