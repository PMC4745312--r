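# Shared, lazily computed fixtures so expensive runs happen once per session.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# The default full-scale benchmark (1000 train / 360 test objects).
bench_default <- function() cached("bench_default",
  run_benchmark(seed = 20260919, B = 1000))

# A small rendered object set reused by feature/ordering tests.
matched_pairs <- function() cached("matched_pairs", {
  lapply(1:6, function(s) {
    list(suitable = render_cell("suitable", 40, 3, seed = s),
         folded = render_cell("folded", 40, 15, seed = s),
         debris = render_cell("debris", 40, 15, seed = s),
         overlapping = render_cell("overlapping", 40, 15, seed = s))
  })
})

# Small segmentation scene shared between segmentation tests.
small_scene <- function() cached("small_scene", {
  spec <- scene_spec(tile_shape = c(256L, 320L), tile_grid = c(1L, 2L),
                     n_suitable = 3L, n_unsuitable = 3L,
                     cell_radius_range = c(18, 26), seed = 11L)
  sc <- generate_slide_scene(spec)
  sc$map <- stitch_tiles(sc$tiles, spec$tile_grid)
  sc
})
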