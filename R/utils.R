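#' @useDynLib cellcull, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var quantile median cor.test predict mad
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# strip EBImage's Image class if present
as_mat <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (is.matrix(x)) x else unclass(x)
}

# Gaussian blur by separable filter2 convolution, replicate boundary.
gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k <- outer(k1, k1)
  as_mat(EBImage::filter2(m, k, boundary = "replicate"))
}

is_rgb <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

stopf <- function(...) stop(sprintf(...), call. = FALSE)
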