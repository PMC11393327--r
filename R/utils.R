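# Shared small helpers.
#
# Coordinate convention (used package-wide): images are arrays (H, W, C) or
# matrices (H, W), 0-based (row, col) pixel coordinates with origin top-left.
# Displacement fields are (H, W, 2) arrays with slice 1 = dx (column offset)
# and slice 2 = dy (row offset), both in pixels, mapping moving -> fixed:
# warped(h, w) = moving(h + dy, w + dx).

`%||%` <- function(a, b) if (is.null(a)) b else a

as_image3 <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

stop_shape <- function(a, b, what = "images") {
  if (!identical(dim(as_image3(a))[1:2], dim(as_image3(b))[1:2])) {
    stop(sprintf("%s must share height/width: %s vs %s", what,
                 paste(dim(as_image3(a))[1:2], collapse = "x"),
                 paste(dim(as_image3(b))[1:2], collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' @useDynLib virtpol, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Separable Gaussian blur of a matrix with replicate-equivalent
# normalization (blur of ones used as denominator near the border).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad <- r
  x <- array(m, dim = c(dim(m), 1L))
  ones <- array(1, dim = dim(x))
  # zero-pad then convolve along one axis at a time
  blur1d <- function(a, along) {
    d <- dim(a)
    if (along == 1L) {
      ap <- array(0, dim = c(d[1] + 2L * pad, d[2], 1L))
      ap[(pad + 1L):(pad + d[1]), , 1L] <- a[, , 1L]
      wk <- array(k, dim = c(2L * r + 1L, 1L, 1L, 1L))
    } else {
      ap <- array(0, dim = c(d[1], d[2] + 2L * pad, 1L))
      ap[, (pad + 1L):(pad + d[2]), 1L] <- a[, , 1L]
      wk <- array(k, dim = c(1L, 2L * r + 1L, 1L, 1L))
    }
    .cpp_conv2d_fw(ap, wk, 0, 1L, 0L)
  }
  num <- blur1d(blur1d(x, 1L), 2L)
  den <- blur1d(blur1d(ones, 1L), 2L)
  matrix(num[, , 1L] / den[, , 1L], nrow = nrow(m))
}

# Counter-based seed splitting: derive independent substream seeds from a
# master seed without consuming the global RNG state ordering.
split_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
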