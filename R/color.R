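# Color-space conversions (vectorized over whole images).
#
# RGB values are floats in [0, 1].  Hue is kept on the [0, 1) scale
# throughout (multiply by 360 for degrees).  YCbCr uses full-range ITU-R
# BT.601 with Cb/Cr offset to 0.5.

#' RGB to HSV
#' @param img (H, W, 3) array in `[0, 1]`.
#' @return (H, W, 3) array with slices hue, saturation, value (all `[0, 1]`).
#' @export
rgb_to_hsv <- function(img) {
  img <- as_image3(img)
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  h <- grDevices::rgb2hsv(m, maxColorValue = 1)
  array(c(h[1, ], h[2, ], h[3, ]), dim = d)
}

#' HSV to RGB
#' @param hsv (H, W, 3) array with slices hue, saturation, value.
#' @return (H, W, 3) RGB array.
#' @export
hsv_to_rgb <- function(hsv) {
  hsv <- as_image3(hsv)
  d <- dim(hsv)
  h <- as.vector(hsv[, , 1]) %% 1
  s <- as.vector(hsv[, , 2])
  v <- as.vector(hsv[, , 3])
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), dim = d)
}

#' RGB to YCbCr (full-range BT.601)
#' @param img (H, W, 3) RGB array in `[0, 1]`.
#' @return (H, W, 3) array with slices Y, Cb, Cr (Cb/Cr centred at 0.5).
#' @export
rgb_to_ycbcr <- function(img) {
  img <- as_image3(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- (b - y) / 1.772 + 0.5
  cr <- (r - y) / 1.402 + 0.5
  array(c(y, cb, cr), dim = dim(img))
}

#' YCbCr to RGB (full-range BT.601)
#' @param ycc (H, W, 3) array with slices Y, Cb, Cr.
#' @return (H, W, 3) RGB array (not clipped).
#' @export
ycbcr_to_rgb <- function(ycc) {
  ycc <- as_image3(ycc)
  y <- ycc[, , 1]; cb <- ycc[, , 2] - 0.5; cr <- ycc[, , 3] - 0.5
  r <- y + 1.402 * cr
  b <- y + 1.772 * cb
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  array(c(r, g, b), dim = dim(ycc))
}

# circular mean of hue values on [0, 1); returns NA for empty input
circular_mean_hue <- function(h) {
  if (length(h) == 0) return(NA_real_)
  a <- 2 * pi * h
  (atan2(mean(sin(a)), mean(cos(a))) / (2 * pi)) %% 1
}

# absolute circular distance between two hues on [0, 1), in degrees
hue_distance_deg <- function(h1, h2) {
  d <- abs(h1 - h2) %% 1
  360 * pmin(d, 1 - d)
}
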