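# Brute-force loop oracles for the loss and metric definitions.  These are
# deliberately naive (double loops, no vectorization) and independent of the
# package implementations they check.

oracle_mae <- function(A, B) {
  s <- 0
  for (i in seq_along(A)) s <- s + abs(A[i] - B[i])
  s / length(A)
}

oracle_mse <- function(A, B) {
  s <- 0
  for (i in seq_along(A)) s <- s + (A[i] - B[i])^2
  s / length(A)
}

oracle_psnr <- function(A, B) {
  10 * log10(max(A)^2 / oracle_mse(A, B))
}

oracle_smooth_l1 <- function(A, B, phi = 1) {
  s <- 0
  for (i in seq_along(A)) {
    d <- A[i] - B[i]
    s <- s + if (abs(d) < phi) 0.5 * d^2 / phi else abs(d) - 0.5 * phi
  }
  s / length(A)
}

oracle_bce <- function(p, label, eps = 1e-7) {
  p <- min(max(p, eps), 1 - eps)
  -(label * log(p) + (1 - label) * log(1 - p))
}

oracle_tv <- function(I) {
  I <- if (is.matrix(I)) array(I, dim = c(dim(I), 1)) else I
  d <- dim(I)
  s <- 0
  for (c in seq_len(d[3])) {
    for (p in seq_len(d[1] - 1)) {
      for (q in seq_len(d[2])) s <- s + abs(I[p + 1, q, c] - I[p, q, c])
    }
    for (p in seq_len(d[1])) {
      for (q in seq_len(d[2] - 1)) s <- s + abs(I[p, q + 1, c] - I[p, q, c])
    }
  }
  s
}

oracle_smoothness <- function(f) {
  d <- dim(f)
  s <- 0
  for (c in 1:2) {
    for (x in seq_len(d[1] - 1)) {
      for (y in seq_len(d[2])) s <- s + (f[x + 1, y, c] - f[x, y, c])^2
    }
    for (x in seq_len(d[1])) {
      for (y in seq_len(d[2] - 1)) s <- s + (f[x, y + 1, c] - f[x, y, c])^2
    }
  }
  s / (d[1] * d[2])
}

oracle_d_iou <- function(A, B, factor = 4, tau = 1 / factor^2) {
  # naive block-average downsample + binarize + IoU
  ds <- function(m) {
    H <- ceiling(nrow(m) / factor)
    W <- ceiling(ncol(m) / factor)
    out <- matrix(0, H, W)
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        s <- 0
        for (di in seq_len(factor)) {
          for (dj in seq_len(factor)) {
            r <- (i - 1) * factor + di
            c <- (j - 1) * factor + dj
            if (r <= nrow(m) && c <= ncol(m) && m[r, c]) s <- s + 1
          }
        }
        out[i, j] <- s / factor^2
      }
    }
    out >= tau
  }
  a <- ds(A); b <- ds(B)
  num <- sum(a & b)
  den <- sum(a | b)
  if (den == 0) 1 else num / den
}

rand_img <- function(h = 8, w = 8, c = 1) {
  if (c == 1) matrix(stats::runif(h * w), h, w)
  else array(stats::runif(h * w * c), dim = c(h, w, c))
}
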