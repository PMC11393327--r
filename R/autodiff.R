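# Minimal reverse-mode automatic differentiation over (H, W, C) tensors.
#
# A tape records nodes in creation order; backward() walks the tape in
# reverse, each node scattering its gradient into its parents.  Nodes are
# environments so gradient accumulation mutates in place.  This engine only
# implements the operations the three networks and their losses need; every
# op has a finite-difference test.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

nd_node <- function(tape, value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- n
  n
}

nd_const <- function(tape, value) nd_node(tape, value)

nd_accum <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n)
  }
  invisible(NULL)
}

# --- elementwise ------------------------------------------------------------

nd_leaky_relu <- function(tape, x, slope = 0.1) {
  pos <- x$value > 0
  v <- x$value * (slope + (1 - slope) * pos)
  nd_node(tape, v, list(x), function(n) {
    nd_accum(n$parents[[1]], n$grad * (slope + (1 - slope) * pos))
  })
}

nd_relu <- function(tape, x) nd_leaky_relu(tape, x, 0)

nd_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  nd_node(tape, s, list(x), function(n) {
    nd_accum(n$parents[[1]], n$grad * s * (1 - s))
  })
}

nd_add <- function(tape, x, y) {
  nd_node(tape, x$value + y$value, list(x, y), function(n) {
    nd_accum(n$parents[[1]], n$grad)
    nd_accum(n$parents[[2]], n$grad)
  })
}

nd_scale <- function(tape, x, k) {
  nd_node(tape, x$value * k, list(x), function(n) {
    nd_accum(n$parents[[1]], n$grad * k)
  })
}

# multiply an (H, W, C) tensor by an (H, W, 1) attention map
nd_mul_map <- function(tape, x, a) {
  am <- a$value[, , 1L]
  C <- dim(x$value)[3]
  v <- x$value * as.vector(am)  # recycles over channels (column-major)
  nd_node(tape, v, list(x, a), function(n) {
    nd_accum(n$parents[[1]], n$grad * as.vector(am))
    hw <- dim(x$value)[1] * dim(x$value)[2]
    ga <- rowSums(matrix(n$grad * x$value, hw, C))
    nd_accum(n$parents[[2]], array(ga, dim = c(dim(am), 1L)))
  })
}

# --- structural -------------------------------------------------------------

nd_concat <- function(tape, x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  v <- array(c(x$value, y$value), dim = c(dx[1], dx[2], dx[3] + dy[3]))
  nd_node(tape, v, list(x, y), function(n) {
    nd_accum(n$parents[[1]], n$grad[, , seq_len(dx[3]), drop = FALSE])
    nd_accum(n$parents[[2]], n$grad[, , dx[3] + seq_len(dy[3]), drop = FALSE])
  })
}

nd_slice_channels <- function(tape, x, ch) {
  d <- dim(x$value)
  nd_node(tape, x$value[, , ch, drop = FALSE], list(x), function(n) {
    g <- array(0, dim = d)
    g[, , ch] <- n$grad
    nd_accum(n$parents[[1]], g)
  })
}

# --- conv / pool / resize ---------------------------------------------------

nd_conv2d <- function(tape, x, w, b, stride = 1L, pad = 1L) {
  v <- .cpp_conv2d_fw(x$value, w$value, b$value, stride, pad)
  nd_node(tape, v, list(x, w, b), function(n) {
    gr <- .cpp_conv2d_bw(n$parents[[1]]$value, n$parents[[2]]$value, n$grad,
                         stride, pad)
    nd_accum(n$parents[[1]], gr$gx)
    nd_accum(n$parents[[2]], gr$gw)
    nd_accum(n$parents[[3]], gr$gb)
  })
}

nd_maxpool2 <- function(tape, x) {
  d <- dim(x$value)
  r <- .cpp_maxpool2_fw(x$value)
  nd_node(tape, r$y, list(x), function(n) {
    nd_accum(n$parents[[1]], .cpp_maxpool2_bw(n$grad, r$idx, d[1], d[2]))
  })
}

nd_upsample2 <- function(tape, x) {
  d <- dim(x$value)
  nd_node(tape, .cpp_upsample2_fw(x$value), list(x), function(n) {
    nd_accum(n$parents[[1]], .cpp_upsample2_bw(n$grad, d[1], d[2]))
  })
}

# warp image node by field node ((H, W, 2): dx, dy)
nd_grid_sample <- function(tape, img, field) {
  dx <- field$value[, , 1L]
  dy <- field$value[, , 2L]
  v <- .cpp_grid_sample_fw(img$value, dx, dy)
  nd_node(tape, v, list(img, field), function(n) {
    gr <- .cpp_grid_sample_bw(n$parents[[1]]$value, dx, dy, n$grad)
    nd_accum(n$parents[[1]], gr$gimg)
    gf <- array(0, dim = dim(field$value))
    gf[, , 1L] <- gr$gdx
    gf[, , 2L] <- gr$gdy
    nd_accum(n$parents[[2]], gf)
  })
}

# --- pooling to vector / dense ----------------------------------------------

nd_global_avg_pool <- function(tape, x) {
  d <- dim(x$value)
  v <- colMeans(matrix(x$value, d[1] * d[2], d[3]))
  nd_node(tape, v, list(x), function(n) {
    g <- array(rep(n$grad / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
    nd_accum(n$parents[[1]], g)
  })
}

# w: (out x in) matrix node, b: length-out node, x: vector node
nd_dense <- function(tape, x, w, b) {
  v <- as.vector(w$value %*% x$value) + b$value
  nd_node(tape, v, list(x, w, b), function(n) {
    nd_accum(n$parents[[1]], as.vector(crossprod(w$value, n$grad)))
    nd_accum(n$parents[[2]], outer(n$grad, n$parents[[1]]$value))
    nd_accum(n$parents[[3]], n$grad)
  })
}

# --- scalar losses ----------------------------------------------------------

nd_smooth_l1 <- function(tape, a, b, phi = 1) {
  d <- a$value - b$value
  N <- length(d)
  quad <- abs(d) < phi
  val <- sum(ifelse(quad, 0.5 * d^2 / phi, abs(d) - 0.5 * phi)) / N
  nd_node(tape, val, list(a, b), function(n) {
    g <- ifelse(quad, d / phi, sign(d)) * (n$grad / N)
    nd_accum(n$parents[[1]], g)
    nd_accum(n$parents[[2]], -g)
  })
}

nd_bce <- function(tape, p, label, eps = 1e-7) {
  pv <- min(max(p$value, eps), 1 - eps)
  val <- -(label * log(pv) + (1 - label) * log(1 - pv))
  clamped <- p$value < eps || p$value > 1 - eps
  nd_node(tape, val, list(p), function(n) {
    g <- if (clamped) 0 else (-(label / pv) + (1 - label) / (1 - pv)) * n$grad
    nd_accum(n$parents[[1]], g)
  })
}

nd_total_variation <- function(tape, x) {
  v <- x$value
  d <- dim(v)
  dv <- v[-1, , , drop = FALSE] - v[-d[1], , , drop = FALSE]
  dh <- v[, -1, , drop = FALSE] - v[, -d[2], , drop = FALSE]
  val <- sum(abs(dv)) + sum(abs(dh))
  nd_node(tape, val, list(x), function(n) {
    g <- array(0, dim = d)
    sv <- sign(dv) * n$grad
    sh <- sign(dh) * n$grad
    g[-1, , ] <- g[-1, , , drop = FALSE] + sv
    g[-d[1], , ] <- g[-d[1], , , drop = FALSE] - sv
    g[, -1, ] <- g[, -1, , drop = FALSE] + sh
    g[, -d[2], ] <- g[, -d[2], , drop = FALSE] - sh
    nd_accum(n$parents[[1]], g)
  })
}

# squared-gradient smoothness of a displacement field node, mean-normalized
nd_smoothness <- function(tape, f) {
  v <- f$value
  d <- dim(v)
  N <- d[1] * d[2]
  dv <- v[-1, , , drop = FALSE] - v[-d[1], , , drop = FALSE]
  dh <- v[, -1, , drop = FALSE] - v[, -d[2], , drop = FALSE]
  val <- (sum(dv^2) + sum(dh^2)) / N
  nd_node(tape, val, list(f), function(n) {
    g <- array(0, dim = d)
    sv <- 2 * dv * (n$grad / N)
    sh <- 2 * dh * (n$grad / N)
    g[-1, , ] <- g[-1, , , drop = FALSE] + sv
    g[-d[1], , ] <- g[-d[1], , , drop = FALSE] - sv
    g[, -1, ] <- g[, -1, , drop = FALSE] + sh
    g[, -d[2], ] <- g[, -d[2], , drop = FALSE] - sh
    nd_accum(n$parents[[1]], g)
  })
}

nd_sum_scalars <- function(tape, nodes, weights) {
  val <- sum(mapply(function(n, w) n$value * w, nodes, weights))
  nd_node(tape, val, nodes, function(n) {
    for (i in seq_along(n$parents)) {
      nd_accum(n$parents[[i]], n$grad * weights[i])
    }
  })
}
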