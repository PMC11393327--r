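# Registration pipeline used to build pixel-aligned training pairs.
#
# Two steps, mirroring the data-preparation workflow for whole-slide pairs:
#  1. global projective registration: scale/rotation-invariant corner
#     features detected on downsampled luminance images, matched by
#     normalized patch descriptors with a ratio test, and a homography
#     estimated by MSAC-style random sampling consensus;
#  2. after tiling, correlation-based pyramid elastic registration:
#     coarse-to-fine block matching by normalized cross-correlation with
#     sub-pixel parabola refinement, block displacements interpolated to a
#     dense smooth field.
# An optional iterated loop trains a style-transfer model (the staining
# generator without its registration submodule) so that elastic registration
# compares images of the same style, repeating until the mean residual
# displacement falls below a threshold.

# --- luminance / pyramid helpers -------------------------------------------

to_gray_any <- function(img) {
  img <- as_image3(img)
  if (dim(img)[3] == 3L) to_gray(img) else apply(img, c(1, 2), mean)
}

downsample_mat <- function(m, factor) {
  if (factor <= 1L) return(m)
  block_downsample(m, factor)[seq_len(nrow(m) %/% factor),
                              seq_len(ncol(m) %/% factor), drop = FALSE]
}

# --- corner features --------------------------------------------------------

harris_corners <- function(g, k = 0.05, max_pts = 400L, min_dist = 6L) {
  gx <- (cbind(g[, -1], g[, ncol(g)]) - cbind(g[, 1], g[, -ncol(g)])) / 2
  gy <- (rbind(g[-1, ], g[nrow(g), ]) - rbind(g[1, ], g[-nrow(g), ])) / 2
  sxx <- gauss_blur(gx * gx, 1.5)
  syy <- gauss_blur(gy * gy, 1.5)
  sxy <- gauss_blur(gx * gy, 1.5)
  resp <- sxx * syy - sxy^2 - k * (sxx + syy)^2
  b <- 10L
  resp[c(seq_len(b), nrow(resp) - seq_len(b) + 1L), ] <- -Inf
  resp[, c(seq_len(b), ncol(resp) - seq_len(b) + 1L)] <- -Inf
  # strict 3x3 local maxima above a response floor, then distance NMS
  is_max <- resp > -Inf
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      is_max <- is_max & (resp >= shift_replicate(resp, di, dj))
    }
  }
  thr <- stats::quantile(resp[is.finite(resp)], 0.5)
  cand <- which(is_max & resp > thr)
  cand <- cand[order(resp[cand], decreasing = TRUE)]
  rows <- ((cand - 1L) %% nrow(resp)) + 1L
  cols <- ((cand - 1L) %/% nrow(resp)) + 1L
  keep_r <- integer(0); keep_c <- integer(0)
  for (i in seq_along(cand)) {
    if (length(keep_r) >= max_pts) break
    if (length(keep_r) == 0 ||
        min((keep_r - rows[i])^2 + (keep_c - cols[i])^2) >= min_dist^2) {
      keep_r <- c(keep_r, rows[i]); keep_c <- c(keep_c, cols[i])
    }
  }
  cbind(row = keep_r, col = keep_c)
}

patch_descriptors <- function(g, pts, radius = 7L) {
  # heavier smoothing makes the normalized patches tolerant to the ~1 px
  # localization jitter of the detector
  gs <- gauss_blur(g, 2)
  n <- nrow(pts)
  ok <- pts[, 1] > radius & pts[, 1] <= nrow(g) - radius &
    pts[, 2] > radius & pts[, 2] <= ncol(g) - radius
  pts <- pts[ok, , drop = FALSE]
  desc <- matrix(0, nrow(pts), (2L * radius + 1L)^2)
  for (i in seq_len(nrow(pts))) {
    p <- gs[(pts[i, 1] - radius):(pts[i, 1] + radius),
            (pts[i, 2] - radius):(pts[i, 2] + radius)]
    p <- p - mean(p)
    nrm <- sqrt(sum(p^2))
    desc[i, ] <- if (nrm > 1e-9) as.vector(p) / nrm else 0
  }
  list(pts = pts, desc = desc)
}

match_descriptors <- function(da, db, ratio = 0.75) {
  if (nrow(da$desc) == 0 || nrow(db$desc) < 2) {
    return(matrix(integer(0), ncol = 2))
  }
  sim <- da$desc %*% t(db$desc)         # correlation since unit-normalized
  m <- matrix(integer(0), ncol = 2)
  for (i in seq_len(nrow(sim))) {
    o <- order(sim[i, ], decreasing = TRUE)
    d1 <- 1 - sim[i, o[1]]
    d2 <- 1 - sim[i, o[2]]
    if (d1 < ratio * d2) m <- rbind(m, c(i, o[1]))
  }
  m
}

# --- homography estimation --------------------------------------------------

# points as (x = col, y = row) 0-based; homography maps moving -> fixed
dlt_homography <- function(src, dst) {
  norm_pts <- function(p) {
    mu <- colMeans(p)
    sc <- sqrt(2) / max(mean(sqrt(rowSums((p - rep(mu, each = nrow(p)))^2))),
                        1e-9)
    T <- rbind(c(sc, 0, -sc * mu[1]), c(0, sc, -sc * mu[2]), c(0, 0, 1))
    list(p = cbind(p[, 1] * sc - sc * mu[1], p[, 2] * sc - sc * mu[2]), T = T)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nv = 9)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

apply_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

#' Global projective registration
#'
#' Estimates the homography mapping `moving` onto `fixed` from matched
#' corner features on downsampled luminance images with MSAC-style robust
#' consensus, rescaled to full resolution.
#'
#' @param moving,fixed Images (matrix, (H, W, C) array); any channel counts.
#' @param downsample_factor Integer downsampling before feature detection.
#' @param inlier_px MSAC reprojection threshold (px, at the downsampled
#'   scale).
#' @param min_inliers Minimum consensus size before the fit is trusted.
#' @param seed Seed for the random sampling.
#' @return List of class `projective_transform` with `matrix` (3x3, maps
#'   moving (x, y, 1) to fixed, 0-based (x = col, y = row) pixel
#'   coordinates, bottom-right element 1) and `n_inliers`.
#' @export
global_register <- function(moving, fixed, downsample_factor = 2L,
                            inlier_px = 2, min_inliers = 8L, seed = 1L) {
  gm <- downsample_mat(to_gray_any(moving), downsample_factor)
  gf <- downsample_mat(to_gray_any(fixed), downsample_factor)
  if (min(dim(gm)) < 128L || min(dim(gf)) < 128L)
    stop("global_register: images must be >= 128 px per side after downsampling")
  dm <- patch_descriptors(gm, harris_corners(gm))
  df <- patch_descriptors(gf, harris_corners(gf))
  matches <- match_descriptors(dm, df)
  if (nrow(matches) < 4L)
    stop(sprintf("registration failure: only %d feature matches", nrow(matches)))
  src <- cbind(dm$pts[matches[, 1], 2] - 1, dm$pts[matches[, 1], 1] - 1)
  dst <- cbind(df$pts[matches[, 2], 2] - 1, df$pts[matches[, 2], 1] - 1)
  best <- NULL
  best_score <- Inf
  n <- nrow(src)
  with_seed(split_seed(seed, "msac"), {
    for (it in seq_len(500L)) {
      s <- sample.int(n, 4L)
      H <- tryCatch(dlt_homography(src[s, , drop = FALSE],
                                   dst[s, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H) || !all(is.finite(H))) next
      proj <- apply_homography(H, src)
      err2 <- rowSums((proj - dst)^2)
      # MSAC score: truncated squared error
      score <- sum(pmin(err2, inlier_px^2))
      if (!is.finite(score)) next
      if (score < best_score) {
        best_score <- score
        best <- H
      }
    }
  })
  if (is.null(best))
    stop("registration failure: no valid homography hypothesis")
  err2 <- rowSums((apply_homography(best, src) - dst)^2)
  err2[!is.finite(err2)] <- Inf
  inl <- err2 <= inlier_px^2
  if (sum(inl) < max(4L, min_inliers))
    stop(sprintf("registration failure: %d inlier matches (need >= %d)",
                 sum(inl), max(4L, min_inliers)))
  H <- dlt_homography(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
  s <- downsample_factor
  S <- diag(c(s, s, 1))
  H_full <- S %*% H %*% solve(S)
  H_full <- H_full / H_full[3, 3]
  # dense sub-pixel refinement: the feature stage localizes to ~1 px at the
  # downsampled scale, so the fitted homography can wobble by a few pixels
  # at the image corners.  Warp once, collect per-block NCC correspondences
  # on the result, and refit the residual homography from them.
  tr0 <- structure(list(matrix = H_full, n_inliers = sum(inl)),
                   class = "projective_transform")
  aw <- to_gray_any(warp_projective(as_image3(moving), tr0))
  gf_full <- to_gray_any(fixed)
  blk <- max(32L, min(dim(aw)) %/% 4L)
  bm <- block_match(aw, gf_full, blk, 3L)
  good <- !is.na(bm$du)
  if (sum(good) >= 4L) {
    # block at fixed-frame position p sampled the warped image at p + d:
    # residual mapping (warped frame -> fixed frame) sends p + d -> p
    src_r <- cbind(bm$c[good] - 1 + bm$du[good], bm$r[good] - 1 + bm$dv[good])
    dst_r <- cbind(bm$c[good] - 1, bm$r[good] - 1)
    Hr <- tryCatch(dlt_homography(src_r, dst_r), error = function(e) NULL)
    if (!is.null(Hr) && all(is.finite(Hr))) {
      H_full <- Hr %*% H_full
      H_full <- H_full / H_full[3, 3]
    }
  }
  structure(list(matrix = H_full, n_inliers = sum(inl)),
            class = "projective_transform")
}

#' Warp an image by a projective transform
#'
#' Resamples `image` so that it aligns with the fixed frame of the
#' homography (inverse mapping with bilinear interpolation, border
#' replication).
#'
#' @param image Image to warp (moving frame).
#' @param transform `projective_transform` from [global_register()].
#' @return Warped image, same shape.
#' @export
warp_projective <- function(image, transform) {
  img <- as_image3(image)
  d <- dim(img)
  Hinv <- solve(transform$matrix)
  xy <- cbind(rep(0:(d[2] - 1), each = d[1]),   # x = col
              rep(0:(d[1] - 1), times = d[2]))  # y = row
  src <- apply_homography(Hinv, xy)
  dx <- matrix(src[, 1] - xy[, 1], d[1], d[2])
  dy <- matrix(src[, 2] - xy[, 2], d[1], d[2])
  out <- .cpp_grid_sample_fw(img, dx, dy)
  if (is.matrix(image)) out[, , 1] else out
}

#' Tile a registered WSI pair into training tiles
#'
#' Non-overlapping grid tiles; edge remainders are dropped; origins are
#' recorded in WSI coordinates (0-based row, col).
#'
#' @param moving_wsi Stained image (H, W, 3), already globally registered.
#' @param fixed_wsi Autofluorescence stack (H, W, C).
#' @param tile_size Tile side in pixels (default 2048).
#' @param modality Modality tag copied into each pair.
#' @return List of tile pairs (`stack`, `target`, `modality`,
#'   `tile_origin`).
#' @export
tile_pairs <- function(moving_wsi, fixed_wsi, tile_size = 2048L,
                       modality = "brightfield") {
  moving_wsi <- as_image3(moving_wsi)
  fixed_wsi <- as_image3(fixed_wsi)
  stop_shape(moving_wsi, fixed_wsi, "WSIs")
  d <- dim(fixed_wsi)
  if (tile_size > d[1] || tile_size > d[2])
    stop("tile_size exceeds WSI dimensions")
  nr <- d[1] %/% tile_size
  nc <- d[2] %/% tile_size
  pairs <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * tile_size
      c0 <- (j - 1L) * tile_size
      k <- k + 1L
      pairs[[k]] <- list(
        stack = fixed_wsi[r0 + seq_len(tile_size), c0 + seq_len(tile_size), ,
                          drop = FALSE],
        target = moving_wsi[r0 + seq_len(tile_size), c0 + seq_len(tile_size), ,
                            drop = FALSE],
        modality = modality, tile_origin = c(r0, c0))
    }
  }
  pairs
}

# --- elastic registration ---------------------------------------------------

integral_image <- function(m) {
  I <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  I[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  I
}

block_sums <- function(I, r0, c0, h, w) {
  # r0, c0: 1-based top-left corners (vectors); returns matrix same length
  I[cbind(r0 + h, c0 + w)] - I[cbind(r0, c0 + w)] -
    I[cbind(r0 + h, c0)] + I[cbind(r0, c0)]
}

shift_replicate <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  m[ri, ci, drop = FALSE]
}

# one pyramid level: best per-block displacement of `a` matching `b`
block_match <- function(a, b, block, search) {
  H <- nrow(a); W <- ncol(a)
  step <- max(4L, block %/% 2L)
  r0 <- seq(1L, H - block + 1L, by = step)
  c0 <- seq(1L, W - block + 1L, by = step)
  grid <- expand.grid(r = r0, c = c0)
  nb <- nrow(grid)
  Ib <- integral_image(b)
  Ib2 <- integral_image(b * b)
  sb <- block_sums(Ib, grid$r, grid$c, block, block)
  sb2 <- block_sums(Ib2, grid$r, grid$c, block, block)
  npx <- block * block
  var_b <- sb2 / npx - (sb / npx)^2
  shifts <- expand.grid(u = -search:search, v = -search:search)
  ncc <- array(NA_real_, dim = c(nb, nrow(shifts)))
  for (si in seq_len(nrow(shifts))) {
    as <- shift_replicate(a, shifts$v[si], shifts$u[si])
    Ia <- integral_image(as)
    Ia2 <- integral_image(as * as)
    Iab <- integral_image(as * b)
    sa <- block_sums(Ia, grid$r, grid$c, block, block)
    sa2 <- block_sums(Ia2, grid$r, grid$c, block, block)
    sab <- block_sums(Iab, grid$r, grid$c, block, block)
    var_a <- sa2 / npx - (sa / npx)^2
    cov_ab <- sab / npx - (sa / npx) * (sb / npx)
    ncc[, si] <- cov_ab / sqrt(pmax(var_a, 1e-12) * pmax(var_b, 1e-12))
  }
  flat <- var_b < 1e-6
  du <- dv <- rep(NA_real_, nb)
  peak <- rep(0, nb)
  ns <- 2L * search + 1L
  # match on |NCC| so anti-correlated modalities (e.g. brightfield
  # absorbance vs autofluorescence emission) still register
  ncc <- abs(ncc)
  for (bi in seq_len(nb)) {
    if (flat[bi]) next
    k <- which.max(ncc[bi, ])
    peak[bi] <- ncc[bi, k]
    ui <- ((k - 1L) %% ns) + 1L
    vi <- ((k - 1L) %/% ns) + 1L
    u <- shifts$u[k]; v <- shifts$v[k]
    # sub-pixel parabola refinement along each axis
    refine <- function(cm, cc, cp) {
      den <- cm - 2 * cc + cp
      if (!is.finite(den) || abs(den) < 1e-12) return(0)
      max(min(0.5 * (cm - cp) / den, 0.5), -0.5)
    }
    if (ui > 1L && ui < ns) {
      u <- u + refine(ncc[bi, k - 1L], ncc[bi, k], ncc[bi, k + 1L])
    }
    if (vi > 1L && vi < ns) {
      v <- v + refine(ncc[bi, k - ns], ncc[bi, k], ncc[bi, k + ns])
    }
    # shifting a by (u, v) aligned it with b, so the sampling displacement
    # (warped(p) = a(p + d)) for this block is d = (u, v)
    du[bi] <- u
    dv[bi] <- v
  }
  # blocks with a weak correlation peak are unreliable: exclude and
  # interpolate over them
  weak <- peak < 0.4
  du[weak] <- NA; dv[weak] <- NA
  list(r = grid$r + block / 2, c = grid$c + block / 2, du = du, dv = dv,
       all_flat = all(flat))
}

# interpolate scattered block displacements (on a regular grid) to a dense
# field via bilinear interpolation + gaussian smoothing
dense_field_from_blocks <- function(bm, H, W, smooth_sigma) {
  rs <- sort(unique(bm$r)); cs <- sort(unique(bm$c))
  gu <- matrix(bm$du, length(rs), length(cs))
  gv <- matrix(bm$dv, length(rs), length(cs))
  # fill excluded (flat) blocks with the field median
  fill <- function(g) {
    if (all(is.na(g))) return(matrix(0, nrow(g), ncol(g)))
    g[is.na(g)] <- stats::median(g, na.rm = TRUE)
    g
  }
  gu <- fill(gu); gv <- fill(gv)
  interp_axis <- function(coords, n) {
    # for each output position, find bracketing grid coords + weight
    x <- seq_len(n)
    i1 <- findInterval(x, coords, all.inside = TRUE)
    i2 <- pmin(i1 + 1L, length(coords))
    t <- ifelse(i2 > i1, (x - coords[i1]) / (coords[i2] - coords[i1]), 0)
    t <- pmin(pmax(t, 0), 1)
    list(i1 = i1, i2 = i2, t = t)
  }
  ar <- interp_axis(rs, H); ac <- interp_axis(cs, W)
  expand <- function(g) {
    g1 <- g[ar$i1, , drop = FALSE] * (1 - ar$t) + g[ar$i2, , drop = FALSE] * ar$t
    g1[, ac$i1, drop = FALSE] * rep(1 - ac$t, each = H) +
      g1[, ac$i2, drop = FALSE] * rep(ac$t, each = H)
  }
  dx <- expand(gu); dy <- expand(gv)
  if (smooth_sigma > 0) {
    dx <- gauss_blur(dx, smooth_sigma)
    dy <- gauss_blur(dy, smooth_sigma)
  }
  array(c(dx, dy), dim = c(H, W, 2L))
}

#' Correlation-based pyramid elastic registration
#'
#' Coarse-to-fine block matching: at each pyramid level the current estimate
#' warps the moving image, residual block displacements are found at the
#' normalized-cross-correlation peak (sub-pixel parabola refinement), and
#' the block grid is interpolated to a dense smooth field.  Zero-variance
#' blocks are excluded; if every block is flat a registration-failure error
#' is raised.  The returned field maps moving to fixed:
#' `warp_image(moving, field)` aligns with `fixed`.
#'
#' @param moving,fixed Same-shape images (converted to luminance).
#' @param levels Pyramid depth (default 4).
#' @param block_size Block side at full resolution (default 64); halved per
#'   level down to 8 px.
#' @param search_px Integer search radius per level (default 3).
#' @param guard If the recovered field would increase the luminance MAE by
#'   more than 1%, return the zero field with a warning.
#' @return (H, W, 2) displacement field (dx, dy).
#' @export
elastic_register <- function(moving, fixed, levels = 4L, block_size = 64L,
                             search_px = 3L, guard = TRUE) {
  gm <- to_gray_any(moving)
  gf <- to_gray_any(fixed)
  if (!identical(dim(gm), dim(gf))) stop("elastic_register: shape mismatch")
  H <- nrow(gm); W <- ncol(gm)
  # pyramid, coarse -> fine
  pyr_m <- list(gm); pyr_f <- list(gf)
  for (l in seq_len(levels - 1L)) {
    pyr_m[[l + 1L]] <- downsample_mat(pyr_m[[l]], 2L)
    pyr_f[[l + 1L]] <- downsample_mat(pyr_f[[l]], 2L)
  }
  field <- NULL
  for (l in rev(seq_len(levels))) {
    a <- pyr_m[[l]]; b <- pyr_f[[l]]
    h <- nrow(a); w <- ncol(a)
    if (is.null(field)) {
      field <- array(0, dim = c(h, w, 2L))
    } else {
      up <- .cpp_upsample2_fw(field) * 2
      field <- up[seq_len(h), seq_len(w), , drop = FALSE]
    }
    blk <- max(16L, min(block_size %/% 2L^(l - 1L), min(h, w) %/% 2L))
    if (min(h, w) < 2L * blk) next
    aw <- .cpp_grid_sample_fw(array(a, dim = c(h, w, 1L)),
                              field[, , 1], field[, , 2])[, , 1]
    bm <- block_match(aw, b, blk, search_px)
    if (bm$all_flat && l == levels) {
      stop("registration failure: all blocks have zero variance")
    }
    if (!bm$all_flat) {
      resid <- dense_field_from_blocks(bm, h, w, smooth_sigma = blk / 4)
      # compose: f_total(p) = resid(p) + f_old(p + resid(p))
      comp <- .cpp_grid_sample_fw(field, resid[, , 1], resid[, , 2])
      field <- comp + resid
    }
  }
  if (guard) {
    aw <- .cpp_grid_sample_fw(array(gm, dim = c(H, W, 1L)),
                              field[, , 1], field[, , 2])[, , 1]
    if (mean(abs(aw - gf)) > 1.01 * mean(abs(gm - gf))) {
      message("elastic_register: recovered field rejected by guard; ",
              "returning zero field")
      field <- array(0, dim = c(H, W, 2L))
    }
  }
  field
}

#' Warp an image by a dense displacement field
#'
#' Bilinear resampling at the displaced coordinates:
#' `out(h, w) = image(h + dy(h, w), w + dx(h, w))`, with border replication
#' for out-of-bounds samples.  All channels are warped identically.
#'
#' @param image Matrix or (H, W, C) array.
#' @param field (H, W, 2) displacement field (dx, dy) in pixels.
#' @return Warped image, same shape as the input.
#' @export
warp_image <- function(image, field) {
  img <- as_image3(image)
  field <- as_image3(field)
  stop_shape(img, field, "image and field")
  if (dim(field)[3] != 2L) stop("field must have 2 components (dx, dy)")
  out <- .cpp_grid_sample_fw(img, field[, , 1], field[, , 2])
  if (is.matrix(image)) out[, , 1] else out
}

# zeroth-round style bridge when no trained style-transfer model is
# supplied: regress the target luminance on the stack channels (ordinary
# least squares over all pixels) so block matching compares images of the
# same contrast polarity.  Misalignment of a few pixels only blurs the fit.
linear_style_proxy <- function(stack, target) {
  st <- as_image3(stack)
  d <- dim(st)
  X <- cbind(matrix(st, d[1] * d[2], d[3]), 1)
  y <- as.vector(to_gray_any(target))
  beta <- tryCatch(qr.solve(crossprod(X), crossprod(X, y)),
                   error = function(e) NULL)
  if (is.null(beta)) return(to_gray_any(st))
  matrix(X %*% beta, d[1], d[2])
}

#' Build a registered training dataset from WSI pairs
#'
#' Orchestrates the full preparation: (1) global projective registration of
#' each stained WSI against its autofluorescence stack and warping; (2)
#' tiling; (3) an iterated loop that trains a style-transfer model (the
#' staining generator without its registration submodule) and applies
#' elastic registration on tiles, until the mean residual displacement
#' drops below `residual_px` or `max_rounds` is reached.  Tiles whose
#' registration fails are kept unwarped and logged.
#'
#' @param stacks List of autofluorescence WSIs (H, W, C).
#' @param stained_images List of stained WSIs (H, W, 3), same order.
#' @param modality Modality of the stained images.
#' @param tile_size Tile side (pixels).
#' @param max_rounds Maximum style-transfer/elastic iterations (default 2).
#' @param residual_px Convergence threshold on the mean residual
#'   displacement (default 0.5 px).
#' @param style_cfg Optional [train_config()] for the style-transfer model;
#'   `NULL` skips style transfer and registers against the mean stack
#'   channel directly (adequate when modalities correlate, e.g. phantoms).
#' @param net_cfg [network_config()] for the style model.
#' @param global Apply the global projective step (disable when the WSIs
#'   are already coarsely aligned).
#' @return List of tile pairs with attribute `residuals` (per-round mean
#'   residual displacement) and `skipped` (indices of failed tiles).
#' @export
prepare_registered_dataset <- function(stacks, stained_images,
                                       modality = "brightfield",
                                       tile_size = 256L, max_rounds = 2L,
                                       residual_px = 0.5,
                                       style_cfg = NULL,
                                       net_cfg = network_config(),
                                       global = TRUE) {
  stopifnot(length(stacks) == length(stained_images))
  pairs <- list()
  for (i in seq_along(stacks)) {
    st <- as_image3(stacks[[i]])
    mv <- as_image3(stained_images[[i]])
    if (global) {
      tr <- global_register(mv, st)
      mv <- warp_projective(mv, tr)
    }
    pairs <- c(pairs, tile_pairs(mv, st, tile_size, modality))
  }
  residuals <- numeric(0)
  skipped <- integer(0)
  for (round in seq_len(max_rounds)) {
    style_model <- if (!is.null(style_cfg)) {
      cfgr <- style_cfg
      cfgr$use_registration <- FALSE
      cfgr$modalities <- modality
      train(pairs, net_cfg = net_cfg, cfg = cfgr)
    } else NULL
    res_round <- numeric(length(pairs))
    for (ti in seq_along(pairs)) {
      p <- pairs[[ti]]
      ref <- if (!is.null(style_model)) {
        infer_tile(style_model, p$stack, modality)
      } else linear_style_proxy(p$stack, p$target)
      field <- tryCatch(
        elastic_register(p$target, ref),
        error = function(e) {
          skipped <<- union(skipped, ti)
          message(sprintf("tile %d round %d: %s", ti, round,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(field)) {
        res_round[ti] <- NA_real_
        next
      }
      pairs[[ti]]$target <- warp_image(p$target, field)
      res_round[ti] <- mean(sqrt(field[, , 1]^2 + field[, , 2]^2))
    }
    residuals <- c(residuals, mean(res_round, na.rm = TRUE))
    if (residuals[length(residuals)] < residual_px) break
  }
  attr(pairs, "residuals") <- residuals
  attr(pairs, "skipped") <- skipped
  pairs
}
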