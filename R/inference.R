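# Deterministic tile-wise virtual staining and seam-free stitching.
#
# Only the generator is used at test time; the DSM channel selects the
# output modality.  Tiles whose size is not divisible by 16 are padded by
# reflection internally and cropped back.  Whole images are processed as
# overlapping tiles blended with linear feathering, so stitching is
# independent of the traversal order.

pad_reflect <- function(img, pr, pc) {
  d <- dim(img)
  ri <- c(seq_len(d[1]), rev(seq_len(d[1]))[seq_len(pr) + 1L])
  ci <- c(seq_len(d[2]), rev(seq_len(d[2]))[seq_len(pc) + 1L])
  img[ri, ci, , drop = FALSE]
}

#' Virtually stain one tile
#'
#' `clip(G(stack (+) DSM), 0, 1)`; deterministic for fixed weights and
#' input.  The stack is normalized with the statistics frozen in the
#' checkpoint.
#'
#' @param checkpoint `virtpol_checkpoint` from [train()] (or a bare
#'   `virtpol_generator` for un-normalized use).
#' @param stack (H, W, in_channels) autofluorescence tile in `[0, 1]`.
#' @param modality `"brightfield"`, `"crosspol"` or `"angleshift"`.
#' @return (H, W, 3) RGB image in `[0, 1]`.
#' @export
infer_tile <- function(checkpoint, stack, modality) {
  if (inherits(checkpoint, "virtpol_checkpoint")) {
    gen <- checkpoint$generator
    stack <- normalize_stack(as_image3(stack), checkpoint$norm_stats)
  } else {
    gen <- checkpoint
    stack <- as_image3(stack)
  }
  d <- dim(stack)
  div <- 2L^gen$config$generator_levels
  pr <- (div - d[1] %% div) %% div
  pc <- (div - d[2] %% div) %% div
  padded <- if (pr > 0L || pc > 0L) pad_reflect(stack, pr, pc) else stack
  dsm <- make_dsm(dim(padded)[1], dim(padded)[2], modality)
  out <- generator_forward(gen, padded, dsm)
  clip01(out[seq_len(d[1]), seq_len(d[2]), , drop = FALSE])
}

feather_weight <- function(n, overlap, at_start, at_end) {
  w <- rep(1, n)
  if (overlap > 0) {
    ramp <- seq_len(overlap) / (overlap + 1)
    if (at_start) w[seq_len(overlap)] <- ramp
    if (at_end) w[n - overlap + seq_len(overlap)] <- rev(ramp)
  }
  w
}

#' Virtually stain a whole image, tile by tile
#'
#' Tiles of side `tile` with `overlap` pixels of overlap are inferred and
#' blended with linear feathering in the overlap zones; all requested
#' modalities are produced from the same stack.
#'
#' @param checkpoint `virtpol_checkpoint`.
#' @param wsi_stack (H, W, in_channels) stack.
#' @param modalities Character vector of modalities to render.
#' @param tile Tile side (pixels).
#' @param overlap Overlap width (>= 0, < tile / 2; default 64).
#' @return Named list of (H, W, 3) images, one per modality.
#' @export
infer_wsi <- function(checkpoint, wsi_stack, modalities = "brightfield",
                      tile = 256L, overlap = 64L) {
  stack <- as_image3(wsi_stack)
  d <- dim(stack)
  if (overlap < 0L || overlap >= tile / 2) stop("need 0 <= overlap < tile/2")
  step <- tile - overlap
  starts <- function(n) {
    if (n <= tile) return(1L)
    s <- seq(1L, n - tile + 1L, by = step)
    if (s[length(s)] + tile - 1L < n) s <- c(s, n - tile + 1L)
    s
  }
  rs <- starts(d[1]); cs <- starts(d[2])
  out <- list()
  for (m in modalities) {
    acc <- array(0, dim = c(d[1], d[2], 3L))
    wacc <- matrix(0, d[1], d[2])
    for (r0 in rs) {
      for (c0 in cs) {
        h <- min(tile, d[1] - r0 + 1L)
        w <- min(tile, d[2] - c0 + 1L)
        tl <- stack[r0 + seq_len(h) - 1L, c0 + seq_len(w) - 1L, ,
                    drop = FALSE]
        pred <- infer_tile(checkpoint, tl, m)
        ov_r <- if (length(rs) > 1L) overlap else 0L
        ov_c <- if (length(cs) > 1L) overlap else 0L
        wr <- feather_weight(h, min(ov_r, h %/% 2L), r0 > 1L,
                             r0 + h - 1L < d[1])
        wc <- feather_weight(w, min(ov_c, w %/% 2L), c0 > 1L,
                             c0 + w - 1L < d[2])
        wt <- outer(wr, wc)
        ridx <- r0 + seq_len(h) - 1L
        cidx <- c0 + seq_len(w) - 1L
        for (ch in 1:3) {
          acc[ridx, cidx, ch] <- acc[ridx, cidx, ch] + pred[, , ch] * wt
        }
        wacc[ridx, cidx] <- wacc[ridx, cidx] + wt
      }
    }
    for (ch in 1:3) acc[, , ch] <- acc[, , ch] / wacc
    out[[m]] <- clip01(acc)
  }
  out
}
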