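# Seeded phantom generator.
#
# Emulates the statistical structure of paired autofluorescence /
# Congo-red-stained cardiac tissue images so the full pipeline is testable
# without patient data: amyloid deposits are irregular blobs (thresholded
# smoothed random fields, not disks) with a correlated multi-channel
# autofluorescence signature; nuclei are non-overlapping disks placed by
# dart-throwing (Poisson-disk style) so the ground-truth count is
# unambiguous.  Brightfield targets render amyloid pink-salmon and nuclei
# dark red-purple on a pale background; cross-polarized targets render
# apple-green (hue near 120 deg) amyloid on a near-black background; the
# angle-shifted target is derived from the cross-polarized one via
# [simulate_angle_shift()].  All intensities are floats in [0, 1]; sub-seeds
# for placement, texture and noise are derived from the master seed by a
# counter scheme so the generator is bit-reproducible.

#' Phantom specification
#'
#' @param image_size Square image side in pixels (>= 64).
#' @param n_amyloid_blobs Number of amyloid deposit seeds (controls blob
#'   granularity; the area is set by `amyloid_area_fraction`).
#' @param amyloid_area_fraction Fraction of pixels covered by amyloid.
#' @param n_nuclei Nuclei count.
#' @param nucleus_radius_px Nucleus disk radius in pixels.
#' @param background_texture_scale Correlation length (pixels) of the tissue
#'   background texture.
#' @param noise_sigma Gaussian noise s.d. added to the stack, in `[0, 1]`
#'   intensity units.
#' @param deformation_amplitude_px Default amplitude for
#'   [apply_synthetic_deformation()].
#' @param seed Master seed.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L, n_amyloid_blobs = 6L,
                         amyloid_area_fraction = 0.15, n_nuclei = 25L,
                         nucleus_radius_px = 5L,
                         background_texture_scale = 12,
                         noise_sigma = 0.01,
                         deformation_amplitude_px = 4,
                         seed = 1L) {
  if (image_size < 64L) stop("image_size must be >= 64")
  if (n_amyloid_blobs < 0L || n_nuclei < 0L) stop("counts must be >= 0")
  if (amyloid_area_fraction < 0 || amyloid_area_fraction > 1)
    stop("amyloid_area_fraction must be in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (deformation_amplitude_px < 0)
    stop("deformation_amplitude_px must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 n_amyloid_blobs = as.integer(n_amyloid_blobs),
                 amyloid_area_fraction = amyloid_area_fraction,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_px = nucleus_radius_px,
                 background_texture_scale = background_texture_scale,
                 noise_sigma = noise_sigma,
                 deformation_amplitude_px = deformation_amplitude_px,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth random field in [0,1], zero-mean-ish, given correlation scale
smooth_field <- function(n, scale) {
  f <- gauss_blur(matrix(stats::rnorm(n * n), n, n), scale)
  rng <- range(f)
  if (diff(rng) < 1e-12) return(matrix(0.5, n, n))
  (f - rng[1]) / diff(rng)
}

poisson_disk <- function(n_points, n, min_dist, margin) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < n_points && tries < 5000L) {
    tries <- tries + 1L
    p <- stats::runif(2, min = margin + 1, max = n - margin)
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_dist) {
      pts <- rbind(pts, p)
    }
  }
  pts
}

disk_mask <- function(n, centers, radius) {
  m <- matrix(FALSE, n, n)
  if (is.null(centers) || nrow(centers) == 0) return(m)
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  for (i in seq_len(nrow(centers))) {
    m <- m | ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2)
  }
  m
}

# amyloid channel gains across (DAPI, FITC, TxRed, Cy5): congophilic regions
# show correlated elevation over all channels with the strongest response in
# the mid-visible channels.  Free parameters of the phantom world (no
# quantitative autofluorescence signature is available); fixed here.
AMYLOID_GAINS <- c(0.35, 0.85, 0.65, 0.75)
TISSUE_GAINS <- c(0.30, 0.25, 0.30, 0.20)

#' Generate one phantom sample
#'
#' @param spec [phantom_spec()].
#' @return List of class `phantom_sample` with `stack` (H, W, 4),
#'   `brightfield_gt`, `crosspol_gt`, `angleshift_gt` (H, W, 3),
#'   `amyloid_mask`, `nuclei_mask` (logical H x W), `nuclei_count`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size

  # amyloid mask: smoothed random field seeded by blob centres, thresholded
  # at the quantile matching the requested area fraction
  amyloid <- with_seed(split_seed(spec$seed, "amyloid"), {
    if (spec$n_amyloid_blobs == 0L || spec$amyloid_area_fraction <= 0) {
      list(mask = matrix(FALSE, n, n), soft = matrix(0, n, n))
    } else {
      scale <- max(4, n / (4 * sqrt(spec$n_amyloid_blobs)))
      f <- smooth_field(n, scale)
      thr <- stats::quantile(f, 1 - spec$amyloid_area_fraction)
      mask <- f >= thr
      soft <- pmin(1, pmax(0, (f - thr) / max(1e-9, (max(f) - thr)) * 3))
      list(mask = mask, soft = soft)
    }
  })
  mask <- amyloid$mask
  soft <- amyloid$soft            # graded deposit density in [0,1]

  nuclei <- with_seed(split_seed(spec$seed, "nuclei"), {
    ctr <- poisson_disk(spec$n_nuclei, n,
                        min_dist = 3 * spec$nucleus_radius_px,
                        margin = 2 * spec$nucleus_radius_px)
    list(mask = disk_mask(n, ctr, spec$nucleus_radius_px),
         count = nrow(ctr))
  })

  texture <- with_seed(split_seed(spec$seed, "texture"), {
    smooth_field(n, spec$background_texture_scale)
  })

  # --- autofluorescence stack ----------------------------------------------
  stack <- array(0, dim = c(n, n, 4L))
  tex <- 0.5 + 0.5 * (texture - 0.5)
  for (c in 1:4) {
    ch <- TISSUE_GAINS[c] * tex + AMYLOID_GAINS[c] * soft
    if (c == 1L) ch <- ch + 0.55 * nuclei$mask   # nuclei visible in DAPI
    stack[, , c] <- clip01(ch)
  }
  stack <- with_seed(split_seed(spec$seed, "stacknoise"), {
    if (spec$noise_sigma > 0) {
      clip01(stack + array(stats::rnorm(length(stack), sd = spec$noise_sigma),
                           dim = dim(stack)))
    } else stack
  })

  # --- brightfield target ---------------------------------------------------
  bg <- c(0.93, 0.91, 0.93)
  amy <- c(0.90, 0.52, 0.50)      # pink-salmon congophilic hue
  nuc <- c(0.45, 0.20, 0.45)      # dark red-purple nuclear stain
  bf <- array(0, dim = c(n, n, 3L))
  shade <- 0.92 + 0.08 * texture
  for (c in 1:3) {
    ch <- bg[c] * shade
    ch <- ch * (1 - soft) + amy[c] * soft * shade
    ch[nuclei$mask] <- nuc[c] * shade[nuclei$mask]
    bf[, , c] <- clip01(ch)
  }

  # --- cross-polarized target ----------------------------------------------
  # apple-green birefringence on near-black background
  glow <- soft * (0.55 + 0.45 * texture)
  cp <- array(0, dim = c(n, n, 3L))
  cp[, , 1] <- clip01(0.02 + 0.18 * glow)
  cp[, , 2] <- clip01(0.02 + 0.80 * glow)
  cp[, , 3] <- clip01(0.02 + 0.12 * glow)

  as_gt <- simulate_angle_shift(cp)

  structure(list(stack = stack, brightfield_gt = bf, crosspol_gt = cp,
                 angleshift_gt = as_gt, amyloid_mask = mask,
                 nuclei_mask = nuclei$mask, nuclei_count = nuclei$count,
                 spec = spec),
            class = "phantom_sample")
}

#' Warp a phantom's stained targets by a smooth random deformation
#'
#' Emulates the tissue distortion introduced by histochemical staining: the
#' stained targets are resampled through a smooth random displacement field
#' of bounded amplitude while the autofluorescence stack stays put, so
#' registration can be tested against the known true field.
#'
#' @param sample A `phantom_sample`.
#' @param amplitude_px Maximum displacement magnitude (pixels, >= 0).
#' @param seed Seed for the random field.
#' @param scale_px Correlation length of the random field in pixels.  An
#'   absolute scale (default 32): staining-induced tissue distortion has a
#'   physical correlation length that does not shrink with the crop size.
#' @return List with `sample` (targets warped) and `field`
#'   ((H, W, 2) true displacement, moving -> fixed).
#' @export
apply_synthetic_deformation <- function(sample, amplitude_px = NULL,
                                        seed = NULL, scale_px = 32) {
  stopifnot(inherits(sample, "phantom_sample"))
  amplitude_px <- amplitude_px %||% sample$spec$deformation_amplitude_px
  seed <- seed %||% split_seed(sample$spec$seed, "deform")
  if (amplitude_px < 0) stop("amplitude_px must be >= 0")
  n <- dim(sample$stack)[1]
  field <- array(0, dim = c(n, n, 2L))
  if (amplitude_px > 0) {
    field <- with_seed(seed, {
      dx <- smooth_field(n, scale_px) - 0.5
      dy <- smooth_field(n, scale_px) - 0.5
      mag <- pmax(sqrt(dx^2 + dy^2), 1e-9)
      k <- amplitude_px / max(mag)
      array(c(dx * k, dy * k), dim = c(n, n, 2L))
    })
    for (nm in c("brightfield_gt", "crosspol_gt", "angleshift_gt")) {
      sample[[nm]] <- warp_image(sample[[nm]], field)
    }
  }
  list(sample = sample, field = field)
}

#' Add Gaussian noise to an autofluorescence stack
#'
#' Each channel is perturbed i.i.d. `N(0, sigma^2)` and clipped to `[0, 1]`,
#' simulating acquisition with a lower-SNR sensor.
#'
#' @param stack (H, W, C) array in `[0, 1]`.
#' @param sigma Noise s.d. (>= 0).
#' @param seed Seed.
#' @return Noisy stack, same shape.
#' @export
add_gaussian_noise <- function(stack, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  stack <- as_image3(stack)
  if (sigma == 0) return(stack)
  with_seed(split_seed(seed, "noise"), {
    clip01(stack + array(stats::rnorm(length(stack), sd = sigma),
                         dim = dim(stack)))
  })
}

#' Build a phantom tile-pair dataset for training
#'
#' Convenience wrapper: generates `n` phantoms (seeds `seed + 0..n-1`) and
#' expands each into one tile pair per requested modality.
#'
#' @param n Number of phantom samples.
#' @param spec Template [phantom_spec()]; its seed is replaced per sample.
#' @param modalities Modalities to emit.
#' @param seed Base seed.
#' @return List of tile pairs (`stack`, `target`, `modality`,
#'   `tile_origin`), plus the samples as attribute `samples`.
#' @export
phantom_dataset <- function(n, spec = phantom_spec(),
                            modalities = c("brightfield", "crosspol"),
                            seed = 1L) {
  samples <- lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- as.integer(seed + i - 1L)
    generate_phantom(sp)
  })
  target_of <- c(brightfield = "brightfield_gt", crosspol = "crosspol_gt",
                 angleshift = "angleshift_gt")
  pairs <- list()
  for (s in samples) {
    for (m in modalities) {
      pairs[[length(pairs) + 1L]] <-
        list(stack = s$stack, target = s[[target_of[[m]]]], modality = m,
             tile_origin = c(0L, 0L))
    }
  }
  attr(pairs, "samples") <- samples
  pairs
}
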