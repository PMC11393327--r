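# Evaluation suite: closed forms, oracles, segmentation, D-IoU, histograms,
# nuclei quantification, angle-shift emulation.

test_that("mae and psnr match closed forms and oracles", {
  a <- matrix(0.2, 8, 8)
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a, a + 0.1), 0.1)
  # max(A) = 1, MSE = 0.01 -> 20 dB
  A <- matrix(c(1, rep(0.5, 63)), 8, 8)
  B <- A + 0.1
  expect_equal(psnr(A, B), 10 * log10(1 / 0.01))
  # peak-from-ground-truth rule: max(A) = 0.5, MSE = 0.0025 -> 20 dB
  A2 <- matrix(0.5, 8, 8)
  expect_equal(psnr(A2, A2 + 0.05), 10 * log10(0.25 / 0.0025))
  expect_warning(v <- psnr(a, a), "identical")
  expect_identical(v, Inf)
  set.seed(14)
  for (i in 1:50) {
    X <- rand_img(); Y <- rand_img()
    expect_equal(mae(X, Y), oracle_mae(X, Y), tolerance = 1e-6)
    expect_equal(psnr(X, Y), oracle_psnr(X, Y), tolerance = 1e-6)
  }
})

test_that("ms_ssim: identity, weights, frozen cross-implementation value", {
  img <- phantom_holdout()$crosspol_gt
  expect_equal(ms_ssim(img, img), 1, tolerance = 1e-9)
  expect_equal(ms_ssim_weights("brightfield"),
               c(0.05, 0.05, 0.1, 0.15, 0.2, 0.45))
  expect_equal(ms_ssim_weights("crosspol"),
               c(0.45, 0.2, 0.15, 0.1, 0.05, 0.05))
  expect_equal(sum(ms_ssim_weights("brightfield")), 1)
  # single-scale SSIM core against scikit-image (structural_similarity with
  # an 11 px gaussian window, sigma 1.5, population covariance) on a seeded
  # pair; reference value frozen from that implementation
  set.seed(99)
  a <- matrix(runif(96 * 96), 96, 96)
  b <- pmin(pmax(a + matrix(rnorm(96 * 96, sd = 0.05), 96, 96), 0), 1)
  m <- asNamespace("virtpol")$ssim_maps(a, b)
  expect_equal(mean(m$l * m$cs), 0.98514271, tolerance = 1e-6)
  # approximate symmetry (luminance-peak convention is symmetric here)
  s <- phantom_holdout()
  v1 <- ms_ssim(s$brightfield_gt, s$crosspol_gt)
  v2 <- ms_ssim(s$crosspol_gt, s$brightfield_gt)
  expect_equal(v1, v2, tolerance = 1e-8)
  expect_error(ms_ssim(matrix(0, 64, 64), matrix(0, 64, 64)), "352")
})

test_that("fid: identical sets, analytic mean-shift limit, Y adjustment", {
  set.seed(31)
  imgs <- lapply(1:4, function(i) rand_img(48, 48, 3))
  expect_equal(fid(imgs, imgs), 0, tolerance = 1e-6)
  expect_equal(fid(imgs, imgs, polarization = TRUE), 0, tolerance = 1e-6)
  # features from N(0, I) vs N(delta, I): FID -> ||delta||^2
  n <- 10000L; p <- 8L
  delta <- seq(0.5, 1.2, length.out = p)
  fa <- matrix(rnorm(n * p), n, p)
  fb <- matrix(rnorm(n * p), n, p) + rep(delta, each = n)
  expect_equal(fid(fa, fb), sum(delta^2), tolerance = 0.15)
  expect_error(fid(imgs[1], imgs), "at least 2")
})

test_that("segment_birefringence isolates the apple-green band", {
  expect_equal(sum(segment_birefringence(array(0, dim = c(64, 64, 3)))), 0)
  # pure apple-green square on black
  img <- array(0, dim = c(64, 64, 3))
  sq <- 20:44
  hsv <- array(0, dim = c(64, 64, 3))
  hsv[sq, sq, 1] <- 120 / 360
  hsv[sq, sq, 2] <- 0.8
  hsv[sq, sq, 3] <- 0.8
  img <- hsv_to_rgb(hsv)
  m <- segment_birefringence(img)
  truth <- matrix(FALSE, 64, 64); truth[sq, sq] <- TRUE
  expect_gte(sum(m & truth) / sum(truth), 0.95)
  expect_equal(sum(m & !truth), 0)
  # pink-salmon patch (hue ~350 deg) is rejected
  hsv[sq, sq, 1] <- 350 / 360
  expect_equal(sum(segment_birefringence(hsv_to_rgb(hsv))), 0)
})

test_that("d_iou: identity, disjoint supports, misalignment resilience", {
  m <- matrix(FALSE, 128, 128)
  m[20:60, 20:60] <- TRUE
  expect_equal(d_iou(m, m), 1)
  m2 <- matrix(FALSE, 128, 128)
  m2[100:125, 100:125] <- TRUE   # > 64 px away from m
  expect_equal(d_iou(m, m2), 0)
  # 8 px shift of a realistic (phantom) mask: coarse D-IoU is more tolerant
  # of the misalignment than plain per-pixel IoU
  am <- phantom256()$amyloid_mask
  ams <- matrix(FALSE, 256, 256)
  ams[9:256, 9:256] <- am[1:248, 1:248]
  plain_iou <- sum(am & ams) / sum(am | ams)
  expect_gt(d_iou(am, ams), plain_iou)
  # empty vs empty: perfect agreement on absence
  e <- matrix(FALSE, 64, 64)
  expect_equal(d_iou(e, e), 1)
  # matches the naive loop oracle on random masks (factor 4, 16x16)
  set.seed(5)
  for (i in 1:50) {
    a <- matrix(runif(256) > 0.6, 16, 16)
    b <- matrix(runif(256) > 0.6, 16, 16)
    expect_equal(d_iou(a, b, factor = 4L), oracle_d_iou(a, b, factor = 4),
                 tolerance = 1e-6)
  }
})

test_that("d_iou is monotone for nested mask families", {
  base <- matrix(FALSE, 128, 128)
  base[40:90, 40:90] <- TRUE
  prev <- -1
  for (r in c(10, 20, 35, 51)) {
    sub <- matrix(FALSE, 128, 128)
    sub[40:(39 + r), 40:(39 + r)] <- TRUE
    v <- d_iou(base, sub)
    expect_gte(v, prev)
    prev <- v
  }
  expect_equal(prev, 1)
})

test_that("color histograms normalize and detect equality", {
  s <- phantom256()
  h <- color_histograms(s$crosspol_gt)
  binw <- diff(h$mid[1:2])
  for (ch in c("Y", "Cb", "Cr")) {
    expect_equal(sum(h$density[h$channel == ch]) * binw, 1,
                 tolerance = 1e-6)
  }
  h2 <- color_histograms(s$crosspol_gt)
  expect_equal(max(abs(h$density - h2$density)), 0)
  # constant image: single occupied bin
  const <- array(0.5, dim = c(32, 32, 3))
  hc <- color_histograms(const)
  expect_equal(sum(hc$density[hc$channel == "Y"] > 0), 1L)
  # empty mask sentinel
  sent <- color_histograms(s$crosspol_gt, mask = matrix(FALSE, 256, 256))
  expect_s3_class(sent, "virtpol_empty_region")
  # masked histogram differs from whole-FOV
  hm <- color_histograms(s$crosspol_gt, mask = s$amyloid_mask)
  expect_false(isTRUE(all.equal(hm$density, h$density)))
})

test_that("count_nuclei recovers phantom ground truth", {
  s <- memo("ph_nuc10", generate_phantom(
    phantom_spec(image_size = 256, n_nuclei = 10, nucleus_radius_px = 5,
                 seed = 23)))
  expect_equal(s$nuclei_count, 10L)
  res <- count_nuclei(s$brightfield_gt)
  expect_equal(res$count, 10L)
  expect_equal(res$mean_area, pi * 25, tolerance = 0.1)
  blank <- count_nuclei(array(1, dim = c(64, 64, 3)))
  expect_equal(blank$count, 0L)
  expect_equal(blank$mean_area, 0)
})

test_that("simulate_angle_shift scales hue and preserves value", {
  # apple-green pixel block: 120 deg -> 72 deg
  hsv <- array(0, dim = c(64, 64, 3))
  hsv[20:44, 20:44, 1] <- 120 / 360
  hsv[20:44, 20:44, 2] <- 0.8
  hsv[20:44, 20:44, 3] <- 0.8
  img <- hsv_to_rgb(hsv)
  shifted <- simulate_angle_shift(img)
  out <- rgb_to_hsv(shifted)
  inner <- 25:40  # away from the morphology margin
  expect_equal(mean(out[inner, inner, 1]) * 360, 72, tolerance = 0.5)
  # value channel untouched
  expect_equal(out[, , 3], rgb_to_hsv(img)[, , 3], tolerance = 1e-9)
  # all-black image unchanged
  black <- array(0, dim = c(32, 32, 3))
  expect_identical(simulate_angle_shift(black), black)
  # on phantoms the yellow output leaves the green band
  s <- phantom256()
  m_after <- segment_birefringence(s$angleshift_gt)
  m_before <- segment_birefringence(s$crosspol_gt)
  expect_lt(sum(m_after), 0.01 * max(1, sum(m_before)))
})

test_that("evaluate_pair dispatches per modality", {
  s <- phantom_holdout()
  r1 <- evaluate_pair(s$brightfield_gt, s$brightfield_gt, "brightfield",
                      fov_id = "fov1")
  expect_equal(r1$mae, 0)
  expect_equal(r1$ms_ssim, 1, tolerance = 1e-9)
  expect_identical(r1$psnr_db, Inf)
  expect_equal(r1$nuclei_count_virtual, r1$nuclei_count_histochemical)
  r2 <- evaluate_pair(s$crosspol_gt, s$crosspol_gt, "crosspol")
  expect_equal(r2$d_iou, 1)
  expect_true(is.na(r2$nuclei_count_virtual))
  expect_error(evaluate_pair(s$crosspol_gt, s$crosspol_gt, "nope"))
})
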