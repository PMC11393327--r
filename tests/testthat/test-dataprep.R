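# Registration pipeline: warping, tiling, global projective and elastic
# registration, and the orchestrated dataset preparation.
#
# WSI sizes are scaled down (256-600 px, tiles 128-256) so the full suite
# stays within its CPU budget; the operations are size-agnostic.

test_that("warp_image: zero field identity, integer shift, round trip", {
  s <- phantom256()
  img <- s$brightfield_gt
  zero <- array(0, dim = c(256, 256, 2))
  expect_equal(warp_image(img, zero), img, tolerance = 1e-12)
  # constant dx = 3: shift with border replication, against an array oracle
  f <- zero; f[, , 1] <- 3
  shifted <- warp_image(img, f)
  oracle <- img[, c(4:256, 256, 256, 256), ]
  expect_equal(shifted, oracle, tolerance = 1e-12)
  # round trip with a small smooth field, interior crop
  d <- apply_synthetic_deformation(s, amplitude_px = 2, seed = 9)
  round_trip <- warp_image(warp_image(img, d$field), -d$field)
  interior <- 17:240
  expect_lt(mae(round_trip[interior, interior, ], img[interior, interior, ]),
            0.02)
  expect_error(warp_image(img, zero[1:100, 1:100, ]), "share")
})

test_that("tile_pairs: grid partition, remainder dropping, validation", {
  wsi <- array(runif(512 * 512 * 3), dim = c(512, 512, 3))
  stk <- array(runif(512 * 512 * 4), dim = c(512, 512, 4))
  tp <- tile_pairs(wsi, stk, 256L, "crosspol")
  expect_length(tp, 4L)
  expect_equal(tp[[4]]$tile_origin, c(256L, 256L))
  expect_equal(vapply(tp, function(p) p$modality, ""), rep("crosspol", 4))
  # reassembly is a lossless partition
  rec <- array(0, dim = c(512, 512, 3))
  for (p in tp) {
    rec[p$tile_origin[1] + 1:256, p$tile_origin[2] + 1:256, ] <- p$target
  }
  expect_identical(rec, wsi)
  # 600^2 with tile 256 -> remainder dropped, still 4 tiles
  wsi2 <- array(runif(600 * 600 * 3), dim = c(600, 600, 3))
  stk2 <- array(runif(600 * 600 * 4), dim = c(600, 600, 4))
  expect_length(tile_pairs(wsi2, stk2, 256L), 4L)
  expect_error(tile_pairs(wsi, stk, 1024L), "exceeds")
})

test_that("global_register recovers identity and known translation", {
  s <- phantom256()
  img <- s$brightfield_gt
  tr <- global_register(img, img)
  corners <- cbind(c(0, 255, 0, 255), c(0, 0, 255, 255))
  ns <- asNamespace("virtpol")
  proj <- ns$apply_homography(tr$matrix, corners)
  expect_lt(max(abs(proj - corners)), 0.5)
  # translation by (dx = 10, dy = -7)
  f <- array(0, dim = c(256, 256, 2))
  f[, , 1] <- 10; f[, , 2] <- -7
  moved <- warp_image(img, f)   # content moves by (-10, +7); mapping
  tr2 <- global_register(moved, img)
  proj2 <- ns$apply_homography(tr2$matrix, corners)
  shift <- proj2 - corners
  expect_lt(max(abs(shift[, 1] - 10)), 1)
  expect_lt(max(abs(shift[, 2] + 7)), 1)
})

test_that("global_register fails cleanly on structureless images", {
  set.seed(77)
  n1 <- matrix(runif(256 * 256), 256, 256)
  n2 <- matrix(runif(256 * 256), 256, 256)
  expect_error(global_register(n1, n2), "registration failure")
  expect_error(global_register(matrix(0.5, 100, 100), matrix(0.5, 100, 100)),
               "128")
})

test_that("elastic_register: identity, recovery, MAE reduction, flat error", {
  s <- phantom256()
  img <- s$brightfield_gt
  f0 <- elastic_register(img, img)
  expect_lt(mean(sqrt(f0[, , 1]^2 + f0[, , 2]^2)), 0.25)
  # known smooth 4 px deformation: compare with the inverse of the applied
  # field (elastic_register maps moving -> fixed)
  d <- apply_synthetic_deformation(s, amplitude_px = 4, seed = 7)
  f <- elastic_register(d$sample$brightfield_gt, img)
  epe <- sqrt((f[, , 1] + d$field[, , 1])^2 + (f[, , 2] + d$field[, , 2])^2)
  expect_lt(mean(epe), 1)
  mae_before <- mae(d$sample$brightfield_gt, img)
  mae_after <- mae(warp_image(d$sample$brightfield_gt, f), img)
  expect_lt(mae_after, 0.5 * mae_before)
  expect_error(elastic_register(matrix(0.5, 256, 256), matrix(0.5, 256, 256)),
               "zero variance")
})

test_that("elastic_register guard never worsens aligned pairs", {
  s <- phantom256()
  a <- s$brightfield_gt
  b <- s$crosspol_gt  # very different images: guard may trigger
  f <- suppressWarnings(elastic_register(a, b))
  ga <- asNamespace("virtpol")$to_gray_any(a)
  gb <- asNamespace("virtpol")$to_gray_any(b)
  expect_lte(mean(abs(asNamespace("virtpol")$to_gray_any(warp_image(a, f)) - gb)),
             1.01 * mean(abs(ga - gb)))
})

test_that("prepare_registered_dataset aligns deformed phantom pairs", {
  s1 <- phantom256()
  s2 <- memo("ph256_s2", generate_phantom(phantom_spec(seed = 31)))
  # already aligned: residual below threshold in round 1
  out0 <- prepare_registered_dataset(list(s1$stack), list(s1$brightfield_gt),
                                     tile_size = 128L, global = FALSE,
                                     max_rounds = 4L)
  expect_lt(attr(out0, "residuals")[1], 0.5)
  expect_length(attr(out0, "residuals"), 1L)  # early exit after round 1
  # 4 px synthetic deformation: residuals shrink and tiles align
  d <- apply_synthetic_deformation(s2, amplitude_px = 4, seed = 13)
  out <- prepare_registered_dataset(list(s2$stack),
                                    list(d$sample$brightfield_gt),
                                    tile_size = 128L, global = FALSE,
                                    max_rounds = 2L)
  res <- attr(out, "residuals")
  mae_before <- mae(d$sample$brightfield_gt, s2$brightfield_gt)
  rec <- array(0, dim = dim(s2$brightfield_gt))
  for (p in out) {
    rec[p$tile_origin[1] + 1:128, p$tile_origin[2] + 1:128, ] <- p$target
  }
  expect_lt(mae(rec, s2$brightfield_gt), mae_before)
  # every tile satisfies the shape invariants
  for (p in out) {
    expect_equal(dim(p$stack)[1:2], c(128L, 128L))
    expect_equal(dim(p$target), c(128L, 128L, 3L))
  }
  # residuals non-increasing over rounds
  if (length(res) > 1) expect_lte(res[2], res[1] + 0.05)
})
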