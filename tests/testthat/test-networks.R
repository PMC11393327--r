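# Network construction and forward contracts.

test_that("make_dsm produces the three constant conditioning matrices", {
  expect_true(all(make_dsm(8, 8, "brightfield") == 1))
  expect_true(all(make_dsm(8, 8, "crosspol") == -1))
  expect_true(all(make_dsm(8, 8, "angleshift") == 2))
  expect_equal(dim(make_dsm(4, 6, "brightfield")), c(4L, 6L))
  expect_error(make_dsm(8, 8, "h&e"), "unknown modality")
})

test_that("network_config validates", {
  expect_error(network_config(base_width = 2), ">= 4")
  expect_error(network_config(in_channels = 0), ">= 1")
})

test_that("generator maps (H, W, in+1) to (H, W, 3) and checks divisibility", {
  nc <- network_config(base_width = 4L)
  gen <- build_generator(nc, seed = 1)
  s <- phantom256()
  out <- generator_forward(gen, s$stack, make_dsm(256, 256, "brightfield"))
  expect_equal(dim(out), c(256L, 256L, 3L))
  expect_true(all(is.finite(out)))
  expect_error(generator_forward(gen, s$stack[1:100, 1:100, ],
                                 make_dsm(100, 100, "brightfield")),
               "divisible by 16")
  expect_error(generator_forward(gen, s$stack[1:64, 1:64, 1:3],
                                 make_dsm(64, 64, "brightfield")),
               "channels")
})

test_that("encoder channel progression doubles from base_width", {
  P <- build_generator(network_config(base_width = 64L), seed = 1)$params
  getc <- function(nm) dim(P[[nm]])[4]
  expect_equal(vapply(paste0("e", 1:4, ".c1.w"), getc, 0L,
                      USE.NAMES = FALSE), c(64L, 128L, 256L, 512L))
  # head reduces to 3 channels
  expect_equal(dim(P[["out.w"]])[4], 3L)
  # parameter count grows ~quadratically with width
  n64 <- sum(vapply(P, length, 0))
  n8 <- sum(vapply(build_generator(network_config(base_width = 8L),
                                   seed = 1)$params, length, 0))
  expect_gt(n64 / n8, 30)
})

test_that("DSM conditioning reaches the generator output", {
  nc <- network_config(base_width = 4L)
  gen <- build_generator(nc, seed = 4)
  set.seed(2)
  stack <- array(runif(32 * 32 * 4), dim = c(32, 32, 4))
  o1 <- generator_forward(gen, stack, make_dsm(32, 32, "brightfield"))
  o2 <- generator_forward(gen, stack, make_dsm(32, 32, "crosspol"))
  expect_gt(mean(abs(o1 - o2)), 0)
})

test_that("discriminator outputs a probability on flexible input sizes", {
  nc <- network_config(base_width = 4L, condition_dsm = FALSE)
  disc <- build_discriminator(nc, seed = 1)
  set.seed(6)
  for (n in c(32L, 64L, 96L)) {
    img <- array(runif(n * n * 3), dim = c(n, n, 3))
    p <- discriminator_forward(disc, img)
    expect_gt(p, 0); expect_lt(p, 1)
  }
  # five stride-2 blocks: 256 -> 8 spatial, channels 32x base
  ns <- asNamespace("virtpol")
  tape <- ns$new_tape()
  ps <- ns$wrap_params(tape, disc$params)
  img <- array(runif(256 * 256 * 3), dim = c(256, 256, 3))
  x <- ns$nd_leaky_relu(tape, ns$conv_g(tape, ps, "c0",
                                        ns$nd_const(tape, img)), 0.1)
  for (i in 1:5) {
    h <- ns$nd_leaky_relu(tape, ns$conv_g(tape, ps, paste0("b", i, ".c1"), x),
                          0.1)
    h <- ns$conv_g(tape, ps, paste0("b", i, ".c2"), h, stride = 2L)
    r <- ns$conv_g(tape, ps, paste0("b", i, ".rp"), x, stride = 2L)
    x <- ns$nd_leaky_relu(tape, ns$nd_add(tape, h, r), 0.1)
  }
  expect_equal(dim(x$value), c(8L, 8L, 4L * 32L))
  # conditioned variant requires the DSM
  disc_c <- build_discriminator(network_config(base_width = 4L), seed = 1)
  expect_error(discriminator_forward(disc_c, img[1:32, 1:32, ]),
               "DSM-conditioned")
})

test_that("registration module: shape, zero-init identity, finiteness", {
  nc <- network_config(base_width = 4L)
  reg <- build_registration_module(nc, seed = 1)
  set.seed(8)
  m <- array(runif(128 * 128 * 3), dim = c(128, 128, 3))
  f <- array(runif(128 * 128 * 3), dim = c(128, 128, 3))
  field <- registration_forward(reg, m, f)
  expect_equal(dim(field), c(128L, 128L, 2L))
  expect_true(all(is.finite(field)))
  # zero-initialized head -> zero field -> warp is the identity at step 0
  expect_equal(max(abs(field)), 0)
  expect_equal(warp_image(m, field), m, tolerance = 1e-12)
  expect_error(registration_forward(reg, m[1:64, 1:64, ], f[1:64, 1:64, ]),
               "divisible")
})

test_that("builds are deterministic under a fixed seed", {
  nc <- network_config(base_width = 4L)
  g1 <- build_generator(nc, seed = 11)
  g2 <- build_generator(nc, seed = 11)
  expect_identical(g1$params, g2$params)
  expect_false(identical(g1$params,
                         build_generator(nc, seed = 12)$params))
  set.seed(1)
  stack <- array(runif(32 * 32 * 4), dim = c(32, 32, 4))
  dsm <- make_dsm(32, 32, "crosspol")
  expect_identical(generator_forward(g1, stack, dsm),
                   generator_forward(g2, stack, dsm))
})

test_that("a small generator forward pass on 128x128 is CPU-fast", {
  gen <- build_generator(network_config(base_width = 8L), seed = 1)
  set.seed(3)
  stack <- array(runif(128 * 128 * 4), dim = c(128, 128, 4))
  el <- system.time(
    generator_forward(gen, stack, make_dsm(128, 128, "brightfield")))[3]
  expect_lt(el, 5)  # spec target: ~1 s; generous CI margin
})
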