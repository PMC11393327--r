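# Loss functions: hand-derived values, analytic properties, oracle checks.

test_that("smooth_l1 matches the two-branch definition", {
  a <- matrix(0, 4, 4)
  expect_equal(smooth_l1(a, a), 0)
  # |d| >= phi branch: d = 2, phi = 1 -> |d| - phi/2 = 1.5
  expect_equal(smooth_l1(a + 2, a, phi = 1), 1.5)
  # quadratic branch: d = 0.5, phi = 1 -> 0.5 * 0.25 / 1 = 0.125
  expect_equal(smooth_l1(a + 0.5, a, phi = 1), 0.125)
  # continuity at |d| = phi: both branches give phi/2
  phi <- 0.7
  eps <- 1e-9
  expect_equal(smooth_l1(a + phi - eps, a, phi), smooth_l1(a + phi, a, phi),
               tolerance = 1e-6)
  expect_equal(smooth_l1(a + phi, a, phi), 0.5 * phi)
  expect_error(smooth_l1(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(smooth_l1(a, a, phi = 0), "positive")
})

test_that("bce matches the closed form and clamps", {
  expect_equal(bce(1, 1), 0, tolerance = 1e-6)
  expect_equal(bce(0.5, 0), log(2))
  expect_equal(bce(0.5, 1), log(2))
  expect_equal(bce(0, 1), -log(1e-7))
  expect_true(is.finite(bce(0, 1)) && is.finite(bce(1, 0)))
})

test_that("total variation: constant, hand case, checkerboard closed form", {
  expect_equal(total_variation(matrix(0.3, 5, 5)), 0)
  expect_equal(total_variation(matrix(c(0, 0, 1, 1), 2, 2)), 2)
  for (n in c(4L, 7L)) {
    cb <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2)
    expect_equal(total_variation(cb), 2 * n * (n - 1))
  }
})

test_that("smoothness penalty: zero, ramp, homogeneity", {
  f0 <- array(2.5, dim = c(6, 6, 2))
  expect_equal(smoothness(f0), 0)
  ramp <- array(0, dim = c(6, 6, 2))
  ramp[, , 1] <- matrix(rep(1:6, each = 6), 6, 6)  # unit slope along cols
  expect_equal(smoothness(ramp), oracle_smoothness(ramp))
  set.seed(11)
  f <- array(rnorm(72), dim = c(6, 6, 2))
  expect_equal(smoothness(3 * f), 9 * smoothness(f))
})

test_that("discriminator loss: perfect, uninformative, non-negative", {
  expect_equal(discriminator_loss(0, 1), 0, tolerance = 1e-6)
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2))
  set.seed(3)
  for (i in 1:20) {
    expect_gte(discriminator_loss(runif(1), runif(1)), 0)
  }
})

test_that("losses match brute-force loop oracles on random 8x8 inputs", {
  set.seed(42)
  for (i in 1:50) {
    A <- rand_img(); B <- rand_img()
    phi <- runif(1, 0.2, 1.5)
    expect_equal(smooth_l1(A, B, phi), oracle_smooth_l1(A, B, phi),
                 tolerance = 1e-6)
    expect_equal(total_variation(A), oracle_tv(A), tolerance = 1e-6)
    f <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
    expect_equal(smoothness(f), oracle_smoothness(f), tolerance = 1e-6)
    p <- runif(1)
    lb <- rbinom(1, 1, 0.5)
    expect_equal(bce(p, lb), oracle_bce(p, lb), tolerance = 1e-6)
  }
})

test_that("generator loss composes its three terms with (10, 1, 1e-4)", {
  w <- loss_weights()
  expect_equal(c(w$alpha, w$beta, w$gamma), c(10, 1, 1e-4))
  expect_equal(c(w$lam, w$mu, w$phi), c(20, 10, 1))
  nc <- network_config(base_width = 4L)
  gen <- build_generator(nc, seed = 2)
  disc <- build_discriminator(nc, seed = 2)
  set.seed(7)
  stack <- array(runif(32 * 32 * 4), dim = c(32, 32, 4))
  target <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  dsm <- make_dsm(32, 32, "crosspol")
  comp <- generator_loss(stack, dsm, target, gen, disc, weights = w)
  expect_equal(comp$total,
               w$alpha * comp$l1 + w$beta * comp$adv + w$gamma * comp$tv,
               tolerance = 1e-10)
  expect_gte(comp$l1, 0)
  expect_gte(comp$tv, 0)
})

test_that("registration loss is zero for identical images at zero-init", {
  nc <- network_config(base_width = 4L)
  reg <- build_registration_module(nc, seed = 1)
  set.seed(8)
  img <- array(runif(128 * 128 * 3), dim = c(128, 128, 3))
  # fresh module has a zero-initialized field head -> identity warp
  out <- registration_loss(img, img, reg)
  expect_equal(out$total, 0)
  expect_equal(max(abs(out$field)), 0)
  # constant image: warp leaves it unchanged, so only smoothness remains
  const <- array(0.4, dim = c(128, 128, 3))
  out2 <- registration_loss(const, const, reg)
  expect_equal(out2$total, loss_weights()$mu * out2$smth)
})
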