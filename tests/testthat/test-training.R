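# Training loop mechanics (full-scale learning behaviour is exercised in
# test-acceptance.R; here the contracts are checked at minimal scale).

tiny_pairs <- function() {
  memo("tiny_pairs", phantom_dataset(
    2, phantom_spec(image_size = 64, n_nuclei = 4),
    modalities = c("brightfield", "crosspol"), seed = 300))
}

tiny_cfg <- function(steps = 6L, seed = 1L) {
  train_config(lr_generator = 1e-3, lr_discriminator = 1e-4,
               batch_size = 2L, crop_size = 32L, max_steps = steps,
               seed = seed, modalities = c("brightfield", "crosspol"),
               use_registration = FALSE)
}

test_that("the 4:1:1 update schedule yields G:40 D:10 R:10 over 60 ticks", {
  pat <- asNamespace("virtpol")$tick_pattern(c(4L, 1L, 1L))
  ticks <- rep(pat, length.out = 60)
  expect_equal(sum(ticks == "G"), 40L)
  expect_equal(sum(ticks == "D"), 10L)
  expect_equal(sum(ticks == "R"), 10L)
})

test_that("train_config validates and records the defaults", {
  cfg <- train_config()
  expect_equal(cfg$lr_generator, 2e-5)
  expect_equal(cfg$lr_discriminator, 2e-6)
  expect_equal(cfg$lr_registration, 2e-6)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$crop_size, 256L)
  expect_equal(cfg$update_ratio, c(4L, 1L, 1L))
  expect_error(train_config(update_ratio = c(0, 1, 1)), "positive")
  expect_error(train_config(modalities = "h&e"))
})

test_that("train rejects datasets missing a configured modality", {
  pairs <- tiny_pairs()
  bf_only <- Filter(function(p) p$modality == "brightfield", pairs)
  expect_error(train(bf_only, network_config(base_width = 4L), tiny_cfg()),
               "missing configured modalities")
  expect_error(train(pairs, network_config(base_width = 4L),
                     train_config(crop_size = 24L,
                                  use_registration = FALSE)),
               "divisible")
})

test_that("a short run produces history and a usable checkpoint", {
  ck <- memo("tiny_ck",
             train(tiny_pairs(), network_config(base_width = 4L),
                   tiny_cfg(steps = 6L)))
  expect_s3_class(ck, "virtpol_checkpoint")
  expect_equal(nrow(ck$history), 6L)
  expect_equal(ck$step, 6L)
  expect_setequal(unique(ck$history$module), c("G", "D"))
  expect_true(all(is.finite(ck$history$total)))
  # checkpoint save/load round trip
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  expect_identical(ck2$generator$params, ck$generator$params)
  # versioned rejection
  bad <- unclass(ck)
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "incompatible")
})

test_that("training is bit-reproducible under a fixed seed", {
  c1 <- train(tiny_pairs(), network_config(base_width = 4L),
              tiny_cfg(steps = 6L, seed = 42L))
  c2 <- train(tiny_pairs(), network_config(base_width = 4L),
              tiny_cfg(steps = 6L, seed = 42L))
  expect_identical(c1$generator$params, c2$generator$params)
  expect_identical(c1$discriminator$params, c2$discriminator$params)
  expect_identical(c1$history, c2$history)
  c3 <- train(tiny_pairs(), network_config(base_width = 4L),
              tiny_cfg(steps = 6L, seed = 43L))
  expect_false(identical(c1$generator$params, c3$generator$params))
})

test_that("fine_tune resumes from a checkpoint and extends the history", {
  ck <- memo("tiny_ck",
             train(tiny_pairs(), network_config(base_width = 4L),
                   tiny_cfg(steps = 6L)))
  ck2 <- fine_tune(ck, tiny_pairs(), tiny_cfg(steps = 4L, seed = 9L))
  expect_equal(ck2$step, 10L)
  expect_equal(nrow(ck2$history), 4L)
  expect_false(identical(ck2$generator$params, ck$generator$params))
  # incompatible checkpoint is rejected
  other <- ck
  other$net_config$base_width <- 16L
  expect_error(fine_tune(other, tiny_pairs(), tiny_cfg(steps = 2L)),
               "does not match")
})

test_that("train_registration reduces the alignment loss", {
  s <- memo("ph128_reg", generate_phantom(
    phantom_spec(image_size = 128, seed = 61)))
  d <- apply_synthetic_deformation(s, amplitude_px = 3, seed = 3)
  pairs <- list(list(moving = s$brightfield_gt,
                     fixed = d$sample$brightfield_gt))
  out <- train_registration(pairs, network_config(base_width = 4L),
                            steps = 40L, lr = 2e-3, seed = 2L)
  expect_length(out$history, 40L)
  expect_lt(mean(tail(out$history, 5)), mean(head(out$history, 5)))
})
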