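# Shared fixtures: phantom samples and (expensive) trained models are built
# once per test run and memoised here.  Desk-scale hyperparameters for the
# toy instantiations (base_width 8, 64 px crops, learning rates 2e-3 / 1e-4)
# are fixed up front; see the methods vignette.

.virtpol_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .virtpol_cache)) {
    assign(key, force(expr), envir = .virtpol_cache)
  }
  get(key, envir = .virtpol_cache)
}

toy_net_cfg <- function(base_width = 8L) network_config(base_width = base_width)

phantom256 <- function(seed = 1L) {
  memo(paste0("ph256_", seed), generate_phantom(phantom_spec(seed = seed)))
}

# held-out phantom large enough for 6-scale MS-SSIM (>= 352 px)
phantom_holdout <- function(seed = 999L) {
  memo(paste0("ph384_", seed),
       generate_phantom(phantom_spec(image_size = 384L, seed = seed)))
}

train_pairs_3mod <- function() {
  memo("pairs3", phantom_dataset(
    6, phantom_spec(image_size = 256),
    modalities = c("brightfield", "crosspol", "angleshift"), seed = 100))
}

# The shared desk-scale model behind acceptance criteria 4, 5, 6 and the
# noise-transfer comparison: one generator, three modalities.
trained_clean_model <- function() {
  memo("clean_model", {
    cfg <- train_config(lr_generator = 2e-3, lr_discriminator = 5e-4,
                        batch_size = 8L, crop_size = 64L,
                        max_steps = 600L, seed = 5L,
                        modalities = c("brightfield", "crosspol",
                                       "angleshift"),
                        use_registration = FALSE)
    train(train_pairs_3mod(), toy_net_cfg(), cfg)
  })
}

# circular mean hue (degrees helper) over a mask
mean_hue_deg <- function(img, mask) {
  hsv <- rgb_to_hsv(img)
  360 * virtpol_circ_mean(hsv[, , 1][mask])
}

virtpol_circ_mean <- function(h) {
  a <- 2 * pi * h
  (atan2(mean(sin(a)), mean(cos(a))) / (2 * pi)) %% 1
}

hue_dist_deg <- function(a_deg, b_deg) {
  d <- abs(a_deg - b_deg) %% 360
  min(d, 360 - d)
}
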