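# Adversarial training loop.
#
# One "tick" updates exactly one module.  The update ratio (4, 1, 1) expands
# to the repeating tick pattern G G G G D R: four generator updates, then one
# discriminator and one registration update, each with its own Adam
# optimizer (betas 0.9/0.999, constant learning rates 2e-5 / 2e-6 / 2e-6 by
# default).  Batches are random 256x256 crops (configurable) with the
# modality drawn uniformly over the configured modalities; each sample's DSM
# always matches its target's modality.  All randomness flows from
# `train_config$seed`, so runs are bit-reproducible on a single CPU thread.

#' Training configuration
#'
#' @param lr_generator,lr_discriminator,lr_registration Adam learning rates.
#' @param batch_size Samples per update.
#' @param crop_size Square crop side in pixels.  Must be divisible by 16, and
#'   by `2^registration_levels` when the registration module is active.
#' @param update_ratio Integer triplet: generator, discriminator and
#'   registration updates per schedule cycle.
#' @param max_steps Total scheduler ticks.
#' @param seed Master seed.
#' @param modalities Character subset of
#'   `c("brightfield", "crosspol", "angleshift")`.
#' @param use_registration Co-train the displacement-field module (disable
#'   for perfectly aligned data).
#' @param standardize Z-score the stack channels with training-set statistics
#'   (frozen into the checkpoint).
#' @return List of class `train_config`.
#' @export
train_config <- function(lr_generator = 2e-5, lr_discriminator = 2e-6,
                         lr_registration = 2e-6, batch_size = 32L,
                         crop_size = 256L, update_ratio = c(4L, 1L, 1L),
                         max_steps = 1000L, seed = 1L,
                         modalities = c("brightfield", "crosspol"),
                         use_registration = TRUE, standardize = TRUE) {
  if (any(update_ratio < 1L) || any(update_ratio != as.integer(update_ratio)))
    stop("update_ratio must be positive integers")
  modalities <- match.arg(modalities,
                          c("brightfield", "crosspol", "angleshift"),
                          several.ok = TRUE)
  structure(list(lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 lr_registration = lr_registration,
                 batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size),
                 update_ratio = as.integer(update_ratio),
                 max_steps = as.integer(max_steps),
                 seed = as.integer(seed),
                 modalities = modalities,
                 use_registration = isTRUE(use_registration),
                 standardize = isTRUE(standardize)),
            class = "train_config")
}

# expand the ratio into the per-cycle tick pattern
tick_pattern <- function(update_ratio) {
  rep(c("G", "D", "R"), times = update_ratio)
}

# --- Adam -------------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

node_grads <- function(ps, scale = 1) {
  lapply(ps, function(n) if (is.null(n$grad)) NULL else n$grad * scale)
}

# --- batching ---------------------------------------------------------------

normalize_stack <- function(stack, stats) {
  if (is.null(stats)) return(stack)
  d <- dim(stack)
  for (c in seq_len(d[3])) {
    stack[, , c] <- (stack[, , c] - stats$mean[c]) / stats$sd[c]
  }
  stack
}

stack_norm_stats <- function(dataset) {
  C <- dim(as_image3(dataset[[1]]$stack))[3]
  m <- numeric(C); s <- numeric(C)
  for (c in seq_len(C)) {
    v <- unlist(lapply(dataset, function(p) as.vector(as_image3(p$stack)[, , c])))
    m[c] <- mean(v)
    s[c] <- max(stats::sd(v), 1e-6)
  }
  list(mean = m, sd = s)
}

sample_crop <- function(pair, crop, stats) {
  st <- as_image3(pair$stack)
  tg <- as_image3(pair$target)
  d <- dim(st)
  if (d[1] < crop || d[2] < crop)
    stop(sprintf("tile %dx%d smaller than crop size %d", d[1], d[2], crop))
  for (try in 1:20) {
    r0 <- sample.int(d[1] - crop + 1L, 1L)
    c0 <- sample.int(d[2] - crop + 1L, 1L)
    tgc <- tg[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L), , drop = FALSE]
    if (stats::var(as.vector(tgc)) >= 1e-4 || try == 20L) {
      stc <- st[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L), , drop = FALSE]
      return(list(stack = normalize_stack(stc, stats), target = tgc,
                  modality = pair$modality))
    }
  }
}

draw_batch <- function(by_modality, cfg, stats) {
  lapply(seq_len(cfg$batch_size), function(i) {
    mod <- cfg$modalities[sample.int(length(cfg$modalities), 1L)]
    pool <- by_modality[[mod]]
    sample_crop(pool[[sample.int(length(pool), 1L)]], cfg$crop_size, stats)
  })
}

# --- per-tick updates -------------------------------------------------------

g_tick <- function(batch, nets, weights, cfg) {
  tape <- new_tape()
  ps_gen <- wrap_params(tape, nets$gen$params)
  ps_disc <- wrap_params(tape, nets$disc$params)
  ps_reg <- if (cfg$use_registration) wrap_params(tape, nets$reg$params)
  comps <- list(total = 0, l1 = 0, adv = 0, tv = 0)
  loss_nodes <- vector("list", length(batch))
  for (i in seq_along(batch)) {
    b <- batch[[i]]
    dsm <- make_dsm(cfg$crop_size, cfg$crop_size, b$modality)
    g <- gan_graph(b$stack, dsm, b$target, nets$gen, nets$disc,
                   if (cfg$use_registration) nets$reg else NULL,
                   weights, tape = tape, ps_gen = ps_gen,
                   ps_disc = ps_disc, ps_reg = ps_reg)
    loss_nodes[[i]] <- g$loss
    for (k in names(comps)) comps[[k]] <- comps[[k]] + g$components[[k]]
  }
  n <- length(batch)
  total <- nd_sum_scalars(tape, loss_nodes, rep(1 / n, n))
  if (!is.finite(total$value))
    stop("generator loss diverged (non-finite); aborting training")
  backward(tape, total)
  upd <- adam_step(nets$gen$params, node_grads(ps_gen), nets$opt_g,
                   cfg$lr_generator)
  nets$gen$params <- upd$params
  nets$opt_g <- upd$state
  nets$last <- lapply(comps, function(v) v / n)
  nets
}

fake_image <- function(nets, b, cfg) {
  gen <- nets$gen
  dsm <- make_dsm(cfg$crop_size, cfg$crop_size, b$modality)
  list(img = generator_forward(gen, b$stack, dsm), dsm = dsm)
}

with_dsm_channel <- function(img, dsm, cond) {
  if (!cond) return(img)
  array(c(img, dsm), dim = dim(img) + c(0L, 0L, 1L))
}

d_tick <- function(batch, nets, cfg) {
  tape <- new_tape()
  ps_disc <- wrap_params(tape, nets$disc$params)
  cond <- nets$disc$config$condition_dsm
  loss_nodes <- list()
  pr <- pf <- 0
  for (b in batch) {
    f <- fake_image(nets, b, cfg)
    fake <- with_dsm_channel(f$img, f$dsm, cond)
    real <- with_dsm_channel(as_image3(b$target), f$dsm, cond)
    p_fake <- discriminator_forward_graph(tape, ps_disc, nets$disc$config,
                                          nd_const(tape, fake))
    p_real <- discriminator_forward_graph(tape, ps_disc, nets$disc$config,
                                          nd_const(tape, real))
    loss_nodes <- c(loss_nodes, list(nd_bce(tape, p_fake, 0),
                                     nd_bce(tape, p_real, 1)))
    pf <- pf + p_fake$value
    pr <- pr + p_real$value
  }
  n <- length(batch)
  total <- nd_sum_scalars(tape, loss_nodes, rep(1 / n, 2L * n))
  backward(tape, total)
  upd <- adam_step(nets$disc$params, node_grads(ps_disc), nets$opt_d,
                   cfg$lr_discriminator)
  nets$disc$params <- upd$params
  nets$opt_d <- upd$state
  nets$last_d <- list(loss = total$value, p_real = pr / n, p_fake = pf / n)
  nets
}

r_tick <- function(batch, nets, weights, cfg) {
  tape <- new_tape()
  ps_reg <- wrap_params(tape, nets$reg$params)
  loss_nodes <- list()
  for (b in batch) {
    f <- fake_image(nets, b, cfg)
    gout <- nd_const(tape, f$img)
    tnode <- nd_const(tape, as_image3(b$target))
    field <- registration_forward_graph(tape, ps_reg, nets$reg$config,
                                        gout, tnode)
    warped <- nd_grid_sample(tape, gout, field)
    l1 <- nd_smooth_l1(tape, warped, tnode, weights$phi)
    sm <- nd_smoothness(tape, field)
    loss_nodes <- c(loss_nodes,
                    list(nd_sum_scalars(tape, list(l1, sm),
                                        c(weights$lam, weights$mu))))
  }
  n <- length(batch)
  total <- nd_sum_scalars(tape, loss_nodes, rep(1 / n, n))
  backward(tape, total)
  upd <- adam_step(nets$reg$params, node_grads(ps_reg), nets$opt_r,
                   cfg$lr_registration)
  nets$reg$params <- upd$params
  nets$opt_r <- upd$state
  nets$last_r <- list(loss = total$value)
  nets
}

# --- public API -------------------------------------------------------------

#' Train the virtual-staining model
#'
#' @param dataset List of tile pairs, each a list with `stack` (H, W, Cin),
#'   `target` (H, W, 3) and `modality`.  Every configured modality must be
#'   present.
#' @param net_cfg [network_config()].
#' @param cfg [train_config()].
#' @param weights [loss_weights()].
#' @param init Optional checkpoint to resume from (used by [fine_tune()]).
#' @param verbose Print progress every 25 ticks.
#' @return List of class `virtpol_checkpoint` with the three networks,
#'   configs, normalization statistics, final `step` and a `history` data
#'   frame of per-tick loss components.
#' @export
train <- function(dataset, net_cfg = network_config(),
                  cfg = train_config(), weights = loss_weights(),
                  init = NULL, verbose = FALSE) {
  mods_present <- unique(vapply(dataset, function(p) p$modality, ""))
  missing_m <- setdiff(cfg$modalities, mods_present)
  if (length(missing_m) > 0)
    stop("dataset is missing configured modalities: ",
         paste(missing_m, collapse = ", "))
  div <- 2L^net_cfg$generator_levels
  if (cfg$crop_size %% div != 0L)
    stop("crop_size must be divisible by ", div)
  if (cfg$use_registration &&
      cfg$crop_size %% (2L^net_cfg$registration_levels) != 0L)
    stop("crop_size must be divisible by 2^registration_levels when the ",
         "registration module is active")
  by_modality <- split(dataset, vapply(dataset, function(p) p$modality, ""))

  if (is.null(init)) {
    stats <- if (cfg$standardize) stack_norm_stats(dataset) else NULL
    nets <- list(gen = build_generator(net_cfg, seed = cfg$seed),
                 disc = build_discriminator(net_cfg, seed = cfg$seed),
                 reg = if (cfg$use_registration)
                   build_registration_module(net_cfg, seed = cfg$seed))
    step0 <- 0L
  } else {
    check_checkpoint(init, net_cfg)
    stats <- init$norm_stats
    nets <- list(gen = init$generator, disc = init$discriminator,
                 reg = init$registration %||%
                   if (cfg$use_registration)
                     build_registration_module(net_cfg, seed = cfg$seed))
    step0 <- init$step
  }
  nets$opt_g <- adam_new(nets$gen$params)
  nets$opt_d <- adam_new(nets$disc$params)
  if (cfg$use_registration) nets$opt_r <- adam_new(nets$reg$params)

  pattern <- tick_pattern(cfg$update_ratio)
  hist <- vector("list", cfg$max_steps)
  with_seed(split_seed(cfg$seed, "train"), {
    for (step in seq_len(cfg$max_steps)) {
      role <- pattern[((step - 1L) %% length(pattern)) + 1L]
      if (role == "R" && !cfg$use_registration) role <- "G"
      batch <- draw_batch(by_modality, cfg, stats)
      nets <- switch(role,
                     G = g_tick(batch, nets, weights, cfg),
                     D = d_tick(batch, nets, cfg),
                     R = r_tick(batch, nets, weights, cfg))
      hist[[step]] <- data.frame(
        step = step0 + step, module = role,
        total = if (role == "G") nets$last$total else
          if (role == "D") nets$last_d$loss else nets$last_r$loss,
        l1 = if (role == "G") nets$last$l1 else NA_real_,
        adv = if (role == "G") nets$last$adv else NA_real_,
        tv = if (role == "G") nets$last$tv else NA_real_,
        p_real = if (role == "D") nets$last_d$p_real else NA_real_,
        p_fake = if (role == "D") nets$last_d$p_fake else NA_real_)
      if (verbose && step %% 25L == 0L) {
        message(sprintf("tick %d/%d [%s] loss %.4f", step, cfg$max_steps,
                        role, hist[[step]]$total))
      }
    }
  })
  structure(list(version = 1L,
                 generator = nets$gen, discriminator = nets$disc,
                 registration = if (cfg$use_registration) nets$reg,
                 net_config = net_cfg, train_config = cfg,
                 norm_stats = stats, step = step0 + cfg$max_steps,
                 history = do.call(rbind, hist)),
            class = "virtpol_checkpoint")
}

check_checkpoint <- function(ckpt, net_cfg) {
  if (!inherits(ckpt, "virtpol_checkpoint"))
    stop("not a virtpol checkpoint")
  if ((ckpt$version %||% 0L) != 1L)
    stop("incompatible checkpoint version: ", ckpt$version %||% "none")
  # the stored networks must agree with the configuration they claim
  if (!identical(ckpt$generator$config$base_width, net_cfg$base_width) ||
      !identical(ckpt$generator$config$in_channels, net_cfg$in_channels))
    stop("checkpoint network configuration does not match")
  invisible(TRUE)
}

#' Fine-tune a trained model (transfer learning)
#'
#' Resumes the generator, discriminator and (if present) registration module
#' from a checkpoint and continues training on a new dataset — typically
#' noise-augmented stacks, to adapt a clean-trained model to low-SNR input.
#'
#' @param checkpoint A `virtpol_checkpoint` from [train()].
#' @param dataset New training pairs (same structure as for [train()]).
#' @param cfg [train_config()] for the fine-tuning phase.
#' @param weights [loss_weights()].
#' @param verbose Print progress.
#' @return Updated `virtpol_checkpoint`.
#' @export
fine_tune <- function(checkpoint, dataset, cfg, weights = loss_weights(),
                      verbose = FALSE) {
  train(dataset, net_cfg = checkpoint$net_config, cfg = cfg,
        weights = weights, init = checkpoint, verbose = verbose)
}

#' Train the registration module alone
#'
#' Optimizes only the displacement-field network on (moving, fixed) image
#' pairs with the registration objective
#' `lam * smooth_l1(fixed, warp(moving, field)) + mu * smoothness(field)`.
#' Used on its own to align misaligned pairs, and as the desk-scale probe
#' of the co-trained registration mechanism (in the full loop `moving` is
#' the generator output).
#'
#' @param pairs List of lists with `moving` and `fixed` (H, W, 3) images;
#'   sizes divisible by `2^registration_levels`.
#' @param net_cfg [network_config()].
#' @param steps Number of updates.
#' @param lr Adam learning rate.
#' @param batch_size Pairs per update.
#' @param seed Seed.
#' @param weights [loss_weights()].
#' @param verbose Print progress.
#' @return List with the trained `reg` network and `history` (per-step loss).
#' @export
train_registration <- function(pairs, net_cfg = network_config(),
                               steps = 300L, lr = 1e-3, batch_size = 1L,
                               seed = 1L, weights = loss_weights(),
                               verbose = FALSE) {
  reg <- build_registration_module(net_cfg, seed = seed)
  opt <- adam_new(reg$params)
  hist <- numeric(steps)
  with_seed(split_seed(seed, "trainreg"), {
    for (step in seq_len(steps)) {
      tape <- new_tape()
      ps <- wrap_params(tape, reg$params)
      loss_nodes <- vector("list", batch_size)
      # sample without replacement when the batch covers the set
      sel <- if (batch_size <= length(pairs)) {
        sample.int(length(pairs), batch_size)
      } else sample.int(length(pairs), batch_size, replace = TRUE)
      for (i in seq_len(batch_size)) {
        p <- pairs[[sel[i]]]
        mnode <- nd_const(tape, as_image3(p$moving))
        fnode <- nd_const(tape, as_image3(p$fixed))
        field <- registration_forward_graph(tape, ps, reg$config, mnode, fnode)
        warped <- nd_grid_sample(tape, mnode, field)
        l1 <- nd_smooth_l1(tape, warped, fnode, weights$phi)
        sm <- nd_smoothness(tape, field)
        loss_nodes[[i]] <- nd_sum_scalars(tape, list(l1, sm),
                                          c(weights$lam, weights$mu))
      }
      total <- nd_sum_scalars(tape, loss_nodes,
                              rep(1 / batch_size, batch_size))
      backward(tape, total)
      upd <- adam_step(reg$params, node_grads(ps), opt, lr)
      reg$params <- upd$params
      opt <- upd$state
      hist[step] <- total$value
      if (verbose && step %% 25L == 0L)
        message(sprintf("reg step %d/%d loss %.4f", step, steps, hist[step]))
    }
  })
  list(reg = reg, history = hist)
}

#' Save / load a checkpoint
#'
#' Checkpoints are versioned lists holding all three networks, both configs,
#' the frozen normalization statistics and the training step.
#'
#' @param ckpt A `virtpol_checkpoint`.
#' @param path File path.
#' @return `load_checkpoint` returns the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "virtpol_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "virtpol_checkpoint") ||
      !identical(ckpt$version %||% 0L, 1L))
    stop("incompatible or unversioned checkpoint file: ", path)
  ckpt
}
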