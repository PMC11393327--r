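# Network architectures.
#
# Three components trained jointly:
#  * generator  - attention U-Net: 4 down blocks (3-conv residual block +
#    leaky ReLU + 2x2/stride-2 max pool, doubling channels) and 4 up blocks
#    (bilinear 2x upsample of the decoder state concatenated with
#    attention-gated skip features, then a residual block reducing channels
#    4x), a residual head and a single conv to 3 channels.  The input is the
#    autofluorescence stack with the digital staining matrix (DSM)
#    concatenated as one extra constant channel.
#  * discriminator - single conv to base_width channels, five 2-conv residual
#    blocks (second conv stride 2, channels doubling), global average pool
#    and two dense layers to a sigmoid probability.
#  * registration module - U-Net with seven down/up pairs over the 6-channel
#    (moving, fixed) concatenation; bottleneck = channel-doubling conv, three
#    residual blocks, channel-halving conv; 1x1 output conv (zero-initialized
#    so training starts from the identity warp) producing the (dx, dy) field.
#
# Kernel sizes are 3x3 except residual paths, attention-gate convolutions and
# the field head (1x1).  No normalization layers.  Channel doubling in the
# registration module is capped at 8x base_width to keep CPU instantiations
# tractable (the deep levels carry little spatial content).

#' Network configuration
#'
#' @param in_channels Autofluorescence channels at the input (default 4:
#'   DAPI, FITC, TxRed, Cy5).
#' @param base_width Feature channels at the first level (default 64; reduce
#'   to 4-8 for desk-scale CPU runs).
#' @param generator_levels Down/upsampling pairs in the generator (4).
#' @param discriminator_blocks Residual blocks in the discriminator (5).
#' @param registration_levels Down/upsampling pairs in the registration
#'   module (7); inputs must be divisible by `2^registration_levels`.
#' @param leaky_slope Negative slope of all leaky ReLUs (0.1).
#' @param condition_dsm Concatenate the DSM to the discriminator input
#'   (default TRUE; the conditional-GAN reading).
#' @return A list of class `network_config`.
#' @export
network_config <- function(in_channels = 4L, base_width = 64L,
                           generator_levels = 4L, discriminator_blocks = 5L,
                           registration_levels = 7L, leaky_slope = 0.1,
                           condition_dsm = TRUE) {
  if (base_width < 4L) stop("base_width must be >= 4")
  if (in_channels < 1L) stop("in_channels must be >= 1")
  structure(list(in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 generator_levels = as.integer(generator_levels),
                 discriminator_blocks = as.integer(discriminator_blocks),
                 registration_levels = as.integer(registration_levels),
                 leaky_slope = leaky_slope,
                 condition_dsm = isTRUE(condition_dsm)),
            class = "network_config")
}

#' Digital staining matrix
#'
#' Constant-valued conditioning channel selecting the output modality:
#' 1 for brightfield, -1 for cross-polarized birefringence, 2 for the
#' angle-shifted birefringence channel.
#'
#' @param height,width Spatial size in pixels.
#' @param modality One of `"brightfield"`, `"crosspol"`, `"angleshift"`.
#' @return An (H, W) matrix with attribute `modality`.
#' @export
make_dsm <- function(height, width, modality) {
  v <- switch(modality,
              brightfield = 1, crosspol = -1, angleshift = 2,
              stop("unknown modality: ", modality))
  structure(matrix(v, height, width), modality = modality)
}

#' @export
dsm_value <- function(modality) {
  switch(modality, brightfield = 1, crosspol = -1, angleshift = 2,
         stop("unknown modality: ", modality))
}

# --- parameter helpers ------------------------------------------------------

p_conv <- function(P, name, kh, kw, cin, cout, zero = FALSE) {
  sd <- sqrt(2 / (kh * kw * cin))
  P[[paste0(name, ".w")]] <- if (zero) {
    array(0, dim = c(kh, kw, cin, cout))
  } else array(stats::rnorm(kh * kw * cin * cout, sd = sd),
               dim = c(kh, kw, cin, cout))
  P[[paste0(name, ".b")]] <- numeric(cout)
  P
}

p_dense <- function(P, name, cin, cout) {
  P[[paste0(name, ".w")]] <- matrix(stats::rnorm(cin * cout,
                                                 sd = sqrt(2 / cin)),
                                    cout, cin)
  P[[paste0(name, ".b")]] <- numeric(cout)
  P
}

p_res3 <- function(P, name, cin, cout) {
  P <- p_conv(P, paste0(name, ".c1"), 3, 3, cin, cout)
  P <- p_conv(P, paste0(name, ".c2"), 3, 3, cout, cout)
  P <- p_conv(P, paste0(name, ".c3"), 3, 3, cout, cout)
  p_conv(P, paste0(name, ".rp"), 1, 1, cin, cout)
}

p_att <- function(P, name, skip_ch, gate_ch) {
  inter <- max(1L, skip_ch %/% 2L)
  P <- p_conv(P, paste0(name, ".wg"), 1, 1, gate_ch, inter)
  P <- p_conv(P, paste0(name, ".ws"), 1, 1, skip_ch, inter)
  p_conv(P, paste0(name, ".psi"), 1, 1, inter, 1L)
}

wrap_params <- function(tape, params) {
  lapply(params, function(p) nd_const(tape, p))
}

conv_g <- function(tape, ps, name, x, stride = 1L) {
  w <- ps[[paste0(name, ".w")]]
  pad <- if (dim(w$value)[1] == 3) 1L else 0L
  nd_conv2d(tape, x, w, ps[[paste0(name, ".b")]], stride, pad)
}

res3_g <- function(tape, ps, name, x, slope) {
  h <- nd_leaky_relu(tape, conv_g(tape, ps, paste0(name, ".c1"), x), slope)
  h <- nd_leaky_relu(tape, conv_g(tape, ps, paste0(name, ".c2"), h), slope)
  h <- conv_g(tape, ps, paste0(name, ".c3"), h)
  r <- conv_g(tape, ps, paste0(name, ".rp"), x)
  nd_leaky_relu(tape, nd_add(tape, h, r), slope)
}

att_g <- function(tape, ps, name, skip, gate) {
  # gate is at half the skip resolution: upsample, project both to the
  # shared intermediate width, sum, ReLU, 1-channel conv, sigmoid
  gu <- nd_upsample2(tape, gate)
  a <- nd_add(tape, conv_g(tape, ps, paste0(name, ".wg"), gu),
              conv_g(tape, ps, paste0(name, ".ws"), skip))
  psi <- nd_sigmoid(tape, conv_g(tape, ps, paste0(name, ".psi"),
                                 nd_relu(tape, a)))
  nd_mul_map(tape, skip, psi)
}

# --- generator --------------------------------------------------------------

#' Build the DSM-conditioned attention U-Net generator
#'
#' @param config [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return List of class `virtpol_generator` with `config` and `params`.
#' @export
build_generator <- function(config = network_config(), seed = 1L) {
  w <- config$base_width
  cin <- config$in_channels + 1L  # + DSM channel
  with_seed(split_seed(seed, "generator"), {
    P <- list()
    ch <- c(w, 2L * w, 4L * w, 8L * w)
    prev <- cin
    for (i in 1:4) {
      P <- p_res3(P, paste0("e", i), prev, ch[i])
      prev <- ch[i]
    }
    gate_ch <- c(w, 2L * w, 4L * w, 8L * w)  # equals skip width at each level
    for (i in 4:1) P <- p_att(P, paste0("a", i), ch[i], gate_ch[i])
    dec_out <- c(max(2L, w %/% 2L), w, 2L * w, 4L * w)
    for (i in 4:1) P <- p_res3(P, paste0("d", i), 2L * ch[i], dec_out[i])
    P <- p_res3(P, "head", dec_out[1], dec_out[1])
    P <- p_conv(P, "out", 3, 3, dec_out[1], 3L)
    structure(list(config = config, params = P, type = "generator"),
              class = "virtpol_generator")
  })
}

generator_forward_graph <- function(tape, ps, cfg, xnode) {
  s <- cfg$leaky_slope
  e <- list()
  x <- xnode
  for (i in 1:4) {
    e[[i]] <- res3_g(tape, ps, paste0("e", i), x, s)
    x <- nd_maxpool2(tape, e[[i]])
  }
  for (i in 4:1) {
    gs <- att_g(tape, ps, paste0("a", i), e[[i]], x)
    x <- nd_concat(tape, nd_upsample2(tape, x), gs)
    x <- res3_g(tape, ps, paste0("d", i), x, s)
  }
  x <- res3_g(tape, ps, "head", x, s)
  conv_g(tape, ps, "out", x)
}

#' Run the generator on one stack
#'
#' Output is linear (not clipped); [infer_tile()] applies the `[0, 1]` clip.
#'
#' @param gen Generator from [build_generator()].
#' @param stack (H, W, in_channels) array, H and W divisible by
#'   `2^generator_levels` (16 by default).
#' @param dsm DSM matrix from [make_dsm()].
#' @return (H, W, 3) array.
#' @export
generator_forward <- function(gen, stack, dsm) {
  stack <- as_image3(stack)
  d <- dim(stack)
  div <- 2L^gen$config$generator_levels
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf("generator input size %dx%d must be divisible by %d",
                 d[1], d[2], div))
  if (d[3] != gen$config$in_channels)
    stop(sprintf("stack has %d channels, config expects %d", d[3],
                 gen$config$in_channels))
  stop_shape(stack, dsm, "stack and DSM")
  x <- array(c(stack, dsm), dim = c(d[1], d[2], d[3] + 1L))
  tape <- new_tape()
  ps <- wrap_params(tape, gen$params)
  out <- generator_forward_graph(tape, ps, gen$config, nd_const(tape, x))
  out$value
}

# --- discriminator ----------------------------------------------------------

#' Build the residual discriminator
#'
#' @inheritParams build_generator
#' @return List of class `virtpol_discriminator`.
#' @export
build_discriminator <- function(config = network_config(), seed = 1L) {
  w <- config$base_width
  cin <- 3L + if (config$condition_dsm) 1L else 0L
  nb <- config$discriminator_blocks
  with_seed(split_seed(seed, "discriminator"), {
    P <- list()
    P <- p_conv(P, "c0", 3, 3, cin, w)
    prev <- w
    for (i in seq_len(nb)) {
      P <- p_conv(P, paste0("b", i, ".c1"), 3, 3, prev, 2L * prev)
      P <- p_conv(P, paste0("b", i, ".c2"), 3, 3, 2L * prev, 2L * prev)
      P <- p_conv(P, paste0("b", i, ".rp"), 1, 1, prev, 2L * prev)
      prev <- 2L * prev
    }
    P <- p_dense(P, "fc1", prev, prev)
    P <- p_dense(P, "fc2", prev, 1L)
    structure(list(config = config, params = P, type = "discriminator"),
              class = "virtpol_discriminator")
  })
}

discriminator_forward_graph <- function(tape, ps, cfg, img) {
  s <- cfg$leaky_slope
  x <- nd_leaky_relu(tape, conv_g(tape, ps, "c0", img), s)
  for (i in seq_len(cfg$discriminator_blocks)) {
    h <- nd_leaky_relu(tape, conv_g(tape, ps, paste0("b", i, ".c1"), x), s)
    h <- conv_g(tape, ps, paste0("b", i, ".c2"), h, stride = 2L)
    r <- conv_g(tape, ps, paste0("b", i, ".rp"), x, stride = 2L)
    x <- nd_leaky_relu(tape, nd_add(tape, h, r), s)
  }
  v <- nd_global_avg_pool(tape, x)
  v <- nd_leaky_relu(tape, nd_dense(tape, v, ps[["fc1.w"]], ps[["fc1.b"]]), s)
  o <- nd_dense(tape, v, ps[["fc2.w"]], ps[["fc2.b"]])
  nd_sigmoid(tape, o)
}

#' Run the discriminator
#'
#' @param disc Discriminator from [build_discriminator()].
#' @param img (H, W, 3) image.
#' @param dsm DSM matrix; required when the network is DSM-conditioned.
#' @return Scalar probability in (0, 1).
#' @export
discriminator_forward <- function(disc, img, dsm = NULL) {
  img <- as_image3(img)
  if (disc$config$condition_dsm) {
    if (is.null(dsm)) stop("this discriminator is DSM-conditioned; pass dsm")
    stop_shape(img, dsm, "image and DSM")
    img <- array(c(img, dsm), dim = dim(img) + c(0L, 0L, 1L))
  }
  tape <- new_tape()
  ps <- wrap_params(tape, disc$params)
  out <- discriminator_forward_graph(tape, ps, disc$config,
                                     nd_const(tape, img))
  as.numeric(out$value)
}

# --- registration module ----------------------------------------------------

reg_channels <- function(cfg) {
  w <- cfg$base_width
  pmin(w * 2L^(seq_len(cfg$registration_levels) - 1L), 8L * w)
}

#' Build the displacement-field registration module
#'
#' @inheritParams build_generator
#' @return List of class `virtpol_registration`.
#' @export
build_registration_module <- function(config = network_config(), seed = 1L) {
  ch <- reg_channels(config)
  L <- config$registration_levels
  with_seed(split_seed(seed, "registration"), {
    P <- list()
    prev <- 6L
    for (i in seq_len(L)) {
      P <- p_res3(P, paste0("e", i), prev, ch[i])
      prev <- ch[i]
    }
    bw <- 2L * ch[L]
    P <- p_conv(P, "bn.up", 3, 3, ch[L], bw)
    for (k in 1:3) P <- p_res3(P, paste0("bn.r", k), bw, bw)
    P <- p_conv(P, "bn.dn", 3, 3, bw, ch[L])
    for (i in L:1) {
      outc <- ch[max(i - 1L, 1L)]
      P <- p_res3(P, paste0("d", i), 2L * ch[i], outc)
    }
    P <- p_conv(P, "out", 1, 1, ch[1], 2L, zero = TRUE)
    structure(list(config = config, params = P, type = "registration"),
              class = "virtpol_registration")
  })
}

registration_forward_graph <- function(tape, ps, cfg, moving, fixed) {
  s <- cfg$leaky_slope
  L <- cfg$registration_levels
  x <- nd_concat(tape, moving, fixed)
  e <- list()
  for (i in seq_len(L)) {
    e[[i]] <- res3_g(tape, ps, paste0("e", i), x, s)
    x <- nd_maxpool2(tape, e[[i]])
  }
  x <- nd_leaky_relu(tape, conv_g(tape, ps, "bn.up", x), s)
  for (k in 1:3) x <- res3_g(tape, ps, paste0("bn.r", k), x, s)
  x <- nd_leaky_relu(tape, conv_g(tape, ps, "bn.dn", x), s)
  for (i in L:1) {
    x <- nd_concat(tape, nd_upsample2(tape, x), e[[i]])
    x <- res3_g(tape, ps, paste0("d", i), x, s)
  }
  conv_g(tape, ps, "out", x)
}

#' Predict the displacement field aligning `moving` to `fixed`
#'
#' @param reg Registration module from [build_registration_module()].
#' @param moving,fixed (H, W, 3) images; H, W divisible by
#'   `2^registration_levels`.
#' @return (H, W, 2) displacement field (dx, dy) in pixels.
#' @export
registration_forward <- function(reg, moving, fixed) {
  moving <- as_image3(moving)
  fixed <- as_image3(fixed)
  stop_shape(moving, fixed, "moving and fixed")
  div <- 2L^reg$config$registration_levels
  d <- dim(moving)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf("registration input %dx%d must be divisible by %d",
                 d[1], d[2], div))
  tape <- new_tape()
  ps <- wrap_params(tape, reg$params)
  out <- registration_forward_graph(tape, ps, reg$config,
                                    nd_const(tape, moving),
                                    nd_const(tape, fixed))
  out$value
}

# --- joint graph used by training and generator_loss ------------------------

# Builds the generator-loss graph for one sample.  Returns the tape, the
# wrapped parameter nodes per module, the total loss node and the component
# values.  `reg = NULL` makes the warp the identity.
gan_graph <- function(input, dsm, target, gen, disc, reg, weights,
                      need = "generator",
                      ps_gen = NULL, ps_disc = NULL, ps_reg = NULL,
                      tape = NULL) {
  input <- as_image3(input)
  target <- as_image3(target)
  stop_shape(input, target)
  tape <- tape %||% new_tape()
  ps_gen <- ps_gen %||% wrap_params(tape, gen$params)
  ps_disc <- ps_disc %||% wrap_params(tape, disc$params)
  ps_reg <- if (is.null(reg)) NULL else ps_reg %||% wrap_params(tape, reg$params)
  d <- dim(input)
  x <- array(c(input, dsm), dim = c(d[1], d[2], d[3] + 1L))
  gout <- generator_forward_graph(tape, ps_gen, gen$config,
                                  nd_const(tape, x))
  tnode <- nd_const(tape, target)
  if (!is.null(reg)) {
    field <- registration_forward_graph(tape, ps_reg, reg$config, gout, tnode)
    warped <- nd_grid_sample(tape, gout, field)
  } else {
    field <- NULL
    warped <- gout
  }
  l1 <- nd_smooth_l1(tape, warped, tnode, weights$phi)
  dimg <- if (gen$config$condition_dsm) {
    nd_concat(tape, gout, nd_const(tape, array(dsm, dim = c(d[1], d[2], 1L))))
  } else gout
  p_fake <- discriminator_forward_graph(tape, ps_disc, disc$config, dimg)
  adv <- nd_bce(tape, p_fake, 1)
  tv <- nd_total_variation(tape, gout)
  total <- nd_sum_scalars(tape, list(l1, adv, tv),
                          c(weights$alpha, weights$beta, weights$gamma))
  sm <- if (!is.null(field)) nd_smoothness(tape, field) else NULL
  reg_total <- if (!is.null(field)) {
    nd_sum_scalars(tape, list(l1, sm), c(weights$lam, weights$mu))
  } else NULL
  list(tape = tape, ps_gen = ps_gen, ps_disc = ps_disc, ps_reg = ps_reg,
       gout = gout, field = field, p_fake = p_fake,
       loss = total, reg_loss = reg_total,
       components = list(total = total$value,
                         l1 = l1$value, adv = adv$value, tv = tv$value,
                         smth = if (!is.null(sm)) sm$value else NA_real_))
}
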