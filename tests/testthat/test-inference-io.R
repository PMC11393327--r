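# Inference contracts, stitching, and NetPBM round trips.

inf_ck <- function() {
  memo("inf_ck", {
    pairs <- phantom_dataset(2, phantom_spec(image_size = 64, n_nuclei = 4),
                             modalities = c("brightfield", "crosspol",
                                            "angleshift"), seed = 400)
    cfg <- train_config(lr_generator = 1e-3, lr_discriminator = 1e-4,
                        batch_size = 2L, crop_size = 32L, max_steps = 6L,
                        seed = 2L,
                        modalities = c("brightfield", "crosspol",
                                       "angleshift"),
                        use_registration = FALSE)
    train(pairs, network_config(base_width = 4L), cfg)
  })
}

test_that("infer_tile is deterministic, clipped, and pads odd sizes", {
  ck <- inf_ck()
  s <- memo("ph80", generate_phantom(phantom_spec(image_size = 80, seed = 71)))
  o1 <- infer_tile(ck, s$stack, "brightfield")
  o2 <- infer_tile(ck, s$stack, "brightfield")
  expect_identical(o1, o2)
  expect_equal(dim(o1), c(80L, 80L, 3L))  # 80 not divisible by 16: pad/crop
  expect_true(all(o1 >= 0 & o1 <= 1))
  # three-modality model renders the angle-shifted channel too
  o3 <- infer_tile(ck, s$stack, "angleshift")
  expect_equal(dim(o3), c(80L, 80L, 3L))
  expect_false(identical(o1, o3))
})

test_that("infer_wsi stitches consistently", {
  ck <- inf_ck()
  s <- phantom256()
  # single tile equals infer_tile
  one <- infer_wsi(ck, s$stack[1:64, 1:64, ], "crosspol", tile = 64L,
                   overlap = 8L)
  expect_equal(one$crosspol, infer_tile(ck, s$stack[1:64, 1:64, ], "crosspol"),
               tolerance = 1e-12)
  # overlap 0: pure abutment equals concatenated tiles
  ab <- infer_wsi(ck, s$stack[1:128, 1:128, ], "crosspol", tile = 64L,
                  overlap = 0L)
  tl <- infer_tile(ck, s$stack[1:64, 1:64, ], "crosspol")
  expect_equal(ab$crosspol[1:64, 1:64, ], tl, tolerance = 1e-12)
  # constant-signal WSI: seams do not exceed the gradients the network
  # already produces inside a tile (conv padding causes edge effects)
  const <- array(0.4, dim = c(128, 128, 4))
  out <- infer_wsi(ck, const, "brightfield", tile = 64L, overlap = 16L)$brightfield
  g <- abs(out[-1, , ] - out[-128, , ])
  boundary_rows <- c(47:49, 63:65, 79:81)
  expect_lte(max(g[boundary_rows, , ]), max(g[-boundary_rows, , ]))
  # both requested modalities come from the same stack
  two <- infer_wsi(ck, s$stack[1:64, 1:64, ], c("brightfield", "crosspol"),
                   tile = 64L, overlap = 16L)
  expect_setequal(names(two), c("brightfield", "crosspol"))
})

test_that("NetPBM images round-trip bit-exactly at 16-bit", {
  set.seed(12)
  img <- array(round(runif(24 * 16 * 3) * 65535) / 65535,
               dim = c(24, 16, 3))
  p <- tempfile(fileext = ".ppm")
  write_pnm(img, p)
  expect_identical(read_pnm(p), img)
  g <- matrix(round(runif(32 * 20) * 65535) / 65535, 32, 20)
  p2 <- tempfile(fileext = ".pgm")
  write_pnm(g, p2)
  expect_identical(read_pnm(p2), g)
})

test_that("stacks round-trip through per-channel PGM plus manifest", {
  s <- memo("ph80", generate_phantom(phantom_spec(image_size = 80, seed = 71)))
  q <- round(s$stack * 65535) / 65535
  pfx <- file.path(tempdir(), "stk")
  write_stack(q, pfx)
  expect_identical(read_stack(pfx), q)
})

test_that("the CLI simulate subcommand writes a sample set", {
  out <- file.path(tempdir(), "cli_sim")
  virtpol_cli(c("simulate", "--out", out, "-n", "1", "--seed", "5",
                "--config", {
                  cfgp <- tempfile(fileext = ".json")
                  jsonlite::write_json(list(image_size = 64, n_nuclei = 3),
                                       cfgp, auto_unbox = TRUE)
                  cfgp
                }))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "sample001_brightfield.ppm")))
  st <- read_stack(file.path(out, "sample001"))
  expect_equal(dim(st), c(64L, 64L, 4L))
})
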