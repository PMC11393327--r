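# Image file I/O.
#
# No TIFF reader/writer is available in this R stack, so images are stored
# as 16-bit binary NetPBM: PPM (P6) for RGB, PGM (P5) for single channels.
# Autofluorescence stacks are stored as one PGM per channel plus a JSON
# manifest.  The 16-bit quantization round-trips [0, 1] floats bit-exactly
# through round(x * 65535).

#' Write / read a 16-bit NetPBM image
#'
#' @param img Matrix (PGM) or (H, W, 3) array (PPM), values in `[0, 1]`.
#' @param path Output path (`.pgm` / `.ppm`).
#' @return `read_pnm` returns a matrix or (H, W, 3) array in `[0, 1]`.
#' @export
write_pnm <- function(img, path) {
  gray <- is.matrix(img) || dim(as_image3(img))[3] == 1L
  img <- as_image3(clip01(img))
  d <- dim(img)
  q <- round(img * 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n65535\n", if (gray) "P5" else "P6",
                    d[2], d[1]), con, eos = NULL)
  # row-major, channel-interleaved, big-endian 16-bit (packed manually to
  # avoid signed-short overflow in writeBin)
  v <- as.vector(aperm(q, c(3, 2, 1)))
  b <- raw(2L * length(v))
  b[c(TRUE, FALSE)] <- as.raw(v %/% 256L)
  b[c(FALSE, TRUE)] <- as.raw(v %% 256L)
  writeBin(b, con)
  invisible(path)
}

#' @rdname write_pnm
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  while (length(hdr) < 4L) {
    line <- sub("#.*", "", readLines(con, n = 1L))
    hdr <- c(hdr, strsplit(trimws(line), "\\s+")[[1]])
  }
  magic <- hdr[1]
  if (!magic %in% c("P5", "P6")) stop("unsupported NetPBM type: ", magic)
  W <- as.integer(hdr[2]); H <- as.integer(hdr[3])
  maxval <- as.integer(hdr[4])
  C <- if (magic == "P6") 3L else 1L
  n <- H * W * C
  vals <- if (maxval > 255L) {
    b <- readBin(con, "raw", n = 2L * n)
    as.integer(b[c(TRUE, FALSE)]) * 256L + as.integer(b[c(FALSE, TRUE)])
  } else {
    as.integer(readBin(con, "raw", n = n))
  }
  a <- aperm(array(vals, dim = c(C, W, H)), c(3, 2, 1)) / maxval
  if (C == 1L) a[, , 1] else a
}

#' Write / read an autofluorescence stack
#'
#' One 16-bit PGM per channel plus a JSON manifest naming the channels.
#'
#' @param stack (H, W, C) array in `[0, 1]`.
#' @param prefix Path prefix; files become `<prefix>_ch<k>.pgm` and
#'   `<prefix>_manifest.json`.
#' @param channels Channel names recorded in the manifest.
#' @return `read_stack` returns the (H, W, C) array.
#' @export
write_stack <- function(stack, prefix,
                        channels = c("DAPI", "FITC", "TxRed", "Cy5")) {
  stack <- as_image3(stack)
  C <- dim(stack)[3]
  channels <- channels[seq_len(C)]
  files <- sprintf("%s_ch%d.pgm", prefix, seq_len(C))
  for (k in seq_len(C)) write_pnm(stack[, , k], files[k])
  jsonlite::write_json(list(channels = channels, files = basename(files),
                            height = dim(stack)[1], width = dim(stack)[2]),
                       paste0(prefix, "_manifest.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  man <- jsonlite::read_json(paste0(prefix, "_manifest.json"),
                             simplifyVector = TRUE)
  chans <- lapply(file.path(dirname(prefix), man$files), read_pnm)
  array(unlist(chans), dim = c(man$height, man$width, length(chans)))
}
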