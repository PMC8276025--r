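# File formats. Video stacks travel as grayscale multipage TIFF (8/16-bit
# integer); MRC stacks (modes 0/1/2/6) are readable for EM ecosystems.
# Masks and measurements are TIFF files paired with a JSON sidecar carrying
# the provenance needed to decode them safely (B, seeds, pixel_peak, scale):
# mask/measurement mix-ups are the dominant failure mode of a mask-coded
# scheme, so every artifact records where it came from and readers check.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_format(sprintf("missing JSON sidecar '%s'", sp))
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Read a grayscale image stack (multipage TIFF or MRC)
#'
#' TIFF pages must be single-channel 8- or 16-bit integer; the bit depth is
#' recorded as `pixel_peak` (255 or 65535) and values are returned unscaled.
#' MRC modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16) are supported,
#' with `pixel_peak` taken from the data maximum rounded up to the nearest
#' integer bit depth.
#'
#' @param path file path; format chosen by extension (`.mrc` vs TIFF).
#' @return a [tcs_video()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: '%s'", path))
  if (grepl("\\.mrc$", path, ignore.case = TRUE)) {
    return(read_mrc_stack(path))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  for (p in pages) {
    if (length(dim(p)) > 2L) {
      stop_format("color TIFF pages are not supported (grayscale dialect only)")
    }
  }
  peak <- 2^bits - 1
  frames <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  tcs_video(frames, pixel_peak = peak)
}

#' Write a video block as a multipage integer TIFF
#'
#' @param video a [tcs_video()].
#' @param path output path.
#' @param bits 8 or 16; `NULL` picks from `pixel_peak`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(video, path, bits = NULL) {
  if (is.null(bits)) bits <- if (video$pixel_peak > 255) 16L else 8L
  if (!bits %in% c(8L, 16L)) stop_parameter("bits must be 8 or 16")
  maxint <- 2^bits - 1
  pages <- lapply(seq_len(video$B), function(t) {
    pmin(pmax(round(video$frames[, , t]), 0), maxint) / maxint
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

# Minimal MRC reader: 1024-byte header, little-endian, no extended-header
# symmetry records beyond the declared size.
read_mrc_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop_format(sprintf("unsupported MRC mode %d", mode)))
  if (length(data) < n) stop_format("truncated MRC data section")
  # MRC stores columns (x) fastest; map to rows = y, cols = x per section
  frames <- array(0, c(ny, nx, nz))
  arr <- array(as.numeric(data), c(nx, ny, nz))
  for (z in seq_len(nz)) frames[, , z] <- t(arr[, , z])
  frames <- frames - min(0, min(frames))  # shift signed data to >= 0
  peak <- if (max(frames) <= 255) 255 else 65535
  tcs_video(frames, pixel_peak = peak)
}

#' Write a mask set (bilevel multipage TIFF + JSON header)
#'
#' The B mask planes go into one bilevel multipage TIFF; the JSON sidecar
#' records `{B, nx, ny, seed, density}` so the set can be validated (or
#' regenerated from the seed alone) at decode time.
#'
#' @param masks a `tcs_masks`.
#' @param path output TIFF path (sidecar at `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  pages <- lapply(seq_len(masks$B), function(b) masks$masks[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  write_sidecar(path, list(kind = "tcs_masks", B = masks$B, nx = masks$nx,
                           ny = masks$ny, seed = masks$seed,
                           density = masks$density))
  invisible(path)
}

#' Read a mask set written by [write_masks()]
#'
#' @param path TIFF path with `<path>.json` sidecar.
#' @return a `tcs_masks`.
#' @export
read_masks <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "tcs_masks")) stop_format("sidecar is not a mask header")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  masks <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) masks[, , b] <- round(pages[[b]])
  if (!all(masks %in% c(0, 1))) stop_format("mask planes are not bilevel")
  if (length(pages) != meta$B || nrow(pages[[1]]) != meta$nx ||
      ncol(pages[[1]]) != meta$ny) {
    stop_provenance("mask file shape disagrees with its sidecar")
  }
  new_tcs_masks(masks, as.integer(meta$seed), meta$density)
}

#' Write a coded measurement (TIFF + JSON sidecar)
#'
#' Integer-valued measurements with dynamic range within 16 bits are stored
#' losslessly as 16-bit TIFF; anything else is stored as 32-bit float TIFF
#' scaled into the unit interval with the scale recorded in the sidecar. The sidecar
#' carries `{B, mask_seed, pixel_peak}` so decoding can verify provenance.
#'
#' @param m a `tcs_measurement`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_measurement <- function(m, path) {
  top <- m$b_used * m$pixel_peak
  integral <- all(m$y == round(m$y)) && top <= 65535
  if (integral) {
    tiff::writeTIFF(m$y / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    scale <- 65535
  } else {
    scale <- max(top, max(m$y), 1)
    tiff::writeTIFF(m$y / scale, path, bits.per.sample = 32L,
                    compression = "none")
  }
  write_sidecar(path, list(kind = "tcs_measurement", B = m$b_used,
                           mask_seed = m$mask_seed,
                           pixel_peak = m$pixel_peak, scale = scale,
                           integral = integral))
  invisible(path)
}

#' Read a measurement written by [write_measurement()]
#'
#' @param path TIFF path with `<path>.json` sidecar.
#' @return a `tcs_measurement`.
#' @export
read_measurement <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "tcs_measurement")) {
    stop_format("sidecar is not a measurement header")
  }
  y <- tiff::readTIFF(path, as.is = isTRUE(meta$integral))
  y <- if (isTRUE(meta$integral)) y * 1 else y * meta$scale
  structure(
    list(y = y, b_used = as.integer(meta$B),
         mask_seed = as.integer(meta$mask_seed),
         pixel_peak = meta$pixel_peak),
    class = "tcs_measurement"
  )
}

#' Save decoder weights to a versioned checkpoint
#'
#' The checkpoint is a serialized list `{schema_version, config, cnn,
#' forward_rnn, backward_rnn}` of named numeric tensors.
#'
#' @param weights a `tcs_weights`.
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_weights <- function(weights, path) {
  if (!inherits(weights, "tcs_weights")) stop_parameter("weights must be a tcs_weights")
  saveRDS(unclass(weights), path)
  invisible(path)
}

#' Load decoder weights saved by [save_weights()]
#'
#' @param path checkpoint path.
#' @return a `tcs_weights`.
#' @export
load_weights <- function(path) {
  w <- readRDS(path)
  if (is.null(w$schema_version) || w$schema_version > 1L) {
    stop_format("unsupported checkpoint schema")
  }
  class(w$config) <- "tcs_net_config"
  structure(w, class = "tcs_weights")
}
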