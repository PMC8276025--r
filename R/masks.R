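# Coded-mask generation and the temporal compressive-sensing forward model.
#
# B video frames X_1..X_B are modulated element-wise by pre-determined binary
# masks C_1..C_B and summed into a single coded measurement
#     Y = sum_b X_b (*) C_b,
# so the stored payload shrinks by a factor of B once the masks are shared.
# The normalized measurement Ybar = Y (/) sum_k C_k is a crude scene estimate
# used as the entry point of the learned decoder.

#' Construct a video block
#'
#' A video block is a stack of B grayscale frames in arbitrary linear
#' intensity units, together with the maximum representable intensity
#' (`pixel_peak`, e.g. 255 for 8-bit sources). Frames are stored as an
#' `nx x ny x B` array (rows x cols x time, origin top-left).
#'
#' @param frames numeric array `nx x ny x B`, or a matrix for B = 1.
#' @param pixel_peak maximum representable intensity of the source.
#' @return an object of class `tcs_video` with fields `frames`, `B`, `nx`,
#'   `ny`, `pixel_peak`.
#' @export
tcs_video <- function(frames, pixel_peak = 255) {
  if (is.matrix(frames)) frames <- array(frames, c(nrow(frames), ncol(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_dimension("frames must be an nx x ny x B array")
  }
  if (dim(frames)[3] < 1L) stop_dimension("a video block needs B >= 1 frames")
  if (!all(is.finite(frames))) stop_parameter("frame intensities must be finite")
  if (min(frames) < 0) stop_parameter("frame intensities must be non-negative")
  if (!is.numeric(pixel_peak) || length(pixel_peak) != 1L || pixel_peak <= 0) {
    stop_parameter("pixel_peak must be a single positive number")
  }
  structure(
    list(frames = frames, B = dim(frames)[3], nx = dim(frames)[1],
         ny = dim(frames)[2], pixel_peak = pixel_peak),
    class = "tcs_video"
  )
}

#' @export
print.tcs_video <- function(x, ...) {
  cat(sprintf("<tcs_video> %d frames of %d x %d, pixel_peak = %g, range [%g, %g]\n",
              x$B, x$nx, x$ny, x$pixel_peak, min(x$frames), max(x$frames)))
  invisible(x)
}

new_tcs_masks <- function(masks, seed, density) {
  structure(
    list(masks = masks, B = dim(masks)[3], nx = dim(masks)[1],
         ny = dim(masks)[2], seed = seed, density = density),
    class = "tcs_masks"
  )
}

#' Generate a set of random binary coding masks
#'
#' Draws B independent Bernoulli(density) masks of size `nx x ny` (values
#' exactly 0 or 1; the default density 0.5 gives 0 and 1 with the same
#' probability). Each mask plane is seeded from `(seed, plane index)` with a
#' counter-based scheme, so regeneration with the same seed and shape is
#' bit-identical and independent of draw order.
#'
#' @param B number of frames collapsed into one measurement (compression
#'   ratio).
#' @param nx,ny mask height and width in pixels.
#' @param seed integer seed.
#' @param density probability of a 1 at each element, in (0, 1).
#' @param guarantee_coverage if `TRUE`, pixels left uncovered by every mask
#'   (`sum_k C_k = 0`) are redrawn until covered, so the normalized
#'   measurement is defined everywhere. Off by default to keep the masks
#'   i.i.d. Bernoulli.
#' @return an object of class `tcs_masks`.
#' @seealso [all_ones_masks()] for the degenerate identity code.
#' @export
generate_masks <- function(B, nx, ny, seed = 1L, density = 0.5,
                           guarantee_coverage = FALSE) {
  for (d in list(B = B, nx = nx, ny = ny)) {
    if (!is.numeric(d) || length(d) != 1L || d < 1 || d != floor(d)) {
      stop_dimension("B, nx and ny must be positive integers")
    }
  }
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density >= 1) {
    stop_parameter("density must lie strictly inside (0, 1)")
  }
  B <- as.integer(B); nx <- as.integer(nx); ny <- as.integer(ny)
  masks <- array(0, c(nx, ny, B))
  for (b in seq_len(B)) {
    masks[, , b] <- with_stream_seed(seed, b, {
      as.numeric(stats::runif(nx * ny) < density)
    })
  }
  if (guarantee_coverage) {
    cov <- mask_coverage_array(masks)
    iter <- 0L
    while (any(cov == 0)) {
      iter <- iter + 1L
      hole <- which(cov == 0)
      draws <- with_stream_seed(seed, B + iter, {
        matrix(as.numeric(stats::runif(length(hole) * B) < density),
               length(hole), B)
      })
      for (b in seq_len(B)) {
        plane <- masks[, , b]
        plane[hole] <- draws[, b]
        masks[, , b] <- plane
      }
      cov <- mask_coverage_array(masks)
      if (iter > 10000L) stop_parameter("coverage guarantee did not converge")
    }
  }
  new_tcs_masks(masks, as.integer(seed), density)
}

#' Degenerate all-ones mask set (identity code)
#'
#' With every mask element equal to 1 the measurement of a single frame is
#' the frame itself; useful for tests and as the density -> 1 limit.
#'
#' @inheritParams generate_masks
#' @return a `tcs_masks` object whose planes are all ones (`seed = NA`).
#' @export
all_ones_masks <- function(B, nx, ny) {
  new_tcs_masks(array(1, c(nx, ny, B)), NA_integer_, 1)
}

#' @export
print.tcs_masks <- function(x, ...) {
  cat(sprintf("<tcs_masks> B = %d planes of %d x %d, density = %g, seed = %s\n",
              x$B, x$nx, x$ny, x$density, format(x$seed)))
  invisible(x)
}

mask_coverage_array <- function(masks) {
  d <- dim(masks)
  matrix(rowSums(matrix(masks, d[1] * d[2], d[3])), d[1], d[2])
}

#' Per-pixel mask coverage sum_k C_k
#'
#' @param masks a `tcs_masks` object.
#' @return an `nx x ny` matrix of integer coverage counts.
#' @export
mask_coverage <- function(masks) mask_coverage_array(masks$masks)

check_shapes_agree <- function(a, b, what) {
  if (a$nx != b$nx || a$ny != b$ny || a$B != b$B) {
    stop_dimension(sprintf(
      "%s: shape mismatch (%d x %d x %d vs %d x %d x %d)",
      what, a$nx, a$ny, a$B, b$nx, b$ny, b$B))
  }
}

#' Encode a video block into a single coded measurement
#'
#' The snapshot forward model: `y = sum_b X_b * C_b` element-wise. Because
#' the masks are 0/1 the operation reduces to indexing the 1 elements and
#' summing across frames; the accumulator is double precision so the dynamic
#' range `B * pixel_peak` is never clipped.
#'
#' @param video a [tcs_video()].
#' @param masks a [generate_masks()] mask set of the same `(B, nx, ny)` shape.
#' @return an object of class `tcs_measurement` with fields `y` (an
#'   `nx x ny` matrix), `b_used`, `mask_seed`, `pixel_peak`.
#' @export
encode <- function(video, masks) {
  if (!inherits(video, "tcs_video")) stop_parameter("video must be a tcs_video")
  if (!inherits(masks, "tcs_masks")) stop_parameter("masks must be a tcs_masks")
  check_shapes_agree(video, masks, "encode")
  n <- video$nx * video$ny
  y <- rowSums(matrix(video$frames, n, video$B) * matrix(masks$masks, n, masks$B))
  structure(
    list(y = matrix(y, video$nx, video$ny), b_used = masks$B,
         mask_seed = masks$seed, pixel_peak = video$pixel_peak),
    class = "tcs_measurement"
  )
}

#' @export
print.tcs_measurement <- function(x, ...) {
  cat(sprintf("<tcs_measurement> %d x %d, B = %d, mask_seed = %s, range [%g, %g]\n",
              nrow(x$y), ncol(x$y), x$b_used, format(x$mask_seed),
              min(x$y), max(x$y)))
  invisible(x)
}

check_measurement_provenance <- function(m, masks) {
  if (m$b_used != masks$B ||
      !identical(is.na(m$mask_seed), is.na(masks$seed)) ||
      (!is.na(m$mask_seed) && m$mask_seed != masks$seed)) {
    stop_provenance(sprintf(
      "measurement was coded with B = %d, mask_seed = %s; supplied masks have B = %d, seed = %s",
      m$b_used, format(m$mask_seed), masks$B, format(masks$seed)))
  }
  if (nrow(m$y) != masks$nx || ncol(m$y) != masks$ny) {
    stop_dimension("measurement and masks have different spatial sizes")
  }
}

#' Normalize a measurement by the mask coverage
#'
#' Computes `Ybar = Y (/) sum_k C_k` element-wise. Where no mask covers a
#' pixel the divisor is zero; such pixels are set to 0, flagged in
#' `zero_coverage`, and a warning is raised (see
#' `generate_masks(guarantee_coverage = TRUE)` to avoid them altogether).
#'
#' @param m a `tcs_measurement` produced by [encode()] with `masks`.
#' @param masks the mask set used to produce `m`.
#' @return an object of class `tcs_normalized` with fields `ybar`,
#'   `zero_coverage` (logical matrix), `b_used`, `mask_seed`, `pixel_peak`.
#' @export
normalize_measurement <- function(m, masks) {
  if (!inherits(m, "tcs_measurement")) stop_parameter("m must be a tcs_measurement")
  check_measurement_provenance(m, masks)
  cov <- mask_coverage(masks)
  zero <- cov == 0
  ybar <- m$y
  ybar[!zero] <- ybar[!zero] / cov[!zero]
  if (any(zero)) {
    ybar[zero] <- 0
    warning(sprintf("%d pixel(s) have zero mask coverage; Ybar set to 0 there",
                    sum(zero)))
  }
  structure(
    list(ybar = ybar, zero_coverage = zero, b_used = m$b_used,
         mask_seed = m$mask_seed, pixel_peak = m$pixel_peak),
    class = "tcs_normalized"
  )
}

#' Approximate coded frames from the normalized measurement
#'
#' Returns the stack `Ybar * C_1, ..., Ybar * C_B`: each plane approximates
#' the true coded frame `C_k * X_k` (exactly so for a constant scene with
#' full coverage) and the planes are used as input channels of the decoder.
#'
#' @param nm a `tcs_normalized` measurement.
#' @param masks the matching mask set.
#' @return an `nx x ny x B` array.
#' @export
approx_coded_frames <- function(nm, masks) {
  if (!inherits(nm, "tcs_normalized")) stop_parameter("nm must be a tcs_normalized")
  if (nrow(nm$ybar) != masks$nx || ncol(nm$ybar) != masks$ny) {
    stop_dimension("normalized measurement and masks have different spatial sizes")
  }
  masks$masks * as.vector(nm$ybar)
}
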