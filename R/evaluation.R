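# Quantitative evaluation: PSNR/SSIM against ground truth, the storage
# rate-matched JPEG baseline, the naive replicated-Ybar baseline, and an
# FFT peak-retention diagnostic for lattice (Bragg-like) frequencies.

as_frame_matrix <- function(x) {
  if (inherits(x, "tcs_video")) return(x$frames)
  x
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop_dimension(sprintf("frame shapes differ: %s vs %s",
                           paste(dim(a), collapse = "x"),
                           paste(dim(b), collapse = "x")))
  }
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE(a, b))` in dB. Identical inputs (zero MSE) return
#' the sentinel `cap` (default 100 dB), which also bounds the result from
#' above.
#'
#' @param a,b numeric matrices of the same shape.
#' @param peak maximum representable intensity.
#' @param cap sentinel/ceiling in dB for the zero-MSE case.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, peak = 255, cap = 100) {
  check_same_shape(a, b)
  if (peak <= 0) stop_parameter("peak must be positive")
  mse <- mean((a - b)^2)
  if (mse == 0) return(cap)
  min(10 * log10(peak^2 / mse), cap)
}

gaussian_kernel_1d <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable valid-region filtering: returns an (nx-size+1) x (ny-size+1)
# matrix of local weighted means.
filter_valid <- function(x, g) {
  size <- length(g)
  nx <- nrow(x); ny <- ncol(x)
  out1 <- matrix(0, nx - size + 1, ny)
  for (i in seq_len(size)) {
    out1 <- out1 + g[i] * x[i:(nx - size + i), , drop = FALSE]
  }
  out2 <- matrix(0, nrow(out1), ny - size + 1)
  for (j in seq_len(size)) {
    out2 <- out2 + g[j] * out1[, j:(ny - size + j), drop = FALSE]
  }
  out2
}

#' Structural similarity index (SSIM)
#'
#' Mean local structural similarity with the standard stabilized form:
#' Gaussian window (11 points, sigma 1.5), constants `C1 = (K1 peak)^2`,
#' `C2 = (K2 peak)^2` with `K = (0.01, 0.03)`. Local statistics are computed
#' on the valid (fully overlapping) window positions.
#'
#' @param a,b numeric matrices of the same shape, at least as large as the
#'   window.
#' @param peak maximum representable intensity.
#' @param window window size in pixels (odd).
#' @param sigma Gaussian window standard deviation in pixels.
#' @param K stabilization constants `c(K1, K2)`.
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(a, b, peak = 255, window = 11, sigma = 1.5,
                 K = c(0.01, 0.03)) {
  check_same_shape(a, b)
  if (nrow(a) < window || ncol(a) < window) {
    stop_parameter("frames must be at least as large as the SSIM window")
  }
  g <- gaussian_kernel_1d(window, sigma)
  C1 <- (K[1] * peak)^2
  C2 <- (K[2] * peak)^2
  mu1 <- filter_valid(a, g)
  mu2 <- filter_valid(b, g)
  s11 <- filter_valid(a * a, g) - mu1^2
  s22 <- filter_valid(b * b, g) - mu2^2
  s12 <- filter_valid(a * b, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Rate-matched JPEG baseline
#'
#' Per frame, finds by bisection the maximum standard JPEG quality (integer
#' 1-100) whose encoded byte size stays within `raw frame bytes / B`, the
#' storage budget that equalizes JPEG with one coded measurement per B
#' frames (the reusable mask bundle is excluded from byte accounting on both
#' sides). If even quality 1 exceeds the budget the frame is flagged
#' infeasible and scored against the quality-1 output.
#'
#' @param video a [tcs_video()] (frames are exported at 8 bits).
#' @param B compression ratio defining the byte budget.
#' @return list with `video` (decoded JPEG frames as a `tcs_video`),
#'   `bytes`, `quality`, `infeasible` (per-frame), and `budget`.
#' @export
jpeg_rate_matched <- function(video, B) {
  if (!inherits(video, "tcs_video")) stop_parameter("video must be a tcs_video")
  bytes_per_px <- if (video$pixel_peak > 255) 2 else 1
  budget <- video$nx * video$ny * bytes_per_px / B
  dec <- array(0, dim(video$frames))
  bytes <- integer(video$B)
  quality <- integer(video$B)
  infeasible <- logical(video$B)
  # libjpeg emits an informational "quantization tables too coarse" caution
  # at very low quality; it is inherent to operating at these budgets
  jpeg_bytes <- function(img, q) {
    length(suppressWarnings(jpeg::writeJPEG(img, raw(), quality = q / 100)))
  }
  for (t in seq_len(video$B)) {
    img <- pmin(pmax(video$frames[, , t] / video$pixel_peak, 0), 1)
    img <- round(img * 255) / 255
    if (jpeg_bytes(img, 1) > budget) {
      q <- 1L
      infeasible[t] <- TRUE
    } else {
      lo <- 1L; hi <- 100L  # invariant: bytes(lo) <= budget
      while (lo < hi) {
        mid <- as.integer(ceiling((lo + hi) / 2))
        if (jpeg_bytes(img, mid) <= budget) lo <- mid else hi <- mid - 1L
      }
      q <- lo
    }
    enc <- suppressWarnings(jpeg::writeJPEG(img, raw(), quality = q / 100))
    bytes[t] <- length(enc)
    quality[t] <- q
    dec[, , t] <- suppressWarnings(jpeg::readJPEG(enc)) * video$pixel_peak
  }
  if (any(infeasible)) {
    warning(sprintf("JPEG quality 1 exceeds the byte budget for %d frame(s); scored against quality-1 output", sum(infeasible)))
  }
  list(video = tcs_video(dec, video$pixel_peak), bytes = bytes,
       quality = quality, infeasible = infeasible, budget = budget)
}

#' Naive replicated-Ybar baseline
#'
#' The training-free lower-bound reference: the normalized measurement
#' replicated B times as the reconstruction of every frame.
#'
#' @param nm a `tcs_normalized` measurement.
#' @param B number of frames to emit.
#' @return a [tcs_video()] of B identical frames.
#' @export
naive_baseline <- function(nm, B) {
  if (!inherits(nm, "tcs_normalized")) stop_parameter("nm must be a tcs_normalized")
  tcs_video(array(rep(nm$ybar, B), c(nrow(nm$ybar), ncol(nm$ybar), B)),
            nm$pixel_peak)
}

#' FFT peak contrast at a spatial frequency
#'
#' Measures how well a periodic (Bragg-like) component survives compression:
#' the maximum FFT magnitude within a `window x window` neighborhood of
#' `+freq` and `-freq`, divided by the median magnitude in a surrounding
#' annulus at the same radius (the local spectral noise floor). A pure
#' cosine gives a very large ratio; white noise gives about 1. The ratio is
#' invariant to constant offsets (the DC bin is never part of peak or
#' annulus).
#'
#' @param image numeric matrix.
#' @param freq 2-vector, cycles/pixel (rows, cols); must lie inside the
#'   Nyquist square.
#' @param window odd neighborhood size (bins) searched around the target
#'   frequency.
#' @param annulus radial band (relative to the peak radius) whose median
#'   magnitude defines the noise floor.
#' @return the contrast ratio (dimensionless).
#' @export
fft_peak_contrast <- function(image, freq, window = 3,
                              annulus = c(0.7, 1.3)) {
  nx <- nrow(image); ny <- ncol(image)
  if (any(abs(freq) > 0.5)) stop_parameter("freq must lie within the Nyquist square")
  if (window < 1 || window %% 2 == 0) stop_parameter("window must be odd and positive")
  if (window >= min(nx, ny)) stop_parameter("window exceeds the spectrum bounds")
  mag <- Mod(stats::fft(image - mean(image)))
  # integer bin of the target frequency (and its conjugate), 0-based
  bin <- round(freq * c(nx, ny))
  if (all(bin == 0)) stop_parameter("freq collapses onto the DC bin at this frame size")
  half <- (window - 1) / 2
  neigh <- function(b) {
    is <- ((b[1] + (-half:half)) %% nx) + 1
    js <- ((b[2] + (-half:half)) %% ny) + 1
    as.matrix(expand.grid(i = is, j = js))
  }
  peak_cells <- rbind(neigh(bin), neigh(-bin))
  peak <- max(mag[peak_cells])
  # annulus at the peak radius, excluding the two peak neighborhoods and DC
  fi <- (seq_len(nx) - 1); fi <- ifelse(fi > nx / 2, fi - nx, fi)
  fj <- (seq_len(ny) - 1); fj <- ifelse(fj > ny / 2, fj - ny, fj)
  r <- sqrt(outer(fi^2, fj^2, "+"))
  r0 <- sqrt(sum(bin^2))
  sel <- r >= annulus[1] * r0 & r <= annulus[2] * r0
  sel[peak_cells] <- FALSE
  sel[1, 1] <- FALSE
  if (!any(sel)) stop_parameter("annulus is empty at this frequency/frame size")
  # numerical floor so an essentially empty annulus (pure spectral line)
  # yields a large, stable ratio instead of dividing by rounding dust
  peak / max(stats::median(mag[sel]), 1e-9 * max(mag))
}

#' Per-frame and average PSNR/SSIM report for candidate reconstructions
#'
#' @param truth ground-truth [tcs_video()].
#' @param candidates named list of [tcs_video()] objects to score.
#' @param bytes optional named list/vector of stored byte counts per method.
#' @param psnr_cap sentinel cap passed to [psnr()].
#' @return an object of class `tcs_metrics`: per-method data frames of
#'   per-frame PSNR (dB) and SSIM plus exact averages, `B`, and byte
#'   accounting (raw vs compressed).
#' @export
metrics_report <- function(truth, candidates, bytes = NULL, psnr_cap = 100) {
  if (!inherits(truth, "tcs_video")) stop_parameter("truth must be a tcs_video")
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    stop_parameter("candidates must be a named list")
  }
  methods <- lapply(names(candidates), function(nm) {
    v <- candidates[[nm]]
    check_shapes_agree(truth, v, paste0("metrics_report[", nm, "]"))
    pf_psnr <- vapply(seq_len(truth$B), function(t) {
      psnr(v$frames[, , t], truth$frames[, , t], truth$pixel_peak, cap = psnr_cap)
    }, numeric(1))
    pf_ssim <- vapply(seq_len(truth$B), function(t) {
      ssim(v$frames[, , t], truth$frames[, , t], truth$pixel_peak)
    }, numeric(1))
    list(frame = seq_len(truth$B), psnr = pf_psnr, ssim = pf_ssim,
         mean_psnr = mean(pf_psnr), mean_ssim = mean(pf_ssim),
         bytes = if (!is.null(bytes)) sum(bytes[[nm]]) else NA_real_)
  })
  names(methods) <- names(candidates)
  bytes_per_px <- if (truth$pixel_peak > 255) 2 else 1
  structure(
    list(methods = methods, B = truth$B,
         raw_bytes = truth$nx * truth$ny * truth$B * bytes_per_px),
    class = "tcs_metrics"
  )
}

#' @export
print.tcs_metrics <- function(x, ...) {
  cat(sprintf("<tcs_metrics> B = %d, raw payload %d bytes\n", x$B, x$raw_bytes))
  for (nm in names(x$methods)) {
    m <- x$methods[[nm]]
    cat(sprintf("  %-12s mean PSNR %6.2f dB  mean SSIM %6.4f%s\n", nm,
                m$mean_psnr, m$mean_ssim,
                if (is.finite(m$bytes)) sprintf("  (%d bytes)", as.integer(m$bytes)) else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.tcs_metrics <- function(x, ...) {
  do.call(rbind, lapply(names(x$methods), function(nm) {
    m <- x$methods[[nm]]
    data.frame(method = nm, frame = m$frame, psnr = m$psnr, ssim = m$ssim)
  }))
}
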