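# Synthetic in-situ TEM scenes for training and testing the codec.
#
# Two regimes are emulated: drifting atomic-lattice fringes (sums of cosine
# gratings, optionally windowed by a shrinking particle envelope, standing in
# for high-resolution imaging of evolving nanocrystals) and dark smooth
# fibers moving over a bright background (large-feature in-situ deformation).
# Detector noise is Poisson shot noise at a configurable dose plus additive
# Gaussian readout noise. Frame-to-frame drift is kept small by default so
# consecutive frames are coherent, which is the operating condition the
# recurrent decoder relies on.

#' Scene configuration for the synthetic EM video generator
#'
#' @param kind `"lattice"` (drifting cosine fringes) or `"fibers"` (dark
#'   ribbons on a bright background).
#' @param B number of frames.
#' @param nx,ny frame size in pixels.
#' @param drift 2-vector, pixels/frame drift of the whole lattice pattern
#'   (rows, cols). Defaults keep |drift| <= 2 so consecutive frames stay
#'   coherent.
#' @param spacings,angles,amplitudes,phases lattice fringe families:
#'   spacing in pixels, orientation in degrees, amplitude in intensity units,
#'   phase in radians (`NULL` phases are drawn from the seed).
#' @param background mean background intensity (lattice) in intensity units.
#' @param envelope if `TRUE`, fringes are windowed by a Gaussian particle
#'   envelope that shrinks over time (sintering-like); `envelope_radius` is
#'   its initial radius in pixels and `envelope_shrink` the per-frame radius
#'   factor.
#' @param envelope_radius,envelope_shrink see `envelope`.
#' @param n_fibers,fiber_width,fiber_center,fiber_velocity,fiber_depth,
#'   fiber_background fiber-scene parameters: number of vertical ribbons,
#'   Gaussian half-widths (px), center columns, velocities (columns/frame),
#'   absorption depths and bright background level. `NULL` centers are
#'   spread evenly.
#' @param dose expected electron counts per pixel at full scale
#'   (`pixel_peak`); Poisson shot noise scales as sqrt(intensity/dose).
#'   `Inf` disables shot noise.
#' @param gaussian_sigma standard deviation of additive Gaussian readout
#'   noise, in intensity units.
#' @param pixel_peak maximum representable intensity (8-bit scale default).
#' @param boundary `"periodic"` (drift wraps; stationary statistics) or
#'   `"clamped"`.
#' @param seed integer seed controlling phases and noise.
#' @return a list of class `tcs_scene_config`.
#' @export
scene_config <- function(kind = c("lattice", "fibers"), B = 10, nx = 64, ny = 64,
                         drift = c(0.7, 0.4),
                         spacings = c(6, 4.2), angles = c(15, 75),
                         amplitudes = c(40, 22), phases = NULL,
                         background = 120,
                         envelope = FALSE, envelope_radius = NULL,
                         envelope_shrink = 0.985,
                         n_fibers = 2, fiber_width = c(4, 7),
                         fiber_center = NULL, fiber_velocity = c(0.8, -0.5),
                         fiber_depth = c(120, 90), fiber_background = 200,
                         dose = 400, gaussian_sigma = 2, pixel_peak = 255,
                         boundary = c("periodic", "clamped"), seed = 1L) {
  kind <- match.arg(kind)
  boundary <- match.arg(boundary)
  if (B < 1 || nx < 1 || ny < 1) stop_dimension("B, nx, ny must be positive")
  if (length(drift) != 2) stop_parameter("drift must be a 2-vector")
  if (dose <= 0) stop_parameter("dose must be positive (Inf allowed)")
  structure(
    list(kind = kind, B = as.integer(B), nx = as.integer(nx),
         ny = as.integer(ny), drift = as.numeric(drift),
         spacings = spacings, angles = angles, amplitudes = amplitudes,
         phases = phases, background = background,
         envelope = envelope,
         envelope_radius = if (is.null(envelope_radius)) min(nx, ny) / 3 else envelope_radius,
         envelope_shrink = envelope_shrink,
         n_fibers = n_fibers, fiber_width = fiber_width,
         fiber_center = fiber_center, fiber_velocity = fiber_velocity,
         fiber_depth = fiber_depth, fiber_background = fiber_background,
         dose = dose, gaussian_sigma = gaussian_sigma,
         pixel_peak = pixel_peak, boundary = boundary,
         seed = as.integer(seed)),
    class = "tcs_scene_config"
  )
}

#' Spatial frequency of a lattice fringe family
#'
#' Returns the 2D spatial frequency (cycles/pixel, rows then cols) of fringe
#' family `i` of a lattice scene: the location of its Bragg-like peak in the
#' frame's Fourier transform.
#'
#' @param config a lattice [scene_config()].
#' @param i fringe family index.
#' @return numeric 2-vector in cycles/pixel.
#' @export
lattice_frequency <- function(config, i = 1) {
  a <- config$angles[i] * pi / 180
  c(cos(a), sin(a)) / config$spacings[i]
}

apply_detector_noise <- function(clean, config, stream_offset) {
  d <- dim(clean)
  n <- length(clean)
  noisy <- with_stream_seed(config$seed, stream_offset, {
    out <- clean
    if (is.finite(config$dose)) {
      lam <- pmax(clean, 0) * config$dose / config$pixel_peak
      out <- stats::rpois(n, lam) * config$pixel_peak / config$dose
    }
    if (config$gaussian_sigma > 0) {
      out <- out + stats::rnorm(n, 0, config$gaussian_sigma)
    }
    out
  })
  array(pmax(noisy, 0), d)  # detector counts cannot be negative
}

lattice_clean_frame <- function(config, t, phases) {
  nx <- config$nx; ny <- config$ny
  v <- config$drift
  # pixel coordinates after removing accumulated drift
  r1 <- matrix(seq_len(nx) - 1, nx, ny) - v[1] * (t - 1)
  r2 <- matrix(rep(seq_len(ny) - 1, each = nx), nx, ny) - v[2] * (t - 1)
  if (config$boundary == "clamped") {
    r1 <- pmin(pmax(r1, 0), nx - 1)
    r2 <- pmin(pmax(r2, 0), ny - 1)
  }
  fr <- 0
  for (i in seq_along(config$spacings)) {
    k <- 2 * pi * lattice_frequency(config, i)
    fr <- fr + config$amplitudes[i] * cos(k[1] * r1 + k[2] * r2 + phases[i])
  }
  if (config$envelope) {
    rad <- config$envelope_radius * config$envelope_shrink^(t - 1)
    c1 <- (nx - 1) / 2; c2 <- (ny - 1) / 2
    d2 <- (matrix(seq_len(nx) - 1, nx, ny) - c1)^2 +
      (matrix(rep(seq_len(ny) - 1, each = nx), nx, ny) - c2)^2
    fr <- fr * exp(-d2 / (2 * rad^2))
  }
  out <- config$background + fr
  if (min(out) < 0) {
    warning("negative intensities after composition; clipped at 0")
    out <- pmax(out, 0)
  }
  out
}

#' Synthesize a drifting-lattice EM video
#'
#' Clean frame t is `background + sum_i A_i cos(k_i . (r - v t) + phi_i)`
#' over the configured fringe families, optionally windowed by a shrinking
#' particle envelope; the noisy companion adds Poisson-Gaussian detector
#' noise. Both clean and noisy stacks are returned so reconstructions can be
#' scored against ground truth.
#'
#' @param config a [scene_config()] with `kind = "lattice"`.
#' @return `list(clean = tcs_video, noisy = tcs_video)`.
#' @export
lattice_video <- function(config) {
  if (config$kind != "lattice") stop_parameter("config$kind must be 'lattice'")
  phases <- config$phases
  if (is.null(phases)) {
    phases <- with_stream_seed(config$seed, 0L, {
      stats::runif(length(config$spacings), 0, 2 * pi)
    })
  }
  clean <- array(0, c(config$nx, config$ny, config$B))
  for (t in seq_len(config$B)) {
    clean[, , t] <- lattice_clean_frame(config, t, phases)
  }
  noisy <- array(0, dim(clean))
  for (t in seq_len(config$B)) {
    noisy[, , t] <- apply_detector_noise(clean[, , t], config, 1000L + t)
  }
  list(clean = tcs_video(clean, config$pixel_peak),
       noisy = tcs_video(noisy, config$pixel_peak))
}

fiber_clean_frame <- function(config, t) {
  nx <- config$nx; ny <- config$ny
  centers <- config$fiber_center
  if (is.null(centers)) {
    centers <- (seq_len(config$n_fibers) - 0.5) * ny / config$n_fibers
  }
  cols <- seq_len(ny) - 0.5
  profile <- rep(0, ny)
  any_out <- FALSE
  for (j in seq_len(config$n_fibers)) {
    c_t <- centers[j] + config$fiber_velocity[j] * (t - 1)
    if (config$boundary == "periodic") c_t <- ((c_t - 0.5) %% ny) + 0.5
    if (c_t < -3 * config$fiber_width[j] || c_t > ny + 3 * config$fiber_width[j]) {
      any_out <- TRUE
    }
    d <- cols - c_t
    if (config$boundary == "periodic") d <- ((d + ny / 2) %% ny) - ny / 2
    profile <- profile + config$fiber_depth[j] * exp(-d^2 / (2 * config$fiber_width[j]^2))
  }
  if (any_out) warning("a fiber lies entirely outside the frame")
  out <- config$fiber_background - matrix(rep(profile, each = nx), nx, ny)
  if (min(out) < 0) {
    warning("negative intensities after composition; clipped at 0")
    out <- pmax(out, 0)
  }
  out
}

#' Synthesize a moving-fiber EM video
#'
#' Dark Gaussian-profile vertical ribbons on a bright background, each
#' advancing by its own velocity (columns/frame); Poisson-Gaussian noise as
#' in [lattice_video()].
#'
#' @param config a [scene_config()] with `kind = "fibers"`.
#' @return `list(clean = tcs_video, noisy = tcs_video)`.
#' @export
fiber_video <- function(config) {
  if (config$kind != "fibers") stop_parameter("config$kind must be 'fibers'")
  clean <- array(0, c(config$nx, config$ny, config$B))
  for (t in seq_len(config$B)) clean[, , t] <- fiber_clean_frame(config, t)
  noisy <- array(0, dim(clean))
  for (t in seq_len(config$B)) {
    noisy[, , t] <- apply_detector_noise(clean[, , t], config, 1000L + t)
  }
  list(clean = tcs_video(clean, config$pixel_peak),
       noisy = tcs_video(noisy, config$pixel_peak))
}

#' Generate a synthetic video from any scene configuration
#'
#' @param config a [scene_config()].
#' @return `list(clean = tcs_video, noisy = tcs_video)`.
#' @export
synthesize_video <- function(config) {
  switch(config$kind,
         lattice = lattice_video(config),
         fibers = fiber_video(config))
}

#' Draw a randomized scene configuration
#'
#' Samples a scene from the fixed study distribution used for decoder
#' training: 70% drifting-lattice scenes (two fringe families, spacings
#' 3.5-8 px, random orientation and phase, drift speed 0.3-1.2 px/frame) and
#' 30% fiber scenes (two fibers, widths 3-8 px, velocities within 1
#' column/frame), all with dose 400 and readout sigma 2 on an 8-bit scale.
#'
#' @param seed integer seed identifying the clip; all scene parameters are a
#'   deterministic function of it.
#' @param B,nx,ny clip shape.
#' @param kind force `"lattice"` or `"fibers"`; `NULL` draws the mix.
#' @return a [scene_config()].
#' @export
random_scene_config <- function(seed, B, nx, ny, kind = NULL) {
  draw <- with_stream_seed(seed, 77L, {
    list(u_kind = stats::runif(1),
         spacings = c(stats::runif(1, 5, 8), stats::runif(1, 3.5, 5)),
         angles = stats::runif(2, 0, 180),
         amplitudes = c(stats::runif(1, 20, 45), stats::runif(1, 10, 25)),
         phases = stats::runif(2, 0, 2 * pi),
         background = stats::runif(1, 100, 140),
         drift_angle = stats::runif(1, 0, 2 * pi),
         drift_speed = stats::runif(1, 0.3, 1.2),
         fiber_width = stats::runif(2, 3, 8),
         fiber_center = sort(stats::runif(2, 0.15, 0.85)) * ny,
         fiber_velocity = stats::runif(2, -1, 1),
         fiber_depth = stats::runif(2, 60, 130),
         fiber_background = stats::runif(1, 180, 220))
  })
  if (is.null(kind)) kind <- if (draw$u_kind < 0.7) "lattice" else "fibers"
  if (kind == "lattice") {
    scene_config(
      kind = "lattice", B = B, nx = nx, ny = ny,
      drift = draw$drift_speed * c(cos(draw$drift_angle), sin(draw$drift_angle)),
      spacings = draw$spacings, angles = draw$angles,
      amplitudes = draw$amplitudes, phases = draw$phases,
      background = draw$background, seed = seed)
  } else {
    scene_config(
      kind = "fibers", B = B, nx = nx, ny = ny,
      n_fibers = 2, fiber_width = draw$fiber_width,
      fiber_center = draw$fiber_center, fiber_velocity = draw$fiber_velocity,
      fiber_depth = draw$fiber_depth, fiber_background = draw$fiber_background,
      seed = seed)
  }
}
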