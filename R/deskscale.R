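# The desk-scale reference study: a fixed, fully seeded configuration small
# enough to train on one CPU core in minutes, used by the test suite, the
# acceptance script and the documentation. One operating point (B = 4,
# 32 x 32 clips, 200 training clips, 2000 Adam steps, 8-channel decoder)
# is trained and then evaluated on held-out clips from the training
# distribution and on larger noisy lattice fixtures against the naive and
# rate-matched JPEG baselines.

#' Desk-scale training configuration
#'
#' The reference small-scale operating point: 32 x 32 clips, 200 training /
#' 24 validation clips, batch size 2, 2000 steps, 8-channel decoder with a
#' 16-pixel attention window.
#'
#' @param B compression ratio.
#' @param seed integer seed for the whole study.
#' @param steps optimization budget (2000 for the main run; the B sweep
#'   uses a shorter common budget).
#' @return a [train_config()].
#' @export
desk_train_config <- function(B = 4, seed = 1L, steps = 2000) {
  train_config(B = B, nx = 32, ny = 32, n_train_clips = 200,
               n_val_clips = 24, batch_size = 2, steps = steps,
               learning_rate = 1e-3, base_channels = 8, patience = 10,
               attention_window = 16, seed = seed)
}

#' Held-out clips from the training distribution
#'
#' Clips drawn from the same scene distribution as training but from a seed
#' stream disjoint from both the training and validation streams.
#'
#' @param B,nx,ny clip shape.
#' @param seed study seed.
#' @param n number of clips.
#' @return list of `list(clean, noisy)` clip pairs.
#' @export
desk_holdout_clips <- function(B, seed, n = 12, nx = 32, ny = 32) {
  lapply(seq_len(n), function(i) {
    sc <- random_scene_config(mix_seed(seed, 3000000L + i), B, nx, ny)
    suppressWarnings(synthesize_video(sc))
  })
}

#' Held-out noisy lattice fixtures for the headline comparison
#'
#' Lattice-only scenes at a larger frame size, used for the decoder-vs-JPEG
#' comparison and the Fourier peak-retention check. The decoder is fully
#' convolutional, so weights trained on 32 x 32 clips apply directly.
#'
#' @param B,nx,ny fixture shape.
#' @param seed study seed.
#' @param n number of fixtures.
#' @return list of `list(config, clean, noisy)`.
#' @export
desk_eval_scenes <- function(B, seed, n = 6, nx = 96, ny = 96) {
  lapply(seq_len(n), function(i) {
    sc <- random_scene_config(mix_seed(seed, 2000000L + i), B, nx, ny,
                              kind = "lattice")
    c(list(config = sc), suppressWarnings(synthesize_video(sc)))
  })
}

#' Score a decoder against the naive baseline on held-out clips
#'
#' Each clip's noisy frames are encoded with freshly generated masks of the
#' clip size (seeded by `mask_seed`), decoded, and scored against the clean
#' ground truth; the naive replicated-Ybar baseline is scored on the same
#' measurements.
#'
#' @param weights trained `tcs_weights`.
#' @param clips list of `list(clean, noisy)` pairs.
#' @param mask_seed seed for the evaluation mask set.
#' @return data.frame with per-clip mean PSNR/SSIM for decoder and naive
#'   baseline.
#' @export
evaluate_on_clips <- function(weights, clips, mask_seed) {
  B <- weights$config$B
  v1 <- clips[[1]]$clean
  masks <- generate_masks(B, v1$nx, v1$ny, seed = mask_seed)
  rows <- lapply(seq_along(clips), function(i) {
    clip <- clips[[i]]
    m <- encode(clip$noisy, masks)
    nm <- suppressWarnings(normalize_measurement(m, masks))
    rec <- reconstruct(m, masks, weights)$video
    nav <- naive_baseline(nm, B)
    rep <- metrics_report(clip$clean, list(decoder = rec, naive = nav))
    data.frame(clip = i,
               psnr_decoder = rep$methods$decoder$mean_psnr,
               psnr_naive = rep$methods$naive$mean_psnr,
               ssim_decoder = rep$methods$decoder$mean_ssim,
               ssim_naive = rep$methods$naive$mean_ssim)
  })
  do.call(rbind, rows)
}

#' Headline comparison on noisy lattice fixtures
#'
#' For each fixture: encode the noisy frames, decode, build the naive
#' baseline and the rate-matched JPEG baseline (JPEG applied directly to the
#' noisy raw frames, budget 1/B of the raw frame bytes), score everything
#' against the clean ground truth, and measure the Fourier peak contrast of
#' the primary lattice frequency on the middle frame of the decoded and
#' JPEG videos.
#'
#' @param weights trained `tcs_weights`.
#' @param scenes fixtures from [desk_eval_scenes()].
#' @param mask_seed seed for the evaluation mask set.
#' @return list with the per-fixture data.frame (`per_scene`) and the
#'   summary means (`summary`).
#' @export
desk_headline_eval <- function(weights, scenes, mask_seed) {
  B <- weights$config$B
  v1 <- scenes[[1]]$clean
  masks <- generate_masks(B, v1$nx, v1$ny, seed = mask_seed)
  rows <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    m <- encode(sc$noisy, masks)
    nm <- suppressWarnings(normalize_measurement(m, masks))
    rec <- reconstruct(m, masks, weights)$video
    nav <- naive_baseline(nm, B)
    jp <- suppressWarnings(jpeg_rate_matched(sc$noisy, B))
    rep <- metrics_report(sc$clean, list(decoder = rec, naive = nav,
                                         jpeg = jp$video))
    mid <- ceiling(B / 2)
    f1 <- lattice_frequency(sc$config, 1)
    data.frame(
      scene = i,
      psnr_decoder = rep$methods$decoder$mean_psnr,
      psnr_naive = rep$methods$naive$mean_psnr,
      psnr_jpeg = rep$methods$jpeg$mean_psnr,
      ssim_decoder = rep$methods$decoder$mean_ssim,
      ssim_jpeg = rep$methods$jpeg$mean_ssim,
      fft_decoder = fft_peak_contrast(rec$frames[, , mid], f1),
      fft_jpeg = fft_peak_contrast(jp$video$frames[, , mid], f1),
      fft_clean = fft_peak_contrast(sc$clean$frames[, , mid], f1),
      jpeg_bytes = sum(jp$bytes),
      jpeg_infeasible = any(jp$infeasible))
  })
  per_scene <- do.call(rbind, rows)
  list(per_scene = per_scene,
       summary = colMeans(per_scene[, c("psnr_decoder", "psnr_naive",
                                        "psnr_jpeg", "ssim_decoder",
                                        "ssim_jpeg", "fft_decoder",
                                        "fft_jpeg")]))
}

#' Run the full desk-scale study at one operating point
#'
#' Trains the decoder under [desk_train_config()] and evaluates it on the
#' held-out clips and the headline lattice fixtures.
#'
#' @param B compression ratio.
#' @param seed study seed.
#' @param steps training step budget.
#' @param verbose print training progress.
#' @return list with `train` (the [train_decoder()] result), `holdout`
#'   (per-clip scores), and `headline` (fixture comparison).
#' @export
desk_study <- function(B = 4, seed = 1L, steps = 2000, verbose = FALSE) {
  config <- desk_train_config(B = B, seed = seed, steps = steps)
  data <- suppressWarnings(make_training_set(config))
  fit <- suppressWarnings(train_decoder(config, data = data, verbose = verbose))
  holdout <- evaluate_on_clips(fit$weights,
                               desk_holdout_clips(B, seed),
                               mask_seed = mix_seed(seed, 4242L))
  headline <- desk_headline_eval(fit$weights,
                                 desk_eval_scenes(B, seed),
                                 mask_seed = mix_seed(seed, 4243L))
  list(config = config, train = fit, holdout = holdout, headline = headline)
}
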