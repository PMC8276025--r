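# Supervised training of the decoder on coded measurements of video clips.
#
# Clips are encoded with one fixed mask set (matching deployment, where the
# masks are pre-determined and reusable); the decoder is optimized with Adam
# on a weighted sum of the forward-branch and backward-branch mean squared
# errors, computed in normalized intensity units (frames / pixel_peak).
# Gradients flow through the whole unrolled network including the residual
# inputs (backpropagation through time over the B frames).

#' Training configuration
#'
#' @param B compression ratio of the trained operating point.
#' @param nx,ny clip size in pixels.
#' @param n_train_clips,n_val_clips number of training / validation clips;
#'   validation clips come from a disjoint seed stream and never enter
#'   training batches.
#' @param batch_size clips per optimization step.
#' @param steps optimization step budget.
#' @param learning_rate Adam step size (constant schedule).
#' @param loss_weights `c(forward, backward)` weights of the two branch
#'   losses.
#' @param patience early-stopping patience in epochs without validation
#'   improvement (an epoch is one pass-worth of training batches).
#' @param base_channels,kernel_size,attention_heads,attention_window decoder
#'   architecture (see [net_config()]).
#' @param noisy_inputs if `TRUE` (default) measurements are encoded from the
#'   noisy clips while targets are the clean clips, so the decoder learns
#'   denoising along with reconstruction.
#' @param seed integer seed governing clip synthesis, masks, weight
#'   initialization and batch sampling.
#' @return a list of class `tcs_train_config`.
#' @export
train_config <- function(B = 4, nx = 32, ny = 32, n_train_clips = 200,
                         n_val_clips = 24, batch_size = 2, steps = 2000,
                         learning_rate = 1e-3, loss_weights = c(1, 1),
                         patience = 10, base_channels = 8, kernel_size = 3,
                         attention_heads = 1, attention_window = 16,
                         noisy_inputs = TRUE, seed = 1L) {
  counts <- c(B, nx, ny, n_train_clips, n_val_clips, batch_size, steps)
  if (any(counts < 1)) stop_parameter("all counts must be positive")
  if (learning_rate <= 0) stop_parameter("learning_rate must be positive")
  if (length(loss_weights) != 2 || any(loss_weights < 0)) {
    stop_parameter("loss_weights must be two non-negative numbers")
  }
  structure(
    list(B = as.integer(B), nx = as.integer(nx), ny = as.integer(ny),
         n_train_clips = as.integer(n_train_clips),
         n_val_clips = as.integer(n_val_clips),
         batch_size = as.integer(batch_size), steps = as.integer(steps),
         learning_rate = learning_rate, loss_weights = loss_weights,
         patience = as.integer(patience),
         base_channels = as.integer(base_channels),
         kernel_size = as.integer(kernel_size),
         attention_heads = as.integer(attention_heads),
         attention_window = as.integer(attention_window),
         noisy_inputs = isTRUE(noisy_inputs), seed = as.integer(seed)),
    class = "tcs_train_config"
  )
}

#' Pair a video clip with its coded measurement
#'
#' The supervised pair is `(encode(video, masks), target)`; by default the
#' target is the video itself. Passing a separate `target` (e.g. the clean
#' clip while `video` is its noisy companion) trains denoising
#' reconstruction.
#'
#' @param video the [tcs_video()] to encode.
#' @param masks the shared mask set.
#' @param target supervision target; defaults to `video`.
#' @return `list(measurement, target)`.
#' @export
make_training_pair <- function(video, masks, target = video) {
  check_shapes_agree(video, masks, "make_training_pair")
  check_shapes_agree(target, masks, "make_training_pair(target)")
  list(measurement = encode(video, masks), target = target)
}

#' Weighted two-branch reconstruction loss
#'
#' `w_f * MSE(forward frames, target) + w_b * MSE(backward frames, target)`,
#' evaluated on whatever intensity scale `state` and `target` share (the
#' trainer applies it in normalized units).
#'
#' @param state a `tcs_recon_state` from [reconstruct()].
#' @param target the ground-truth [tcs_video()].
#' @param loss_weights `c(forward, backward)` branch weights.
#' @return scalar loss.
#' @export
decoder_loss <- function(state, target, loss_weights = c(1, 1)) {
  if (!inherits(state, "tcs_recon_state")) stop_parameter("state must be a tcs_recon_state")
  tf <- target$frames
  if (!identical(dim(state$forward_frames), dim(tf))) {
    stop_dimension("state and target shapes differ")
  }
  loss_weights[1] * mean((state$forward_frames - tf)^2) +
    loss_weights[2] * mean((state$backward_frames - tf)^2)
}

#' Generate the synthetic training and validation clip sets
#'
#' Clips are drawn from the fixed study distribution of
#' [random_scene_config()]. Training clip i uses seed stream `(seed, i)`;
#' validation clip j uses `(seed, 10^6 + j)`, so the two sets are disjoint
#' by construction.
#'
#' @param config a [train_config()].
#' @return `list(train, val)`, each a list of `list(clean, noisy)` clip
#'   pairs, plus the seed vectors used.
#' @export
make_training_set <- function(config) {
  gen <- function(offsets) {
    lapply(offsets, function(o) {
      sc <- random_scene_config(mix_seed(config$seed, o), config$B,
                                config$nx, config$ny)
      synthesize_video(sc)
    })
  }
  train_offsets <- seq_len(config$n_train_clips)
  val_offsets <- 1000000L + seq_len(config$n_val_clips)
  list(train = gen(train_offsets), val = gen(val_offsets),
       train_seeds = vapply(train_offsets, function(o) mix_seed(config$seed, o), integer(1)),
       val_seeds = vapply(val_offsets, function(o) mix_seed(config$seed, o), integer(1)))
}

# Precompute normalized per-clip tensors for the trainer.
prep_clip <- function(clip, masks, config) {
  video_in <- if (config$noisy_inputs) clip$noisy else clip$clean
  pair <- make_training_pair(video_in, masks, target = clip$clean)
  m <- pair$measurement
  nm <- suppressWarnings(normalize_measurement(m, masks))
  peak <- m$pixel_peak
  n <- masks$nx * masks$ny
  list(y = matrix(m$y / peak, n, 1L),
       ybar = matrix(nm$ybar / peak, n, 1L),
       target = matrix(pair$target$frames / peak, n, config$B))
}

# Loss node for one prepared batch; returns list(loss_node, graph).
batch_loss_graph <- function(tp, batch, mask_vecs_rep, wnodes, cfg, loss_weights) {
  d <- c(cfg$nx, cfg$ny, length(batch))
  y <- ag_const(set_fmd(do.call(rbind, lapply(batch, `[[`, "y")), d))
  ybar <- ag_const(set_fmd(do.call(rbind, lapply(batch, `[[`, "ybar")), d))
  g <- decode_graph(tp, y, ybar, mask_vecs_rep, wnodes, cfg$net)
  B <- cfg$net$B
  targets <- do.call(rbind, lapply(batch, `[[`, "target"))
  losses <- vector("list", 2L * B)
  for (k in seq_len(B)) {
    tk <- targets[, k, drop = FALSE]
    losses[[k]] <- ag_mse(tp, g$forward_frames[[k]], tk)
    losses[[B + k]] <- ag_mse(tp, g$backward_frames[[k]], tk)
  }
  w <- c(rep(loss_weights[1] / B, B), rep(loss_weights[2] / B, B))
  list(loss = ag_wsum(tp, losses, w), graph = g)
}

#' Loss of the naive replicated-Ybar predictor on a clip set
#'
#' The training-free reference the decoder must beat: every frame predicted
#' as `Ybar`. Computed in the same normalized units and with the same branch
#' weighting as the training loss.
#'
#' @param clips list of `list(clean, noisy)` clip pairs.
#' @param masks the shared mask set.
#' @param config a [train_config()].
#' @return scalar loss.
#' @export
naive_predictor_loss <- function(clips, masks, config) {
  vals <- vapply(clips, function(clip) {
    p <- prep_clip(clip, masks, config)
    mean((matrix(p$ybar, nrow(p$target), ncol(p$target)) - p$target)^2)
  }, numeric(1))
  sum(config$loss_weights) * mean(vals)
}

#' Train the decoder
#'
#' Seeded Adam optimization of the full decoder on coded measurements of
#' synthetic (or user-supplied) clips, with per-epoch validation, early
#' stopping on a validation plateau, and a full loss history. Training is
#' reproducible: the same `(config, data)` yields identical weights on the
#' same numerical stack.
#'
#' @param config a [train_config()].
#' @param data `list(train, val)` clip sets as returned by
#'   [make_training_set()]; `NULL` synthesizes them from the config.
#' @param masks the shared mask set; `NULL` generates one from the config
#'   seed.
#' @param init_weights optional `tcs_weights` to resume from (the optimizer
#'   moments restart).
#' @param verbose print per-epoch progress.
#' @return list with `weights`, `history` (data.frame: step, split, loss),
#'   `masks`, `naive_val_loss`, `best_val_loss`, and `stopped_early`.
#' @export
train_decoder <- function(config, data = NULL, masks = NULL,
                          init_weights = NULL, verbose = FALSE) {
  if (!inherits(config, "tcs_train_config")) {
    stop_parameter("config must be a tcs_train_config")
  }
  if (is.null(data)) data <- make_training_set(config)
  if (is.null(masks)) {
    masks <- generate_masks(config$B, config$nx, config$ny, seed = config$seed)
  }
  net <- net_config(config$B, base_channels = config$base_channels,
                    kernel_size = config$kernel_size,
                    attention_heads = config$attention_heads,
                    attention_window = config$attention_window,
                    seed = config$seed)
  weights <- if (is.null(init_weights)) init_decoder_weights(net) else init_weights
  check_weight_config(weights, net)

  train_prep <- lapply(data$train, prep_clip, masks = masks, config = config)
  val_prep <- lapply(data$val, prep_clip, masks = masks, config = config)
  n_train <- length(train_prep)
  mask_vec1 <- lapply(seq_len(config$B), function(b) as.vector(masks$masks[, , b]))
  rep_masks <- function(nb) lapply(mask_vec1, function(v) rep(v, nb))
  mask_vecs_batch <- rep_masks(config$batch_size)

  cfg <- list(net = net, nx = config$nx, ny = config$ny)
  flat <- flatten_weight_tree(weights)
  adam <- list(m = lapply(flat, function(x) x * 0),
               v = lapply(flat, function(x) x * 0),
               t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)

  val_loss <- function(w) {
    wn <- wrap_decoder_weights(w, as_param = FALSE)
    chunks <- split(seq_along(val_prep),
                    ceiling(seq_along(val_prep) / max(config$batch_size, 8L)))
    tot <- 0
    for (ch in chunks) {
      tp <- tape_new()
      bl <- batch_loss_graph(tp, val_prep[ch], rep_masks(length(ch)), wn, cfg,
                             config$loss_weights)
      tot <- tot + bl$loss$value * length(ch)
    }
    tot / length(val_prep)
  }

  epoch_len <- ceiling(n_train / config$batch_size)
  history <- vector("list", config$steps + ceiling(config$steps / epoch_len) + 2L)
  hn <- 0L
  push <- function(step, split, loss) {
    hn <<- hn + 1L
    history[[hn]] <<- data.frame(step = step, split = split, loss = loss)
  }
  best_val <- Inf
  best_weights <- weights
  epochs_since_best <- 0L
  stopped_early <- FALSE

  for (step in seq_len(config$steps)) {
    idx <- with_stream_seed(config$seed, 5000000L + step, {
      sample.int(n_train, config$batch_size, replace = n_train < config$batch_size)
    })
    tp <- tape_new()
    wnodes <- wrap_decoder_weights(weights, as_param = TRUE)
    bl <- batch_loss_graph(tp, train_prep[idx], mask_vecs_batch, wnodes, cfg,
                           config$loss_weights)
    if (!is.finite(bl$loss$value)) {
      stop_training(sprintf("non-finite training loss at step %d", step),
                    step = step, history = do.call(rbind, history[seq_len(hn)]))
    }
    push(step, "train", bl$loss$value)
    ag_backward(tp, bl$loss)
    grads <- collect_weight_grads(wnodes)
    adam$t <- adam$t + 1L
    lr_t <- config$learning_rate *
      sqrt(1 - adam$beta2^adam$t) / (1 - adam$beta1^adam$t)
    for (nm in names(flat)) {
      gmat <- grads[[nm]]
      adam$m[[nm]] <- adam$beta1 * adam$m[[nm]] + (1 - adam$beta1) * gmat
      adam$v[[nm]] <- adam$beta2 * adam$v[[nm]] + (1 - adam$beta2) * gmat^2
      flat[[nm]] <- flat[[nm]] - lr_t * adam$m[[nm]] / (sqrt(adam$v[[nm]]) + adam$eps)
    }
    weights <- unflatten_weight_tree(weights, flat)

    if (step %% epoch_len == 0L || step == config$steps) {
      vl <- val_loss(weights)
      push(step, "val", vl)
      if (verbose) {
        message(sprintf("step %5d  train %.5f  val %.5f", step,
                        bl$loss$value, vl))
      }
      if (vl < best_val) {
        best_val <- vl
        best_weights <- weights
        epochs_since_best <- 0L
      } else {
        epochs_since_best <- epochs_since_best + 1L
        if (epochs_since_best > config$patience) {
          stopped_early <- TRUE
          break
        }
      }
    }
  }
  list(weights = best_weights,
       history = do.call(rbind, history[seq_len(hn)]),
       masks = masks,
       naive_val_loss = naive_predictor_loss(data$val, masks, config),
       best_val_loss = best_val,
       stopped_early = stopped_early)
}
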