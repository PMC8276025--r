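# The learned decoder. A measurement and its masks are turned into B frame
# estimates in three stages that share one code path at any frame size:
#
#   1. a 12-unit CNN (two four-layer convolution stages, one three-layer
#      residual block, one self-attention block) maps the concatenation of
#      Ybar with the B approximate coded frames Ybar*C_k to the first frame;
#   2. a forward recurrent chain generates frames 2..B, each cell taking the
#      previous estimate, a two-channel residual input (Ybar plus the
#      measurement residual), and the previous hidden state (zero before the
#      first cell);
#   3. a structurally identical but parameter-disjoint backward chain
#      refines frames B..1 using residuals built from all forward estimates,
#      its hidden chain initialized from the last forward hidden state.
#
# Internally the network runs in normalized units (intensities divided by
# pixel_peak); public entry points rescale at the boundary.

#' Decoder network configuration
#'
#' @param B compression ratio; must match the mask set used.
#' @param base_channels feature-map width of the hidden layers (>= 8).
#' @param kernel_size convolution kernel size (odd).
#' @param attention_heads number of self-attention heads (must divide
#'   `base_channels`).
#' @param attention_window self-attention is computed on non-overlapping
#'   `attention_window^2`-pixel windows to bound memory.
#' @param nonlinearity activation name (only `"relu"` is implemented).
#' @param seed integer seed for weight initialization.
#' @return a list of class `tcs_net_config`.
#' @export
net_config <- function(B, base_channels = 64, kernel_size = 3,
                       attention_heads = 1, attention_window = 16,
                       nonlinearity = "relu", seed = 1L) {
  if (B < 1) stop_configuration("B must be >= 1")
  if (base_channels < 8) stop_configuration("base_channels must be >= 8")
  if (kernel_size %% 2 != 1) stop_configuration("kernel_size must be odd")
  if (base_channels %% attention_heads != 0) {
    stop_configuration("attention_heads must divide base_channels")
  }
  if (!identical(nonlinearity, "relu")) {
    stop_configuration("only the 'relu' nonlinearity is implemented")
  }
  structure(
    list(B = as.integer(B), base_channels = as.integer(base_channels),
         kernel_size = as.integer(kernel_size),
         attention_heads = as.integer(attention_heads),
         attention_window = as.integer(attention_window),
         nonlinearity = nonlinearity, seed = as.integer(seed)),
    class = "tcs_net_config"
  )
}

# Frame-emitting convolutions start near zero (1% of He scale): every frame
# estimate then begins close to 0, so the unrolled residual feedback
# (estimates re-entering later cells through the measurement residuals)
# cannot compound across deep B-step chains at initialization. The layers
# still receive full gradients.
out_gain <- sqrt(2) * 0.01

init_rnn_cell_weights <- function(c, k) {
  out <- init_conv_stack(c(c, c, 1), k)
  out[[2]] <- init_conv(c, 1, k, gain = out_gain)
  list(sub_first = init_conv_stack(c(1, c), k),
       sub_resid = init_conv_stack(c(2, c), k),
       sub_hidden = init_conv_stack(c(c, c), k),
       fuse = init_conv(3 * c, c, k),
       res1 = init_res_block(c, k),
       res2 = init_res_block(c, k),
       out = out)
}

#' Initialize decoder weights
#'
#' Seeded fan-in (He) initialization of every convolution and attention
#' projection; forward and backward recurrent cells are initialized
#' independently (they share structure, never storage).
#'
#' @param config a [net_config()].
#' @return an object of class `tcs_weights` holding `config`, `cnn`,
#'   `forward_rnn`, `backward_rnn` and a `schema_version`.
#' @export
init_decoder_weights <- function(config) {
  c <- config$base_channels
  k <- config$kernel_size
  B <- config$B
  with_stream_seed(config$seed, 101L, {
    stage_out <- init_conv_stack(c(c, c, c, c, 1), k)
    stage_out[[4]] <- init_conv(c, 1, k, gain = out_gain)
    structure(
      list(schema_version = 1L, config = config,
           cnn = list(stage_in = init_conv_stack(c(B + 1L, c, c, c, c), k),
                      res = init_res_block(c, k),
                      attn = init_attention(c),
                      stage_out = stage_out),
           forward_rnn = init_rnn_cell_weights(c, k),
           backward_rnn = init_rnn_cell_weights(c, k)),
      class = "tcs_weights"
    )
  })
}

#' @export
print.tcs_weights <- function(x, ...) {
  cen <- decoder_census(x)
  cat(sprintf("<tcs_weights> B = %d, %d channels, %d parameters; CNN units: %d\n",
              x$config$B, x$config$base_channels, decoder_param_count(x),
              cen$total_units))
  invisible(x)
}

# ---- weight-tree utilities -------------------------------------------------

weight_leaf_names <- c("W", "b", "Wq", "Wk", "Wv", "Wo", "bo")

flatten_weight_tree <- function(w, prefix = "", leaf_test = is.numeric) {
  out <- list()
  nms <- names(w)
  if (is.null(nms)) nms <- rep("", length(w))
  for (i in seq_along(w)) {
    nm <- if (nms[i] == "") as.character(i) else nms[i]
    key <- paste0(prefix, nm)
    el <- w[[i]]
    if (nms[i] %in% weight_leaf_names && leaf_test(el)) {
      out[[key]] <- el
    } else if (is.list(el) && !(nms[i] %in% c("config"))) {
      out <- c(out, flatten_weight_tree(el, paste0(key, "."), leaf_test))
    }
  }
  out
}

unflatten_weight_tree <- function(w, flat, prefix = "") {
  nms <- names(w)
  if (is.null(nms)) nms <- rep("", length(w))
  for (i in seq_along(w)) {
    nm <- if (nms[i] == "") as.character(i) else nms[i]
    key <- paste0(prefix, nm)
    el <- w[[i]]
    if (nms[i] %in% weight_leaf_names && is.numeric(el)) {
      w[[i]] <- flat[[key]]
    } else if (is.list(el) && !(nms[i] %in% c("config"))) {
      w[[i]] <- unflatten_weight_tree(el, flat, paste0(key, "."))
    }
  }
  w
}

wrap_rnn_cell <- function(cell, as_param = TRUE) {
  list(sub_first = wrap_conv_stack(cell$sub_first, as_param),
       sub_resid = wrap_conv_stack(cell$sub_resid, as_param),
       sub_hidden = wrap_conv_stack(cell$sub_hidden, as_param),
       fuse = wrap_conv(cell$fuse, as_param),
       res1 = wrap_res_block(cell$res1, as_param),
       res2 = wrap_res_block(cell$res2, as_param),
       out = wrap_conv_stack(cell$out, as_param))
}

wrap_decoder_weights <- function(w, as_param = TRUE) {
  list(cnn = list(stage_in = wrap_conv_stack(w$cnn$stage_in, as_param),
                  res = wrap_res_block(w$cnn$res, as_param),
                  attn = wrap_attention(w$cnn$attn, as_param),
                  stage_out = wrap_conv_stack(w$cnn$stage_out, as_param)),
       forward_rnn = wrap_rnn_cell(w$forward_rnn, as_param),
       backward_rnn = wrap_rnn_cell(w$backward_rnn, as_param))
}

collect_weight_grads <- function(wnodes) {
  flat <- flatten_weight_tree(wnodes, leaf_test = is.environment)
  lapply(flat, function(nd) {
    if (is.null(nd$grad)) array(0, dim(as.array(nd$value))) else nd$grad
  })
}

#' Architectural census of the first-frame CNN
#'
#' Walks the weight structure and itemizes the CNN into its declared units:
#' plain convolution stages, the residual block (two convolutions plus the
#' skip-add stage), and the self-attention block.
#'
#' @param weights a `tcs_weights` object.
#' @return list with `stage_lengths` (convolutions per plain stage),
#'   `residual_block_layers`, `attention_blocks` and `total_units`.
#' @export
decoder_census <- function(weights) {
  cnn <- weights$cnn
  stage_lengths <- c(length(cnn$stage_in), length(cnn$stage_out))
  res_layers <- length(cnn$res) + 1L  # conv1, conv2, skip-add
  attn_blocks <- as.integer(!is.null(cnn$attn))
  list(stage_lengths = stage_lengths,
       residual_block_layers = res_layers,
       attention_blocks = attn_blocks,
       total_units = sum(stage_lengths) + res_layers + attn_blocks)
}

#' Total number of trainable parameters in a decoder
#'
#' @param weights a `tcs_weights` object.
#' @return integer parameter count.
#' @export
decoder_param_count <- function(weights) {
  sum(vapply(flatten_weight_tree(weights), length, integer(1)))
}

check_weight_config <- function(weights, config) {
  wc <- weights$config
  if (wc$B != config$B || wc$base_channels != config$base_channels ||
      wc$kernel_size != config$kernel_size ||
      wc$attention_heads != config$attention_heads) {
    stop_configuration("weights were initialized for a different net_config")
  }
}

# ---- network graph ---------------------------------------------------------

apply_cnn <- function(tp, stack, wc, cfg) {
  x <- apply_conv_stack(tp, stack, wc$stage_in, relu_last = TRUE)
  x <- apply_res_block(tp, x, wc$res)
  x <- apply_attention(tp, x, wc$attn, cfg$attention_heads, cfg$attention_window)
  apply_conv_stack(tp, x, wc$stage_out, relu_last = FALSE)
}

apply_rnn_cell <- function(tp, first, resid_fm, hidden, wcell, cfg) {
  f1 <- apply_conv_stack(tp, first, wcell$sub_first)
  f2 <- apply_conv_stack(tp, resid_fm, wcell$sub_resid)
  f3 <- apply_conv_stack(tp, hidden, wcell$sub_hidden)
  z <- ag_concat(tp, list(f1, f2, f3))
  z <- ag_relu(tp, apply_conv(tp, z, wcell$fuse))
  z <- apply_res_block(tp, z, wcell$res1)
  h_new <- apply_res_block(tp, z, wcell$res2)
  frame <- apply_conv_stack(tp, h_new, wcell$out, relu_last = FALSE)
  list(frame = frame, hidden = h_new)
}

# Full unrolled decoder graph in normalized units. y, ybar: (H*W*N) x 1
# nodes; mask_vecs: list of B numeric vectors of length H*W*N. Returns node
# lists for both branches and all hidden states.
decode_graph <- function(tp, y, ybar, mask_vecs, wnodes, cfg) {
  d <- fmd(ybar$value)
  B <- cfg$B
  HWN <- nrow(ybar$value)
  coded <- vector("list", B)  # Ybar * C_b (approximate coded frames)
  for (b in seq_len(B)) coded[[b]] <- ag_mulc(tp, ybar, mask_vecs[[b]])
  stack <- ag_concat(tp, c(list(ybar), coded))
  x1 <- apply_cnn(tp, stack, wnodes$cnn, cfg)

  zero_h <- ag_const(set_fmd(matrix(0, HWN, cfg$base_channels), d))
  fwd_frames <- vector("list", B)
  fwd_hidden <- vector("list", B)
  fwd_frames[[1]] <- x1
  fwd_hidden[[1]] <- zero_h
  cfx <- vector("list", B)  # memoized C_t * X~_t^f nodes
  coded_fwd <- function(t) {
    if (is.null(cfx[[t]])) cfx[[t]] <<- ag_mulc(tp, fwd_frames[[t]], mask_vecs[[t]])
    cfx[[t]]
  }
  h <- zero_h
  if (B >= 2L) {
    for (k in 2:B) {
      resid <- y
      for (t in seq_len(k - 1L)) resid <- ag_sub(tp, resid, coded_fwd(t))
      if (k < B) for (t in (k + 1L):B) resid <- ag_sub(tp, resid, coded[[t]])
      resid_fm <- ag_concat(tp, list(ybar, resid))
      cell <- apply_rnn_cell(tp, fwd_frames[[k - 1L]], resid_fm, h,
                             wnodes$forward_rnn, cfg)
      fwd_frames[[k]] <- cell$frame
      h <- cell$hidden
      fwd_hidden[[k]] <- h
    }
  }
  hBf <- h  # zero state when B = 1

  total <- ag_sum_nodes(tp, lapply(seq_len(B), coded_fwd))
  bwd_frames <- vector("list", B)
  bwd_hidden <- vector("list", B)
  h <- hBf
  for (k in seq.int(B, 1L)) {
    resid <- ag_add(tp, ag_sub(tp, y, total), coded_fwd(k))
    resid_fm <- ag_concat(tp, list(ybar, resid))
    first <- if (k == B) fwd_frames[[B]] else bwd_frames[[k + 1L]]
    cell <- apply_rnn_cell(tp, first, resid_fm, h, wnodes$backward_rnn, cfg)
    bwd_frames[[k]] <- cell$frame
    bwd_hidden[[k]] <- cell$hidden
    h <- cell$hidden
  }
  list(forward_frames = fwd_frames, backward_frames = bwd_frames,
       forward_hidden = fwd_hidden, backward_hidden = bwd_hidden, hBf = hBf)
}

# ---- public numeric operations --------------------------------------------

#' Build the CNN input stack
#'
#' Concatenates the normalized measurement with the B approximate coded
#' frames along the channel dimension: channel 1 is `Ybar`, channel `1 + k`
#' is `Ybar * C_k`.
#'
#' @param nm a `tcs_normalized` measurement.
#' @param masks the matching mask set.
#' @return an `nx x ny x (B+1)` array.
#' @export
build_cnn_input <- function(nm, masks) {
  coded <- approx_coded_frames(nm, masks)
  out <- array(0, c(masks$nx, masks$ny, masks$B + 1L))
  out[, , 1] <- nm$ybar
  out[, , 1 + seq_len(masks$B)] <- coded
  out
}

#' Run the first-frame CNN
#'
#' Applies the 12-unit CNN to a `(B+1)`-channel input stack (see
#' [build_cnn_input()]) and returns the first-frame estimate. The stack is
#' scaled by `1 / pixel_peak` on entry and the output rescaled, so the
#' network always operates near the unit interval.
#'
#' @param stack `nx x ny x (B+1)` input array.
#' @param config the [net_config()] the weights were built for.
#' @param weights a `tcs_weights` object.
#' @param pixel_peak intensity scale of the stack (1 if already normalized).
#' @return an `nx x ny` matrix.
#' @export
cnn_first_frame <- function(stack, config, weights, pixel_peak = 1) {
  if (length(dim(stack)) != 3L) stop_dimension("stack must be a 3D array")
  if (dim(stack)[3] != config$B + 1L) {
    stop_configuration(sprintf("stack has %d channels; config B = %d needs %d",
                               dim(stack)[3], config$B, config$B + 1L))
  }
  check_weight_config(weights, config)
  nx <- dim(stack)[1]; ny <- dim(stack)[2]
  tp <- tape_new()
  x <- ag_const(set_fmd(matrix(stack / pixel_peak, nx * ny, dim(stack)[3]),
                        c(nx, ny, 1L)))
  wn <- wrap_decoder_weights(weights, as_param = FALSE)
  out <- apply_cnn(tp, x, wn$cnn, config)
  matrix(out$value * pixel_peak, nx, ny)
}

residual_common_checks <- function(k, m, nm, masks) {
  check_measurement_provenance(m, masks)
  if (nm$b_used != masks$B) stop_provenance("normalized measurement and masks disagree on B")
  if (k < 1 || k > masks$B) stop_state(sprintf("frame index k = %d outside 1..%d", k, masks$B))
}

frames_to_list <- function(frames) {
  if (is.null(frames)) return(list())
  if (is.list(frames)) return(frames)
  if (is.matrix(frames)) return(list(frames))
  lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
}

new_residual_input <- function(ybar, resid, k, direction) {
  structure(
    list(xbb = array(c(ybar, resid), c(nrow(ybar), ncol(ybar), 2L)),
         k = k, direction = direction),
    class = "tcs_residual_input"
  )
}

#' Residual input of the forward recurrent chain
#'
#' For frame k, channel 1 is `Ybar` and channel 2 the measurement residual
#' `Y - sum_(t<k) C_t * X~_t^f - sum_(t>k) C_t * Ybar`: what remains of the
#' measurement once already-estimated frames are explained exactly and
#' not-yet-estimated frames are approximated by `Ybar`. With perfect prior
#' estimates (and for t > k, a constant scene) it telescopes to the true
#' coded frame `C_k * X_k`.
#'
#' @param k frame index in 1..B.
#' @param m the `tcs_measurement`.
#' @param nm its `tcs_normalized` companion.
#' @param masks the mask set.
#' @param prior_frames estimates `X~_1^f .. X~_(k-1)^f` (list, matrix, or
#'   `nx x ny x (k-1)` array).
#' @return a `tcs_residual_input` with a two-channel `xbb` stack.
#' @export
forward_residual_input <- function(k, m, nm, masks, prior_frames = NULL) {
  residual_common_checks(k, m, nm, masks)
  priors <- frames_to_list(prior_frames)
  if (length(priors) != k - 1L) {
    stop_state(sprintf("forward residual at k = %d needs %d prior frame(s), got %d",
                       k, k - 1L, length(priors)))
  }
  resid <- m$y
  for (t in seq_len(k - 1L)) resid <- resid - masks$masks[, , t] * priors[[t]]
  if (k < masks$B) {
    for (t in (k + 1L):masks$B) resid <- resid - masks$masks[, , t] * nm$ybar
  }
  new_residual_input(nm$ybar, resid, k, "forward")
}

#' Residual input of the backward refinement chain
#'
#' For frame k, channel 2 is `Y - sum_(t != k) C_t * X~_t^f`, which equals
#' the true coded frame `C_k * X_k` exactly when every forward estimate is
#' exact (the telescoping identity of the forward model).
#'
#' @inheritParams forward_residual_input
#' @param forward_frames all B forward estimates.
#' @return a `tcs_residual_input`.
#' @export
backward_residual_input <- function(k, m, nm, masks, forward_frames) {
  residual_common_checks(k, m, nm, masks)
  fwd <- frames_to_list(forward_frames)
  if (length(fwd) != masks$B) {
    stop_state(sprintf("backward residual needs all %d forward frames, got %d",
                       masks$B, length(fwd)))
  }
  resid <- m$y
  for (t in seq_len(masks$B)) {
    if (t != k) resid <- resid - masks$masks[, , t] * fwd[[t]]
  }
  new_residual_input(nm$ybar, resid, k, "backward")
}

#' Evaluate one recurrent cell
#'
#' The three input parts (previous frame estimate, two-channel residual
#' input, hidden state) pass through three sub-CNNs, are concatenated and
#' fused, pass through two residual blocks yielding the new hidden unit,
#' and an output sub-CNN emits the frame estimate.
#'
#' @param first_part `nx x ny` matrix: previous frame estimate.
#' @param residual a `tcs_residual_input` (or `nx x ny x 2` array).
#' @param hidden `nx x ny x base_channels` array, or `NULL` for the zero
#'   state.
#' @param config the [net_config()].
#' @param weights_cell one recurrent cell's weights (`weights$forward_rnn`
#'   or `weights$backward_rnn`).
#' @return `list(frame = nx x ny matrix, hidden = nx x ny x base_channels
#'   array)`.
#' @export
rnn_cell <- function(first_part, residual, hidden, config, weights_cell) {
  if (inherits(residual, "tcs_residual_input")) residual <- residual$xbb
  nx <- nrow(first_part); ny <- ncol(first_part)
  if (length(dim(residual)) != 3L || any(dim(residual) != c(nx, ny, 2L))) {
    stop_configuration("residual input must be an nx x ny x 2 stack")
  }
  if (is.null(hidden)) hidden <- array(0, c(nx, ny, config$base_channels))
  if (length(dim(hidden)) != 3L ||
      any(dim(hidden) != c(nx, ny, config$base_channels))) {
    stop_configuration("hidden state must have shape nx x ny x base_channels")
  }
  if (weights_cell$sub_hidden[[1]]$cin != config$base_channels) {
    stop_configuration("cell weights do not match config base_channels")
  }
  d <- c(nx, ny, 1L)
  tp <- tape_new()
  wn <- wrap_rnn_cell(weights_cell, as_param = FALSE)
  cell <- apply_rnn_cell(
    tp,
    ag_const(set_fmd(matrix(first_part, nx * ny, 1L), d)),
    ag_const(set_fmd(matrix(residual, nx * ny, 2L), d)),
    ag_const(set_fmd(matrix(hidden, nx * ny, config$base_channels), d)),
    wn, config)
  list(frame = matrix(cell$frame$value, nx, ny),
       hidden = array(cell$hidden$value, c(nx, ny, config$base_channels)))
}

#' Reconstruct a video block from one coded measurement
#'
#' Runs the full decoder: measurement normalization, the first-frame CNN,
#' the forward recurrent chain (hidden state starting at zero), and the
#' backward refinement chain (hidden chain initialized from the last
#' forward hidden state; its outputs, in ascending frame order, are the
#' final reconstruction). A pure function of `(measurement, masks,
#' weights)`.
#'
#' @param m a `tcs_measurement`.
#' @param masks the mask set that produced `m` (checked).
#' @param weights a `tcs_weights` object whose config B matches.
#' @return `list(video, state)`: the reconstructed [tcs_video()] and a
#'   `tcs_recon_state` with `forward_frames`, `backward_frames` (arrays
#'   `nx x ny x B`, intensity units) and `forward_hidden`,
#'   `backward_hidden` (arrays `nx x ny x base_channels x B`).
#' @export
reconstruct <- function(m, masks, weights) {
  if (!inherits(weights, "tcs_weights")) stop_parameter("weights must be a tcs_weights")
  check_measurement_provenance(m, masks)
  cfg <- weights$config
  if (cfg$B != masks$B) {
    stop_configuration(sprintf("weights built for B = %d; masks have B = %d",
                               cfg$B, masks$B))
  }
  nx <- masks$nx; ny <- masks$ny
  peak <- m$pixel_peak
  # internal re-normalization; zero-coverage pixels are the caller's concern
  # (normalize_measurement() reports and flags them)
  nm <- suppressWarnings(normalize_measurement(m, masks))
  d <- c(nx, ny, 1L)
  tp <- tape_new()
  y <- ag_const(set_fmd(matrix(m$y / peak, nx * ny, 1L), d))
  ybar <- ag_const(set_fmd(matrix(nm$ybar / peak, nx * ny, 1L), d))
  mask_vecs <- lapply(seq_len(cfg$B), function(b) as.vector(masks$masks[, , b]))
  wn <- wrap_decoder_weights(weights, as_param = FALSE)
  g <- decode_graph(tp, y, ybar, mask_vecs, wn, cfg)
  to_arr <- function(nodes) {
    array(vapply(nodes, function(nd) nd$value * peak, numeric(nx * ny)),
          c(nx, ny, cfg$B))
  }
  to_hid <- function(nodes) {
    array(vapply(nodes, function(nd) as.vector(nd$value),
                 numeric(nx * ny * cfg$base_channels)),
          c(nx, ny, cfg$base_channels, cfg$B))
  }
  bwd <- to_arr(g$backward_frames)
  state <- structure(
    list(forward_frames = to_arr(g$forward_frames),
         backward_frames = bwd,
         forward_hidden = to_hid(g$forward_hidden),
         backward_hidden = to_hid(g$backward_hidden)),
    class = "tcs_recon_state"
  )
  list(video = tcs_video(pmax(bwd, 0), peak), state = state)
}
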