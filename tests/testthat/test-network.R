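# Decoder structure, residual-input identities, and the full reconstruction
# contract.

small_setup <- function(B = 3, nx = 8, ny = 8, seed = 5) {
  masks <- generate_masks(B, nx, ny, seed = seed, guarantee_coverage = TRUE)
  video <- tiny_clip(B = B, nx = nx, ny = ny)
  m <- encode(video, masks)
  nm <- normalize_measurement(m, masks)
  list(masks = masks, video = video, m = m, nm = nm)
}

test_that("the CNN input stack is Ybar plus the approximate coded frames", {
  ex <- worked_example()
  m <- encode(ex$video, ex$masks)
  nm <- normalize_measurement(m, ex$masks)
  st <- build_cnn_input(nm, ex$masks)
  expect_equal(dim(st), c(2L, 2L, 3L))  # B = 2 -> 3 channels
  expect_equal(st[, , 1], ex$Ybar)
  expect_equal(st[, , 2], matrix(c(1, 5, 0, 4), 2, 2))
  expect_equal(st[, , 3], matrix(c(0, 5, 6, 0), 2, 2))

  # constant scene with full coverage: channel 0 constant, channel k = c * C_k
  masks <- all_ones_masks(2, 4, 4)
  nmc <- normalize_measurement(encode(tcs_video(array(9, c(4, 4, 2))), masks),
                               masks)
  stc <- build_cnn_input(nmc, masks)
  expect_true(all(stc[, , 1] == 9))
  expect_true(all(stc[, , 2] == 9 * masks$masks[, , 1]))
})

test_that("the first-frame CNN is deterministic and respects the zero construction", {
  s <- small_setup()
  cfg <- net_config(B = 3, base_channels = 8, attention_window = 4, seed = 2)
  w <- init_decoder_weights(cfg)
  st <- build_cnn_input(s$nm, s$masks)
  f1 <- cnn_first_frame(st, cfg, w, pixel_peak = 255)
  expect_equal(dim(f1), c(8L, 8L))
  expect_identical(f1, cnn_first_frame(st, cfg, w, pixel_peak = 255))
  # zero input with a zero-initialized final layer gives exactly zero
  w0 <- w
  w0$cnn$stage_out[[4]]$W[] <- 0
  w0$cnn$stage_out[[4]]$b[] <- 0
  expect_true(all(cnn_first_frame(array(0, c(8, 8, 4)), cfg, w0) == 0))
  expect_error(cnn_first_frame(array(0, c(8, 8, 3)), cfg, w),
               class = "tcs_configuration_error")
})

test_that("decoder parameter count matches the closed-form census sum", {
  cfg <- net_config(B = 4, base_channels = 16, seed = 1)
  w <- init_decoder_weights(cfg)
  c <- 16; k2 <- 9
  conv_p <- function(cin, cout) k2 * cin * cout + cout
  cnn <- conv_p(5, c) + 3 * conv_p(c, c) +      # four-layer input stage
    2 * conv_p(c, c) +                          # residual block
    4 * c * c + c +                             # attention: Wq Wk Wv Wo + bo
    3 * conv_p(c, c) + conv_p(c, 1)             # four-layer output stage
  cell <- conv_p(1, c) + conv_p(2, c) + conv_p(c, c) +  # three sub-CNNs
    conv_p(3 * c, c) +                                  # fusion conv
    4 * conv_p(c, c) +                                  # two residual blocks
    conv_p(c, c) + conv_p(c, 1)                         # output sub-CNN
  expect_equal(decoder_param_count(w), cnn + 2 * cell)
})

test_that("the CNN census introspects to exactly 12 units", {
  w <- init_decoder_weights(net_config(B = 2, base_channels = 8, seed = 3))
  cen <- decoder_census(w)
  expect_equal(cen$stage_lengths, c(4L, 4L))
  expect_equal(cen$residual_block_layers, 3L)
  expect_equal(cen$attention_blocks, 1L)
  expect_equal(cen$total_units, 12L)
})

test_that("forward and backward RNNs share structure but not parameters", {
  w <- init_decoder_weights(net_config(B = 3, base_channels = 8, seed = 4))
  shape_of <- function(cell) lapply(tcsem:::flatten_weight_tree(cell), dim)
  expect_identical(shape_of(w$forward_rnn), shape_of(w$backward_rnn))
  fl_f <- tcsem:::flatten_weight_tree(w$forward_rnn)
  fl_b <- tcsem:::flatten_weight_tree(w$backward_rnn)
  # independent initializations: no shared tensor values (biases start at 0
  # by design, so compare the weight matrices)
  wnames <- grep("\\.W$", names(fl_f), value = TRUE)
  expect_true(all(vapply(wnames, function(nm) !identical(fl_f[[nm]], fl_b[[nm]]),
                         logical(1))))
  # mutating one chain leaves the other untouched
  w2 <- w
  w2$forward_rnn$fuse$W[] <- 0
  expect_false(identical(w2$forward_rnn$fuse$W, w2$backward_rnn$fuse$W))
})

test_that("forward residual inputs match the hand oracle and telescoping identities", {
  ex <- worked_example()
  m <- encode(ex$video, ex$masks)
  nm <- normalize_measurement(m, ex$masks)
  # k = 1, B = 2: residual = Y - C_2 * Ybar = [[1,0],[5,4]]
  r1 <- forward_residual_input(1, m, nm, ex$masks)
  expect_equal(r1$xbb[, , 1], ex$Ybar)
  expect_equal(r1$xbb[, , 2], matrix(c(1, 5, 0, 4), 2, 2))

  # constant scene, priors exactly c: residual = c * C_k
  s <- small_setup()
  const <- tcs_video(array(20, c(8, 8, 3)))
  mc <- encode(const, s$masks)
  nmc <- normalize_measurement(mc, s$masks)
  pri <- list(matrix(20, 8, 8))
  r2 <- forward_residual_input(2, mc, nmc, s$masks, pri)
  expect_equal(r2$xbb[, , 2], 20 * s$masks$masks[, , 2], tolerance = 1e-9)

  # k = B with perfect priors: residual = C_B * X_B exactly
  pri_all <- lapply(1:2, function(t) s$video$frames[, , t])
  rB <- forward_residual_input(3, s$m, s$nm, s$masks, pri_all)
  expect_equal(rB$xbb[, , 2], s$masks$masks[, , 3] * s$video$frames[, , 3],
               tolerance = 1e-9)

  expect_error(forward_residual_input(2, s$m, s$nm, s$masks, NULL),
               class = "tcs_state_error")
  expect_error(forward_residual_input(5, s$m, s$nm, s$masks),
               class = "tcs_state_error")
})

test_that("backward residual inputs recover the exact coded frame from perfect forward estimates", {
  s <- small_setup()
  fwd <- lapply(1:3, function(t) s$video$frames[, , t])
  for (k in 1:3) {
    rk <- backward_residual_input(k, s$m, s$nm, s$masks, fwd)
    expect_equal(rk$xbb[, , 2], s$masks$masks[, , k] * s$video$frames[, , k],
                 tolerance = 1e-9)
  }
  # all-zero forward estimates: residual = Y
  r0 <- backward_residual_input(2, s$m, s$nm, s$masks,
                                lapply(1:3, function(t) matrix(0, 8, 8)))
  expect_equal(r0$xbb[, , 2], s$m$y)
  # worked example: k = 2, forward estimates = Ybar -> Y - C_1 * Ybar
  ex <- worked_example()
  m <- encode(ex$video, ex$masks)
  nm <- normalize_measurement(m, ex$masks)
  rb <- backward_residual_input(2, m, nm, ex$masks, list(ex$Ybar, ex$Ybar))
  expect_equal(rb$xbb[, , 2], matrix(c(0, 5, 6, 0), 2, 2))
  expect_error(backward_residual_input(1, m, nm, ex$masks, list(ex$Ybar)),
               class = "tcs_state_error")
})

test_that("rnn_cell is deterministic with the declared hidden-state shape", {
  cfg <- net_config(B = 3, base_channels = 8, attention_window = 4, seed = 7)
  w <- init_decoder_weights(cfg)
  first <- matrix(runif(64), 8, 8)
  resid <- array(runif(128), c(8, 8, 2))
  out1 <- rnn_cell(first, resid, NULL, cfg, w$forward_rnn)
  out2 <- rnn_cell(first, resid, NULL, cfg, w$forward_rnn)
  expect_identical(out1, out2)
  expect_equal(dim(out1$frame), c(8L, 8L))
  expect_equal(dim(out1$hidden), c(8L, 8L, 8L))
  out3 <- rnn_cell(first, resid, out1$hidden, cfg, w$forward_rnn)
  expect_false(identical(out1$frame, out3$frame))
  expect_error(rnn_cell(first, array(0, c(8, 8, 3)), NULL, cfg, w$forward_rnn),
               class = "tcs_configuration_error")
  expect_error(rnn_cell(first, resid, array(0, c(8, 8, 4)), cfg, w$forward_rnn),
               class = "tcs_configuration_error")
})

test_that("reconstruct returns B frames, is bit-reproducible, and leaves the RNG alone", {
  s <- small_setup()
  cfg <- net_config(B = 3, base_channels = 8, attention_window = 4, seed = 9)
  w <- init_decoder_weights(cfg)
  set.seed(123)
  rng_before <- .Random.seed
  r1 <- reconstruct(s$m, s$masks, w)
  expect_identical(.Random.seed, rng_before)  # pure function, no hidden state
  r2 <- reconstruct(s$m, s$masks, w)
  expect_identical(r1$video$frames, r2$video$frames)
  expect_equal(dim(r1$video$frames), c(8L, 8L, 3L))
  expect_equal(dim(r1$state$forward_frames), c(8L, 8L, 3L))
  expect_equal(dim(r1$state$forward_hidden), c(8L, 8L, 8L, 3L))
  # hidden chain initializations: h_1^f is zero, backward chain starts at h_B^f
  expect_true(all(r1$state$forward_hidden[, , , 1] == 0))
  expect_false(all(r1$state$backward_hidden[, , , 3] == 0))

  # provenance and configuration guards
  other <- generate_masks(3, 8, 8, seed = 99)
  expect_error(reconstruct(s$m, other, w), class = "tcs_provenance_error")
  w4 <- init_decoder_weights(net_config(B = 4, base_channels = 8, seed = 9))
  expect_error(reconstruct(s$m, s$masks, w4), class = "tcs_configuration_error")
})

test_that("residual channels inside reconstruct follow the public residual operations", {
  # the state exposes forward frames; rebuild the backward residual for k = 2
  # from them and check it equals what the internal graph used, by checking
  # the public op on the same inputs is consistent with the telescoping sum
  s <- small_setup()
  cfg <- net_config(B = 3, base_channels = 8, attention_window = 4, seed = 11)
  w <- init_decoder_weights(cfg)
  r <- reconstruct(s$m, s$masks, w)
  fwd <- lapply(1:3, function(t) r$state$forward_frames[, , t])
  rk <- backward_residual_input(2, s$m, s$nm, s$masks, fwd)
  manual <- s$m$y
  for (t in c(1, 3)) manual <- manual - s$masks$masks[, , t] * fwd[[t]]
  expect_equal(rk$xbb[, , 2], manual, tolerance = 1e-9)
})
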