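# The reverse-mode tape and its compiled convolution kernels.

test_that("compiled convolution matches an independent quadruple-loop reference", {
  set.seed(12)
  for (case in list(c(H = 5, W = 4, N = 2, Cin = 3, Cout = 2, k = 3),
                    c(H = 4, W = 4, N = 1, Cin = 1, Cout = 4, k = 3),
                    c(H = 6, W = 3, N = 2, Cin = 2, Cout = 1, k = 5))) {
    H <- case["H"]; W <- case["W"]; N <- case["N"]
    Cin <- case["Cin"]; Cout <- case["Cout"]; k <- case["k"]
    x <- matrix(rnorm(H * W * N * Cin), H * W * N, Cin)
    wm <- matrix(rnorm(k * k * Cin * Cout), k * k * Cin, Cout)
    bias <- rnorm(Cout)
    tp <- tcsem:::tape_new()
    xn <- tcsem:::ag_const(tcsem:::set_fmd(x, c(H, W, N)))
    out <- tcsem:::ag_conv2d(tp, xn, tcsem:::ag_const(wm),
                             tcsem:::ag_const(bias), k)
    ref <- conv2d_reference(x, wm, bias, H, W, N, k)
    expect_equal(as.vector(out$value), as.vector(ref), tolerance = 1e-12)
  }
})

test_that("tape gradients agree with central finite differences", {
  # a small conv -> relu -> conv -> attention -> mse composition
  set.seed(3)
  H <- 4; W <- 4; N <- 1; C <- 4
  x <- matrix(rnorm(H * W * C), H * W, C)
  target <- matrix(rnorm(H * W), H * W, 1)
  w1 <- matrix(rnorm(9 * C * C, sd = 0.3), 9 * C, C)
  w2 <- matrix(rnorm(9 * C * 1, sd = 0.3), 9 * C, 1)
  at <- list(Wq = matrix(rnorm(C * C, sd = 0.3), C, C),
             Wk = matrix(rnorm(C * C, sd = 0.3), C, C),
             Wv = matrix(rnorm(C * C, sd = 0.3), C, C),
             Wo = matrix(rnorm(C * C, sd = 0.3), C, C),
             bo = rnorm(C, sd = 0.1))
  b1 <- rnorm(C, sd = 0.1); b2 <- rnorm(1, sd = 0.1)
  run <- function(w1, b1, w2, b2, at, grad = FALSE) {
    tp <- tcsem:::tape_new()
    mk <- if (grad) tcsem:::ag_param else tcsem:::ag_const
    w1n <- mk(w1); b1n <- mk(b1); w2n <- mk(w2); b2n <- mk(b2)
    atn <- lapply(at, mk)
    xn <- tcsem:::ag_const(tcsem:::set_fmd(x, c(H, W, N)))
    z <- tcsem:::ag_conv2d(tp, xn, w1n, b1n, 3, relu = TRUE)
    z <- tcsem:::apply_attention(tp, z, atn, heads = 2L, win = 2L)
    z <- tcsem:::ag_conv2d(tp, z, w2n, b2n, 3)
    loss <- tcsem:::ag_mse(tp, z, target)
    if (grad) {
      tcsem:::ag_backward(tp, loss)
      return(list(v = loss$value,
                  g = list(w1 = w1n$grad, b1 = b1n$grad, w2 = w2n$grad,
                           b2 = b2n$grad, Wq = atn$Wq$grad, Wo = atn$Wo$grad,
                           bo = atn$bo$grad)))
    }
    loss$value
  }
  an <- run(w1, b1, w2, b2, at, grad = TRUE)
  eps <- 1e-6
  fd_check <- function(get, set, gname, idx) {
    for (j in idx) {
      pp <- get(); pp[j] <- pp[j] + eps
      lp <- do.call(run, set(pp))
      pm <- get(); pm[j] <- pm[j] - eps
      lm <- do.call(run, set(pm))
      fd <- (lp - lm) / (2 * eps)
      expect_equal(an$g[[gname]][j], fd, tolerance = 1e-4)
    }
  }
  fd_check(function() w1, function(p) list(p, b1, w2, b2, at), "w1", c(1, 20, 60))
  fd_check(function() b1, function(p) list(w1, p, w2, b2, at), "b1", c(1, 3))
  fd_check(function() w2, function(p) list(w1, b1, p, b2, at), "w2", c(2, 15))
  fd_check(function() at$Wq,
           function(p) { a <- at; a$Wq <- p; list(w1, b1, w2, b2, a) },
           "Wq", c(1, 7, 16))
  fd_check(function() at$Wo,
           function(p) { a <- at; a$Wo <- p; list(w1, b1, w2, b2, a) },
           "Wo", c(3, 11))
  fd_check(function() at$bo,
           function(p) { a <- at; a$bo <- p; list(w1, b1, w2, b2, a) },
           "bo", c(2, 4))
})

test_that("rnn cell gradients are nonzero and match finite differences on a 4x4 instance", {
  set.seed(6)
  cfg <- net_config(B = 2, base_channels = 8, attention_window = 4, seed = 2)
  cell <- tcsem:::init_rnn_cell_weights(8, 3)
  # move every leaf off the zero-bias ReLU kink so the loss is locally smooth
  flat <- tcsem:::flatten_weight_tree(cell)
  for (nm in names(flat)) flat[[nm]] <- flat[[nm]] + rnorm(length(flat[[nm]]), sd = 0.05)
  cell <- tcsem:::unflatten_weight_tree(cell, flat)
  H <- 4; W <- 4
  first <- matrix(rnorm(H * W), H * W, 1)
  resid <- matrix(rnorm(H * W * 2), H * W, 2)
  hid <- matrix(rnorm(H * W * 8), H * W, 8)
  target <- matrix(rnorm(H * W), H * W, 1)
  run <- function(cell, grad = FALSE) {
    tp <- tcsem:::tape_new()
    cn <- tcsem:::wrap_rnn_cell(cell, as_param = grad)
    d <- c(H, W, 1L)
    out <- tcsem:::apply_rnn_cell(
      tp, tcsem:::ag_const(tcsem:::set_fmd(first, d)),
      tcsem:::ag_const(tcsem:::set_fmd(resid, d)),
      tcsem:::ag_const(tcsem:::set_fmd(hid, d)), cn, cfg)
    loss <- tcsem:::ag_mse(tp, out$frame, target)
    if (grad) {
      tcsem:::ag_backward(tp, loss)
      return(list(v = loss$value, g = tcsem:::collect_weight_grads(cn)))
    }
    loss$value
  }
  an <- run(cell, grad = TRUE)
  # every weight tensor receives gradient
  expect_true(all(vapply(an$g, function(g) sum(abs(g)) > 0, logical(1))))
  set.seed(8)
  eps <- 1e-6
  for (nm in sample(names(flat), 8)) {
    j <- sample(length(flat[[nm]]), 1)
    f <- flat; f[[nm]][j] <- f[[nm]][j] + eps
    lp <- run(tcsem:::unflatten_weight_tree(cell, f))
    f[[nm]][j] <- flat[[nm]][j] - eps
    lm <- run(tcsem:::unflatten_weight_tree(cell, f))
    fd <- (lp - lm) / (2 * eps)
    expect_equal(an$g[[nm]][j], fd, tolerance = 1e-3)
  }
})

test_that("windowed attention preserves shape and is deterministic", {
  set.seed(4)
  H <- 8; W <- 8; C <- 8
  x <- matrix(rnorm(H * W * C), H * W, C)
  at <- tcsem:::init_attention(C)
  tp <- tcsem:::tape_new()
  xn <- tcsem:::ag_const(tcsem:::set_fmd(x, c(H, W, 1L)))
  atn <- lapply(at, tcsem:::ag_const)
  o1 <- tcsem:::apply_attention(tp, xn, atn, heads = 1L, win = 4L)
  o2 <- tcsem:::apply_attention(tcsem:::tape_new(), xn, atn, heads = 1L, win = 4L)
  expect_equal(dim(o1$value), c(H * W, C))
  expect_identical(o1$value, o2$value)
  # window larger than the frame falls back to full attention
  o3 <- tcsem:::apply_attention(tcsem:::tape_new(), xn, atn, heads = 1L,
                                win = 64L)
  expect_equal(dim(o3$value), c(H * W, C))
})
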