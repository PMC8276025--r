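# Weight initialization and the structural building blocks of the decoder:
# plain convolution stacks, residual blocks (two convolutions + identity
# skip), and windowed self-attention. Weight containers are plain nested
# lists of numeric arrays so checkpoints are transparent; graph-building
# functions mirror the same structure with autograd nodes.

# He (fan-in) initialized convolution; biases start at zero.
init_conv <- function(cin, cout, k, gain = sqrt(2)) {
  fan_in <- k * k * cin
  list(W = matrix(stats::rnorm(fan_in * cout, sd = gain / sqrt(fan_in)),
                  fan_in, cout),
       b = rep(0, cout), k = k, cin = cin, cout = cout)
}

init_conv_stack <- function(widths, k) {
  # widths: vector of channel counts length L+1 for an L-layer stack
  lapply(seq_len(length(widths) - 1L), function(i) {
    init_conv(widths[i], widths[i + 1L], k)
  })
}

init_res_block <- function(c, k) {
  list(conv1 = init_conv(c, c, k), conv2 = init_conv(c, c, k))
}

init_attention <- function(c, gain = 1) {
  list(Wq = matrix(stats::rnorm(c * c, sd = gain / sqrt(c)), c, c),
       Wk = matrix(stats::rnorm(c * c, sd = gain / sqrt(c)), c, c),
       Wv = matrix(stats::rnorm(c * c, sd = gain / sqrt(c)), c, c),
       Wo = matrix(stats::rnorm(c * c, sd = 0.1 / sqrt(c)), c, c),
       bo = rep(0, c))
}

# The callers know the weight-tree structure, so node wrapping is done
# explicitly to avoid ambiguity between structural scalars (k, cin, cout)
# and 1-element weight tensors.
wrap_conv <- function(cv, as_param = TRUE) {
  mk <- if (as_param) ag_param else ag_const
  list(W = mk(cv$W), b = mk(cv$b), k = cv$k, cin = cv$cin, cout = cv$cout)
}

wrap_conv_stack <- function(st, as_param = TRUE) {
  lapply(st, wrap_conv, as_param = as_param)
}

wrap_res_block <- function(rb, as_param = TRUE) {
  list(conv1 = wrap_conv(rb$conv1, as_param),
       conv2 = wrap_conv(rb$conv2, as_param))
}

wrap_attention <- function(at, as_param = TRUE) {
  mk <- if (as_param) ag_param else ag_const
  list(Wq = mk(at$Wq), Wk = mk(at$Wk), Wv = mk(at$Wv),
       Wo = mk(at$Wo), bo = mk(at$bo))
}

# ---- graph builders --------------------------------------------------------

apply_conv <- function(tp, x, cv, relu = FALSE) {
  ag_conv2d(tp, x, cv$W, cv$b, cv$k, relu = relu)
}

# L-layer convolution stack with ReLU after every layer except (optionally)
# the last.
apply_conv_stack <- function(tp, x, stack, relu_last = TRUE) {
  for (i in seq_along(stack)) {
    x <- apply_conv(tp, x, stack[[i]], relu = relu_last || i < length(stack))
  }
  x
}

# Residual block: relu(x + conv2(relu(conv1(x)))). Census: two convolutions
# plus the skip-add stage.
apply_res_block <- function(tp, x, rb) {
  z <- apply_conv(tp, x, rb$conv1, relu = TRUE)
  z <- apply_conv(tp, z, rb$conv2)
  ag_relu(tp, ag_add(tp, x, z))
}

# Row indices (into the (H*W*N)-row feature map) of each non-overlapping
# window of each batch sample; rows run H fastest, then W, then N.
window_indices <- function(H, W, N, win) {
  win <- min(win, H, W)
  nwi <- ceiling(H / win)
  nwj <- ceiling(W / win)
  idx <- vector("list", nwi * nwj * N)
  p <- 0L
  for (n in seq_len(N)) {
    for (wj in seq_len(nwj)) {
      for (wi in seq_len(nwi)) {
        is <- (((wi - 1L) * win + 1L):min(wi * win, H))
        js <- (((wj - 1L) * win + 1L):min(wj * win, W))
        p <- p + 1L
        idx[[p]] <- as.integer(outer(is, (js - 1L) * H, "+") + (n - 1L) * H * W)
      }
    }
  }
  idx
}

# Scaled dot-product self-attention over spatial positions, computed on
# non-overlapping windows to bound memory, with a learnable output
# projection and an identity skip.
apply_attention <- function(tp, x, at, heads = 1L, win = 16L) {
  d <- fmd(x$value)
  C <- ncol(x$value)
  if (C %% heads != 0L) stop_configuration("attention heads must divide the channel count")
  dk <- C %/% heads
  idxs <- window_indices(d[1], d[2], d[3], win)
  pieces <- vector("list", length(idxs))
  for (i in seq_along(idxs)) {
    xw <- ag_rows(tp, x, idxs[[i]])
    q <- ag_matmul(tp, xw, at$Wq)
    k <- ag_matmul(tp, xw, at$Wk)
    v <- ag_matmul(tp, xw, at$Wv)
    head_out <- vector("list", heads)
    for (h in seq_len(heads)) {
      jd <- ((h - 1L) * dk + 1L):(h * dk)
      qh <- if (heads == 1L) q else ag_cols(tp, q, jd)
      kh <- if (heads == 1L) k else ag_cols(tp, k, jd)
      vh <- if (heads == 1L) v else ag_cols(tp, v, jd)
      sc <- ag_scale(tp, ag_matmul(tp, qh, kh, transpose_b = TRUE), 1 / sqrt(dk))
      att <- ag_softmax_rows(tp, sc)
      head_out[[h]] <- ag_matmul(tp, att, vh)
    }
    o <- if (heads == 1L) head_out[[1]] else ag_concat(tp, head_out)
    proj <- ag_add_bias_cols(tp, ag_matmul(tp, o, at$Wo), at$bo)
    pieces[[i]] <- ag_add(tp, proj, xw)
  }
  ag_scatter_rows(tp, pieces, idxs, nrow(x$value), d)
}
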