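# Minimal reverse-mode automatic differentiation for the decoder network.
#
# Values are feature maps stored channels-last: a (H*W*N) x C matrix whose
# rows run over rows, then columns, then batch samples, with the spatial
# shape kept in the "fmd" attribute c(H, W, N). Convolutions are evaluated
# as im2col + BLAS matrix products, which is where essentially all the
# compute goes; the tape itself only records lightweight closures.
#
# Nodes are environments: $value, $grad (accumulated during backward),
# $back (closure propagating an incoming gradient to the parents) and
# $needs_grad (whether any ancestor is a parameter, so dead branches of the
# backward pass are skipped). Constants and parameters are off-tape leaf
# nodes; operation nodes are appended to the tape in creation order and the
# backward sweep walks the tape in reverse.

fmd <- function(x) attr(x, "fmd")

set_fmd <- function(x, d) { attr(x, "fmd") <- d; x }

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

new_leaf <- function(value, needs_grad = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$back <- NULL
  nd$needs_grad <- needs_grad
  nd
}

ag_const <- function(value) new_leaf(value, FALSE)
ag_param <- function(value) new_leaf(value, TRUE)

new_op <- function(tp, value, needs_grad, back) {
  nd <- new_leaf(value, needs_grad)
  nd$back <- if (needs_grad) back else NULL
  if (needs_grad) {
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes)) {
      tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    }
    tp$nodes[[tp$n]] <- nd
  }
  nd
}

acc_grad <- function(nd, g) {
  if (!nd$needs_grad) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Backward sweep from a scalar node.
ag_backward <- function(tp, node) {
  node$grad <- 1
  if (tp$n == 0L) return(invisible(NULL))
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$back)) nd$back(nd$grad)
  }
  invisible(NULL)
}

any_grad <- function(...) {
  for (nd in list(...)) if (nd$needs_grad) return(TRUE)
  FALSE
}

# ---- operations ------------------------------------------------------------

# Same-padding 2D convolution. W is a (k*k*Cin) x Cout matrix whose rows run
# over kernel row offset (fastest), kernel column offset, then input channel
# blocks of size Cin per offset; b is a length-Cout bias. The im2col +
# BLAS inner loops are compiled (src/conv.cpp).
ag_conv2d <- function(tp, x, W, b, k, relu = FALSE) {
  d <- fmd(x$value)
  Cin <- ncol(x$value)
  ng <- any_grad(x, W, b)
  fw <- conv2d_forward_cpp(x$value, W$value, b$value, d[1], d[2], d[3], k,
                           keep_patches = W$needs_grad, relu = relu)
  out <- set_fmd(fw$out, d)
  Pptr <- if (W$needs_grad) fw$P else NULL
  nd <- new_op(tp, out, ng, function(g) {
    bw <- conv2d_backward_cpp(Pptr, W$value, g, nd$value, Cin,
                              d[1], d[2], d[3], k,
                              x$needs_grad, W$needs_grad, relu)
    if (W$needs_grad) {
      acc_grad(W, bw$dW)
      acc_grad(b, bw$db)
    }
    if (x$needs_grad) acc_grad(x, set_fmd(bw$dx, d))
  })
  nd
}

ag_relu <- function(tp, x) {
  pos <- x$value > 0
  out <- set_fmd(x$value * pos, fmd(x$value))
  new_op(tp, out, x$needs_grad, function(g) {
    acc_grad(x, g * pos)
  })
}

ag_add <- function(tp, a, b) {
  out <- set_fmd(a$value + b$value, fmd(a$value))
  new_op(tp, out, any_grad(a, b), function(g) {
    acc_grad(a, g)
    acc_grad(b, g)
  })
}

ag_sub <- function(tp, a, b) {
  out <- set_fmd(a$value - b$value, fmd(a$value))
  new_op(tp, out, any_grad(a, b), function(g) {
    acc_grad(a, g)
    acc_grad(b, -g)
  })
}

# Element-wise product with a constant (mask) vector/matrix, recycled over
# columns of the feature map.
ag_mulc <- function(tp, x, const) {
  cv <- as.vector(const)
  out <- set_fmd(x$value * cv, fmd(x$value))
  new_op(tp, out, x$needs_grad, function(g) {
    acc_grad(x, set_fmd(g * cv, fmd(x$value)))
  })
}

ag_concat <- function(tp, nodes) {
  out <- do.call(cbind, lapply(nodes, function(nd) nd$value))
  out <- set_fmd(out, fmd(nodes[[1]]$value))
  widths <- vapply(nodes, function(nd) ncol(nd$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ng <- any(vapply(nodes, function(nd) nd$needs_grad, logical(1)))
  new_op(tp, out, ng, function(g) {
    for (i in seq_along(nodes)) {
      gi <- g[, starts[i]:ends[i], drop = FALSE]
      acc_grad(nodes[[i]], set_fmd(gi, fmd(nodes[[i]]$value)))
    }
  })
}

ag_rows <- function(tp, x, idx) {
  out <- x$value[idx, , drop = FALSE]
  new_op(tp, out, x$needs_grad, function(g) {
    gx <- matrix(0, nrow(x$value), ncol(x$value))
    gx[idx, ] <- g
    acc_grad(x, set_fmd(gx, fmd(x$value)))
  })
}

ag_cols <- function(tp, x, jdx) {
  out <- x$value[, jdx, drop = FALSE]
  new_op(tp, out, x$needs_grad, function(g) {
    gx <- matrix(0, nrow(x$value), ncol(x$value))
    gx[, jdx] <- g
    acc_grad(x, gx)
  })
}

# Reassemble row-blocks produced per window/sample into a full feature map.
ag_scatter_rows <- function(tp, pieces, idxs, nrow_total, d) {
  C <- ncol(pieces[[1]]$value)
  out <- matrix(0, nrow_total, C)
  for (i in seq_along(pieces)) out[idxs[[i]], ] <- pieces[[i]]$value
  out <- set_fmd(out, d)
  ng <- any(vapply(pieces, function(nd) nd$needs_grad, logical(1)))
  new_op(tp, out, ng, function(g) {
    for (i in seq_along(pieces)) {
      acc_grad(pieces[[i]], g[idxs[[i]], , drop = FALSE])
    }
  })
}

ag_matmul <- function(tp, a, b, transpose_b = FALSE) {
  out <- if (transpose_b) tcrossprod(a$value, b$value) else a$value %*% b$value
  new_op(tp, out, any_grad(a, b), function(g) {
    if (transpose_b) {
      if (a$needs_grad) acc_grad(a, g %*% b$value)
      if (b$needs_grad) acc_grad(b, crossprod(g, a$value))
    } else {
      if (a$needs_grad) acc_grad(a, tcrossprod(g, b$value))
      if (b$needs_grad) acc_grad(b, crossprod(a$value, g))
    }
  })
}

ag_scale <- function(tp, x, s) {
  out <- set_fmd(x$value * s, fmd(x$value))
  new_op(tp, out, x$needs_grad, function(g) acc_grad(x, set_fmd(g * s, fmd(x$value))))
}

ag_add_bias_cols <- function(tp, x, b) {
  out <- set_fmd(x$value + rep(b$value, each = nrow(x$value)), fmd(x$value))
  new_op(tp, out, any_grad(x, b), function(g) {
    acc_grad(x, g)
    if (b$needs_grad) acc_grad(b, colSums(g))
  })
}

ag_softmax_rows <- function(tp, x) {
  v <- exp(x$value - apply(x$value, 1, max))
  s <- v / rowSums(v)
  new_op(tp, s, x$needs_grad, function(g) {
    acc_grad(x, (g - rowSums(g * s)) * s)
  })
}

# Mean squared error against a constant target; returns a scalar node.
ag_mse <- function(tp, x, target) {
  diff <- x$value - target
  out <- mean(diff^2)
  new_op(tp, out, x$needs_grad, function(g) {
    acc_grad(x, set_fmd(g * 2 * diff / length(diff), fmd(x$value)))
  })
}

# Weighted sum of scalar nodes.
ag_wsum <- function(tp, nodes, w) {
  vals <- vapply(nodes, function(nd) nd$value, numeric(1))
  out <- sum(vals * w)
  ng <- any(vapply(nodes, function(nd) nd$needs_grad, logical(1)))
  new_op(tp, out, ng, function(g) {
    for (i in seq_along(nodes)) acc_grad(nodes[[i]], g * w[i])
  })
}

# Sum of a list of feature-map nodes (used for telescoping mask sums).
ag_sum_nodes <- function(tp, nodes) {
  out <- nodes[[1]]$value
  if (length(nodes) > 1L) {
    for (i in 2:length(nodes)) out <- out + nodes[[i]]$value
  }
  out <- set_fmd(out, fmd(nodes[[1]]$value))
  ng <- any(vapply(nodes, function(nd) nd$needs_grad, logical(1)))
  new_op(tp, out, ng, function(g) {
    for (nd in nodes) acc_grad(nd, g)
  })
}
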