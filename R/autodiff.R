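# Minimal define-by-run reverse-mode autodifferentiation.
#
# A forward pass builds a tape of nodes in creation order (which is a valid
# topological order); `tape_backward()` walks it in reverse. Heavy operators
# (convolution, pooling, resampling) call the compiled kernels in src/.
# Feature maps are (H, W, C) arrays; 3D features are (H, W, D, C); channel
# descriptors are plain vectors. Running with `tape = NULL` gives a
# gradient-free forward pass (prediction).

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  t
}

tape_record <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

nd_leaf <- function(tape, value, name = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$name <- name
  node$backward <- NULL
  if (!is.null(tape)) tape_record(tape, node)
  node
}

nd_op <- function(tape, value, backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$name <- NULL
  if (!is.null(tape)) {
    node$backward <- backward
    tape_record(tape, node)
  } else {
    node$backward <- NULL
  }
  node
}

nd_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

#' @noRd
tape_backward <- function(tape, root, seed_grad = 1) {
  root$grad <- seed_grad
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node)
  }
  invisible(tape)
}

# Collect gradients of named leaves into a named list.
tape_param_grads <- function(tape) {
  out <- list()
  for (i in seq_len(tape$n)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$name) && !is.null(node$grad)) out[[node$name]] <- node$grad
  }
  out
}

# ---- primitive ops ---------------------------------------------------------

op_conv2d <- function(tape, x, W, b, k) {
  r <- .cpp_conv2d_fw(x$value, dim(x$value), W$value, b$value, as.integer(k),
                      !is.null(tape))
  nd_op(tape, r$out, function(node) {
    bw <- .cpp_conv2d_bw(r$cols, dim(x$value), W$value, node$grad, as.integer(k))
    nd_accum(x, bw$dx)
    nd_accum(W, bw$dW)
    nd_accum(b, as.numeric(bw$db))
  })
}

op_conv3d <- function(tape, x, W, b, k) {
  r <- .cpp_conv3d_fw(x$value, dim(x$value), W$value, b$value, as.integer(k),
                      !is.null(tape))
  nd_op(tape, r$out, function(node) {
    bw <- .cpp_conv3d_bw(r$cols, dim(x$value), W$value, node$grad, as.integer(k))
    nd_accum(x, bw$dx)
    nd_accum(W, bw$dW)
    nd_accum(b, as.numeric(bw$db))
  })
}

op_linear <- function(tape, v, W, b) {
  y <- as.numeric(v$value %*% W$value) + b$value
  nd_op(tape, y, function(node) {
    g <- node$grad
    nd_accum(v, as.numeric(W$value %*% g))
    nd_accum(W, outer(v$value, g))
    nd_accum(b, g)
  })
}

op_relu <- function(tape, x) {
  y <- x$value
  y[y < 0] <- 0
  nd_op(tape, y, function(node) {
    g <- node$grad
    g[x$value <= 0] <- 0
    nd_accum(x, g)
  })
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  nd_op(tape, y, function(node) nd_accum(x, node$grad * y * (1 - y)))
}

op_add <- function(tape, a, b) {
  nd_op(tape, a$value + b$value, function(node) {
    nd_accum(a, node$grad)
    nd_accum(b, node$grad)
  })
}

# x: (H, W, C); m: (H, W) single-channel weight map broadcast over channels.
op_mul_map <- function(tape, x, m) {
  d <- dim(x$value)
  mv <- as.numeric(m$value)
  y <- x$value * mv  # recycles over the channel dimension
  nd_op(tape, y, function(node) {
    g <- node$grad
    nd_accum(x, g * mv)
    dm <- rowSums(matrix(g * x$value, prod(d[1:2]), d[3]))
    dim(dm) <- d[1:2]
    nd_accum(m, dm)
  })
}

# x: (H, W, C); w: length-C channel weight vector.
op_mul_chan <- function(tape, x, w) {
  d <- dim(x$value)
  hw <- prod(d[1:2])
  wr <- rep(w$value, each = hw)
  y <- x$value * wr
  nd_op(tape, y, function(node) {
    g <- node$grad
    nd_accum(x, g * wr)
    nd_accum(w, colSums(matrix(g * x$value, hw, d[3])))
  })
}

# Concatenate along the trailing (channel) dimension.
op_concat <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  d0 <- dim(vals[[1]])
  nd <- length(d0)
  chans <- vapply(vals, function(v) dim(v)[nd], numeric(1))
  out <- array(unlist(vals, use.names = FALSE), dim = c(d0[-nd], sum(chans)))
  nd_op(tape, out, function(node) {
    g <- node$grad
    block <- prod(d0[-nd])
    off <- 0L
    for (t in seq_along(nodes)) {
      len <- block * chans[t]
      gt <- g[(off + 1):(off + len)]
      dim(gt) <- c(d0[-nd], chans[t])
      nd_accum(nodes[[t]], gt)
      off <- off + len
    }
  })
}

op_maxpool2 <- function(tape, x) {
  r <- .cpp_maxpool2_fw(x$value, dim(x$value))
  nd_op(tape, r$out, function(node) {
    dx <- .cpp_maxpool2_bw(node$grad, r$arg, length(x$value))
    dim(dx) <- dim(x$value)
    nd_accum(x, dx)
  })
}

op_upsample2 <- function(tape, x) {
  d <- dim(x$value)
  y <- .cpp_resize_bilinear(x$value, d, 2L * d[1], 2L * d[2])
  nd_op(tape, y, function(node) {
    nd_accum(x, .cpp_resize_bilinear_bw(node$grad, dim(node$grad), d[1], d[2]))
  })
}

op_reshape <- function(tape, x, newdim) {
  y <- x$value
  dim(y) <- newdim
  nd_op(tape, y, function(node) {
    g <- node$grad
    dim(g) <- dim(x$value)
    nd_accum(x, g)
  })
}

# Instance normalization: per-channel over all leading (spatial) dims.
op_instnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[length(d)]
  N <- prod(d[-length(d)])
  m <- matrix(x$value, N, C)
  mu <- colMeans(m)
  va <- colMeans(m * m) - mu * mu
  va[va < 0] <- 0
  invstd <- 1 / sqrt(va + eps)
  xhat <- (m - rep(mu, each = N)) * rep(invstd, each = N)
  y <- xhat * rep(gamma$value, each = N) + rep(beta$value, each = N)
  dim(y) <- d
  nd_op(tape, y, function(node) {
    gm <- matrix(node$grad, N, C)
    nd_accum(gamma, colSums(gm * xhat))
    nd_accum(beta, colSums(gm))
    dxhat <- gm * rep(gamma$value, each = N)
    t1 <- rep(colMeans(dxhat), each = N)
    t2 <- xhat * rep(colMeans(dxhat * xhat), each = N)
    dx <- rep(invstd, each = N) * (dxhat - t1 - t2)
    dim(dx) <- d
    nd_accum(x, dx)
  })
}

# Global average pool over all leading dims -> length-C vector.
op_gap <- function(tape, x) {
  d <- dim(x$value)
  C <- d[length(d)]
  N <- prod(d[-length(d)])
  y <- colMeans(matrix(x$value, N, C))
  nd_op(tape, y, function(node) {
    dx <- rep(node$grad / N, each = N)
    dim(dx) <- d
    nd_accum(x, dx)
  })
}

# Global max pool over all leading dims -> length-C vector.
op_gmp <- function(tape, x) {
  d <- dim(x$value)
  C <- d[length(d)]
  N <- prod(d[-length(d)])
  m <- matrix(x$value, N, C)
  arg <- max.col(t(m), ties.method = "first")
  y <- m[cbind(arg, seq_len(C))]
  nd_op(tape, y, function(node) {
    dx <- array(0, dim = d)
    dxm <- matrix(dx, N, C)
    dxm[cbind(arg, seq_len(C))] <- node$grad
    dim(dxm) <- d
    nd_accum(x, dxm)
  })
}

# Soft Dice loss node: y is a fixed binary array, yhat a probability node.
op_dice_loss <- function(tape, yhat, y, eps = 1e-6) {
  num <- 2 * sum(y * yhat$value) + eps
  den <- sum(y) + sum(yhat$value) + eps
  loss <- 1 - num / den
  nd_op(tape, loss, function(node) {
    d <- (num - 2 * y * den) / (den * den)
    dim(d) <- dim(yhat$value)
    nd_accum(yhat, node$grad * d)
  })
}
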