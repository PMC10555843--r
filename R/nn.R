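# Minimal reverse-mode autodiff over 4-D feature maps [H, W, C, N].
#
# The network graph is rebuilt at every forward pass: ops append nodes to a
# tape and register backward closures; ad_backward() walks the tape in
# reverse, accumulating gradients into parent nodes.  Leaves (parameters and
# the input) receive gradients in their $grad slot.  This is deliberately
# small: only the operations the denoising network needs are implemented.

ad_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$tape <- vector("list", 256L)
  g$n <- 0L
  g
}

ad_node <- function(g, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  g$n <- g$n + 1L
  if (g$n > length(g$tape)) g$tape <- c(g$tape, vector("list", length(g$tape)))
  g$tape[[g$n]] <- nd
  nd
}

ad_leaf <- function(g, value) ad_node(g, value)

# Backpropagate from `root`, seeding its gradient with `seed` (same shape as
# root$value, or a scalar for scalar roots).
ad_backward <- function(g, root, seed = 1) {
  root$grad <- seed
  for (i in rev(seq_len(g$n))) {
    nd <- g$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (is.null(gs[[j]])) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    nd$grad <- NULL  # free memory early
  }
  invisible(NULL)
}

# --- broadcasting helpers (per-channel scale/shift over [H,W,C,N]) --------

ch_scale <- function(x, s) {
  hw <- prod(dim(x)[1:2])
  x * rep(s, each = hw)
}

ch_sum <- function(x) {
  d <- dim(x)
  m <- matrix(colSums(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
  rowSums(m)
}

# --- operations -----------------------------------------------------------

# 2-D convolution, optionally with a fixed multiplicative kernel mask.  The
# mask is applied to the weights at every evaluation, so the effective
# masked coefficients are zero regardless of the stored parameter values,
# and their gradients are zeroed the same way.
op_conv <- function(g, x, w, b, k, dil = 1L, mask = NULL,
                    need_input_grad = TRUE) {
  weff <- if (is.null(mask)) w$value else w$value * mask
  y <- cpp_conv2d_fw(x$value, weff, b$value, as.integer(k), as.integer(dil))
  xv <- x$value
  ad_node(g, y, list(x, w, b), function(gy) {
    r <- cpp_conv2d_bw(xv, weff, gy, as.integer(k), as.integer(dil),
                       need_input_grad)
    gw <- if (is.null(mask)) r$gw else r$gw * mask
    list(if (need_input_grad) r$gx else NULL, gw, as.numeric(r$gb))
  })
}

op_lrelu <- function(g, x, slope = 0.1) {
  v <- x$value
  ad_node(g, cpp_lrelu_fw(v, slope), list(x), function(gy) {
    list(cpp_lrelu_bw(v, gy, slope))
  })
}

# Batch normalisation over (H, W, N) per channel.  `state` is an environment
# carrying running_mean / running_var (updated as a side effect in training
# mode) and eps/momentum.
op_bn <- function(g, x, gamma, beta, state, training) {
  v <- x$value
  d <- dim(v)
  hw <- d[1] * d[2]
  m <- hw * d[4]
  if (training) {
    xm <- matrix(v, nrow = hw)
    mu <- rowMeans(matrix(colMeans(xm), d[3], d[4]))
    m2 <- rowMeans(matrix(colMeans(xm * xm), d[3], d[4]))
    va <- pmax(m2 - mu^2, 0)
    state$running_mean <- (1 - state$momentum) * state$running_mean +
      state$momentum * mu
    state$running_var <- (1 - state$momentum) * state$running_var +
      state$momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + state$eps)
  xhat <- ch_scale(sweep_ch(v, mu), inv)
  y <- sweep_ch(ch_scale(xhat, gamma$value), -beta$value)
  ad_node(g, y, list(x, gamma, beta), function(gy) {
    dgamma <- ch_sum(gy * xhat)
    dbeta <- ch_sum(gy)
    dxhat <- ch_scale(gy, gamma$value)
    if (training) {
      gx <- ch_scale(
        sweep_ch(dxhat, ch_sum(dxhat) / m) -
          ch_scale(xhat, gamma$value * dgamma / m),
        inv)
    } else {
      gx <- ch_scale(dxhat, inv)
    }
    list(gx, dgamma, dbeta)
  })
}

# subtract per-channel vector: x - s[c]
sweep_ch <- function(x, s) {
  hw <- prod(dim(x)[1:2])
  x - rep(s, each = hw)
}

op_maxpool <- function(g, x) {
  r <- cpp_maxpool2_fw(x$value)
  H <- dim(x$value)[1]; W <- dim(x$value)[2]
  ad_node(g, r$y, list(x), function(gy) {
    list(cpp_maxpool2_bw(r$idx, gy, H, W))
  })
}

op_upsample <- function(g, x) {
  ad_node(g, cpp_upsample2_fw(x$value), list(x), function(gy) {
    list(cpp_upsample2_bw(gy))
  })
}

# concatenate along the channel axis
op_concat <- function(g, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  d <- dim(vals[[1]])
  Cs <- vapply(vals, function(v) dim(v)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(Cs), d[4]))
  hi <- cumsum(Cs)
  lo <- hi - Cs + 1L
  for (i in seq_along(vals)) out[, , lo[i]:hi[i], ] <- vals[[i]]
  ad_node(g, out, nodes, function(gy) {
    lapply(seq_along(nodes), function(i) gy[, , lo[i]:hi[i], , drop = FALSE])
  })
}

op_slice_ch <- function(g, x, idx) {
  d <- dim(x$value)
  y <- x$value[, , idx, , drop = FALSE]
  ad_node(g, y, list(x), function(gy) {
    gx <- array(0, d)
    gx[, , idx, ] <- gy
    list(gx)
  })
}

op_add <- function(g, a, b) {
  ad_node(g, a$value + b$value, list(a, b), function(gy) list(gy, gy))
}

# zero-pad bottom/right to (H2, W2); inverse crop for backward
op_pad_br <- function(g, x, H2, W2) {
  d <- dim(x$value)
  if (H2 == d[1] && W2 == d[2]) return(x)
  y <- array(0, c(H2, W2, d[3], d[4]))
  y[seq_len(d[1]), seq_len(d[2]), , ] <- x$value
  ad_node(g, y, list(x), function(gy) {
    list(gy[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE])
  })
}

op_crop <- function(g, x, H, W) {
  d <- dim(x$value)
  if (H == d[1] && W == d[2]) return(x)
  y <- x$value[seq_len(H), seq_len(W), , , drop = FALSE]
  ad_node(g, y, list(x), function(gy) {
    gx <- array(0, d)
    gx[seq_len(H), seq_len(W), , ] <- gy
    list(gx)
  })
}

# weighted L1/L2 regression loss against a fixed target array
op_l1l2_loss <- function(g, pred, target, alpha) {
  r <- pred$value - target
  n <- length(r)
  val <- alpha * mean(abs(r)) + (1 - alpha) * mean(r * r)
  ad_node(g, val, list(pred), function(gy) {
    list(gy * (alpha * sign(r) / n + 2 * (1 - alpha) * r / n))
  })
}
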