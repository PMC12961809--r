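#' @useDynLib gliomaseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode autodiff over 4-d arrays (H, W, C, N).
#
# Nodes are environments holding $value, $grad, $parents and a $backward
# closure that receives the upstream gradient and pushes contributions into
# the parents.  A "tape" (active during a training forward pass) records
# every intermediate node in creation order; backpropagation walks it in
# reverse, which is a valid topological order.  Parameters are leaf nodes
# created off-tape; their gradients accumulate across the pass and are
# consumed by the optimizer.
# ---------------------------------------------------------------------------

.tg <- new.env(parent = emptyenv())
.tg$tape <- NULL

tg_tape_start <- function() {
  .tg$tape <- vector("list", 256L)
  .tg$n <- 0L
  invisible(NULL)
}

tg_tape_stop <- function() {
  .tg$tape <- NULL
  .tg$n <- 0L
  invisible(NULL)
}

tg_node <- function(value, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$requires <- !is.null(backward) &&
    any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  if (!is.null(.tg$tape)) {
    .tg$n <- .tg$n + 1L
    if (.tg$n > length(.tg$tape)) .tg$tape <- c(.tg$tape, vector("list", length(.tg$tape)))
    .tg$tape[[.tg$n]] <- n
  }
  n
}

tg_param <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- list()
  n$backward <- NULL
  n$requires <- TRUE
  n
}

tg_const <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- list()
  n$backward <- NULL
  n$requires <- FALSE
  n
}

tg_acc <- function(node, g) {
  if (!isTRUE(node$requires)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the active tape.
tg_backward <- function(loss) {
  stopifnot(!is.null(.tg$tape))
  loss$grad <- 1
  for (i in rev(seq_len(.tg$n))) {
    nd <- .tg$tape[[i]]
    if (isTRUE(nd$requires) && !is.null(nd$grad) && !is.null(nd$backward)) {
      nd$backward(nd$grad)
    }
  }
  invisible(NULL)
}

# --- primitive ops ---------------------------------------------------------

tg_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  y <- .conv2d_fwd(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  tg_node(y, list(x, w, b), function(g) {
    gr <- .conv2d_bwd(x$value, w$value, g, as.integer(stride), as.integer(pad))
    tg_acc(x, gr$dx); tg_acc(w, gr$dw); tg_acc(b, gr$db)
  })
}

tg_maxpool2 <- function(x) {
  f <- .maxpool2_fwd(x$value)
  xdim <- dim(x$value)
  tg_node(f$y, list(x), function(g) {
    tg_acc(x, .maxpool2_bwd(g, f$idx, xdim))
  })
}

tg_avgpool <- function(x, k) {
  if (k == 1L) return(x)
  xdim <- dim(x$value)
  tg_node(.avgpool_fwd(x$value, as.integer(k)), list(x), function(g) {
    tg_acc(x, .avgpool_bwd(g, as.integer(k), xdim))
  })
}

tg_bilinear <- function(x, ho, wo) {
  xdim <- dim(x$value)
  tg_node(.bilinear_fwd(x$value, as.integer(ho), as.integer(wo)), list(x), function(g) {
    tg_acc(x, .bilinear_bwd(g, xdim))
  })
}

tg_relu <- function(x) {
  pos <- x$value > 0
  tg_node(x$value * pos, list(x), function(g) tg_acc(x, g * pos))
}

tg_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  tg_node(s, list(x), function(g) tg_acc(x, g * s * (1 - s)))
}

tg_add <- function(a, b) {
  tg_node(a$value + b$value, list(a, b), function(g) {
    tg_acc(a, g); tg_acc(b, g)
  })
}

# Multiply feature map x (H,W,C,N) by per-channel gains s (C x N matrix).
tg_scale_channels <- function(x, s) {
  d <- dim(x$value)
  sx <- array(rep(s$value, each = d[1] * d[2]), dim = d)
  tg_node(x$value * sx, list(x, s), function(g) {
    tg_acc(x, g * sx)
    gs <- matrix(colSums(matrix(g * x$value, nrow = d[1] * d[2])), nrow = d[3])
    tg_acc(s, gs)
  })
}

# Multiply feature map x (H,W,C,N) by a spatial map m (H,W,1,N).
tg_scale_spatial <- function(x, m) {
  d <- dim(x$value)
  mx <- array(m$value[, , rep(1L, d[3]), , drop = FALSE], dim = d)
  tg_node(x$value * mx, list(x, m), function(g) {
    tg_acc(x, g * mx)
    gm <- array(rowSums(aperm(array(g * x$value, dim = d), c(1, 2, 4, 3)), dims = 3),
                dim = c(d[1], d[2], 1, d[4]))
    tg_acc(m, gm)
  })
}

tg_concat_c <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  d <- c(d1[1], d1[2], sum(cs), d1[4])
  out <- array(0, dim = d)
  at <- 0L
  for (i in seq_along(vals)) {
    out[, , at + seq_len(cs[i]), ] <- vals[[i]]
    at <- at + cs[i]
  }
  tg_node(out, nodes, function(g) {
    at <- 0L
    for (i in seq_along(nodes)) {
      tg_acc(nodes[[i]], array(g[, , at + seq_len(cs[i]), , drop = FALSE],
                               dim = dim(nodes[[i]]$value)))
      at <- at + cs[i]
    }
  })
}

# Global average pool over H,W -> C x N matrix.
tg_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  v <- matrix(colMeans(matrix(x$value, nrow = hw)), nrow = d[3])
  tg_node(v, list(x), function(g) {
    tg_acc(x, array(rep(g / hw, each = hw), dim = d))
  })
}

# Global max pool over H,W -> C x N matrix.
tg_gmp <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  xm <- matrix(x$value, nrow = hw)
  idx <- max.col(t(xm), ties.method = "first") # argmax per (c,n) column
  v <- matrix(xm[cbind(idx, seq_along(idx))], nrow = d[3])
  tg_node(v, list(x), function(g) {
    dx <- matrix(0, nrow = hw, ncol = d[3] * d[4])
    dx[cbind(idx, seq_along(idx))] <- as.vector(g)
    tg_acc(x, array(dx, dim = d))
  })
}

# Dense layer on C x N column matrices: y = W %*% x + b.
tg_dense <- function(x, w, b) {
  y <- w$value %*% x$value + b$value
  tg_node(y, list(x, w, b), function(g) {
    tg_acc(x, crossprod(w$value, g))
    tg_acc(w, tcrossprod(g, x$value))
    tg_acc(b, rowSums(g))
  })
}

tg_add_mat <- function(a, b) tg_add(a, b)

# Per-pixel mean and max across channels -> (H,W,1,N); used by spatial attention.
tg_channel_mean <- function(x) {
  d <- dim(x$value)
  v <- array(rowMeans(aperm(x$value, c(1, 2, 4, 3)), dims = 3), dim = c(d[1], d[2], 1, d[4]))
  tg_node(v, list(x), function(g) {
    tg_acc(x, array(g[, , rep(1L, d[3]), , drop = FALSE], dim = d) / d[3])
  })
}

tg_channel_max <- function(x) {
  d <- dim(x$value)
  xm <- matrix(aperm(x$value, c(3, 1, 2, 4)), nrow = d[3]) # channel-first columns
  idx <- max.col(t(xm), ties.method = "first")
  v <- array(xm[cbind(idx, seq_along(idx))], dim = c(d[1], d[2], 1, d[4]))
  tg_node(v, list(x), function(g) {
    dxm <- matrix(0, nrow = d[3], ncol = d[1] * d[2] * d[4])
    dxm[cbind(idx, seq_along(idx))] <- as.vector(g)
    tg_acc(x, aperm(array(dxm, dim = c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4)))
  })
}

# Batch normalization over (H,W,N) per channel.  `bn` is a stateful list env
# with running_mean / running_var updated in training mode.
tg_batchnorm <- function(x, gamma, beta, bn, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  C <- d[3]; N <- d[4]
  m <- hw * N
  xm <- matrix(colMeans(matrix(x$value, nrow = hw)), nrow = C) # C x N per-sample means
  if (training) {
    mu <- rowMeans(xm)
    # per-channel variance over all (H,W,N)
    sq <- matrix(colMeans(matrix(x$value^2, nrow = hw)), nrow = C)
    va <- rowMeans(sq) - mu^2
    va <- pmax(va, 0)
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * va * m / max(m - 1, 1)
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
  }
  inv <- 1 / sqrt(va + eps)
  mu_b <- array(rep(mu, each = hw), dim = c(d[1], d[2], C, 1))[, , , rep(1L, N), drop = FALSE]
  dim(mu_b) <- d
  inv_b <- array(rep(inv, each = hw), dim = c(d[1], d[2], C, 1))[, , , rep(1L, N), drop = FALSE]
  dim(inv_b) <- d
  xhat <- (x$value - mu_b) * inv_b
  g_b <- array(rep(gamma$value, each = hw), dim = c(d[1], d[2], C, 1))[, , , rep(1L, N), drop = FALSE]
  dim(g_b) <- d
  b_b <- array(rep(beta$value, each = hw), dim = c(d[1], d[2], C, 1))[, , , rep(1L, N), drop = FALSE]
  dim(b_b) <- d
  y <- g_b * xhat + b_b
  tg_node(y, list(x, gamma, beta), function(g) {
    per_ch <- function(a) { # sum over (H,W,N) per channel
      rowSums(matrix(colSums(matrix(a, nrow = hw)), nrow = C))
    }
    dgamma <- per_ch(g * xhat)
    dbeta <- per_ch(g)
    tg_acc(gamma, dgamma)
    tg_acc(beta, dbeta)
    if (training) {
      dxhat <- g * g_b
      s1 <- per_ch(dxhat)
      s2 <- per_ch(dxhat * xhat)
      s1_b <- array(rep(s1, each = hw), dim = c(d[1], d[2], C, 1))[, , , rep(1L, N), drop = FALSE]
      dim(s1_b) <- d
      s2_b <- array(rep(s2, each = hw), dim = c(d[1], d[2], C, 1))[, , , rep(1L, N), drop = FALSE]
      dim(s2_b) <- d
      tg_acc(x, inv_b / m * (m * dxhat - s1_b - xhat * s2_b))
    } else {
      tg_acc(x, g * g_b * inv_b)
    }
  })
}

# Spatial (2-D "channel") dropout: zero whole channels with probability p.
tg_dropout_channels <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  d <- dim(x$value)
  keep <- matrix(stats::rbinom(d[3] * d[4], 1L, 1 - p), nrow = d[3]) / (1 - p)
  kx <- array(rep(keep, each = d[1] * d[2]), dim = d)
  tg_node(x$value * kx, list(x), function(g) tg_acc(x, g * kx))
}
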