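# The attention encoder-decoder.
#
# Stem (7x7 stride-2 conv + BN + ReLU + 2x2 max-pool), a hierarchy of
# DownBlocks (two 3x3 conv blocks, CBAM, channel dropout), an attention-gated
# decoder with extended skip connections (every shallower encoder stage is
# average-pooled, channel-reduced and concatenated), CBAM refinement at each
# decoder stage, two upsampling blocks back to full resolution, a sigmoid
# head, and two auxiliary deep-supervision heads at 1/4 and 1/2 resolution.

#' Network configuration
#'
#' @param base_filters Channels of the first encoder stage; stage `i` uses
#'   `base_filters * 2^(i-1)`. Typical choices are 32/64/128/256; 8 gives a
#'   tiny desk-scale model.
#' @param n_stages Number of encoder stages, 2 to 4.
#' @param cbam_reduction Channel-attention bottleneck ratio (clamped per
#'   block to the block's channel count).
#' @param dropout Channel-dropout rate applied after each DownBlock,
#'   in `[0, 0.5]`.
#' @param lambda1,lambda2 Deep-supervision loss weights of the 1/2- and
#'   1/4-resolution auxiliary heads.
#' @return Object of class `"net_config"`.
#' @export
net_config <- function(base_filters = 32L, n_stages = 4L, cbam_reduction = 16L,
                       dropout = 0.1, lambda1 = 0.4, lambda2 = 0.2) {
  stopifnot(base_filters >= 4, n_stages %in% 2:4, cbam_reduction >= 1,
            dropout >= 0, dropout <= 0.5,
            is.finite(lambda1), is.finite(lambda2), lambda1 >= 0, lambda2 >= 0)
  structure(list(base_filters = as.integer(base_filters),
                 n_stages = as.integer(n_stages),
                 cbam_reduction = as.integer(cbam_reduction),
                 dropout = dropout, lambda1 = lambda1, lambda2 = lambda2),
            class = "net_config")
}

stage_channels <- function(cfg, i) cfg$base_filters * 2L^(i - 1L)

kaiming_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

new_conv <- function(kh, kw, cin, cout) {
  list(w = tg_param(kaiming_uniform(c(kh, kw, cin, cout), kh * kw * cin)),
       b = tg_param(rep(0, cout)))
}

new_bn <- function(c) {
  e <- new.env(parent = emptyenv())
  e$gamma <- tg_param(rep(1, c))
  e$beta <- tg_param(rep(0, c))
  e$running_mean <- rep(0, c)
  e$running_var <- rep(1, c)
  e
}

new_dense <- function(cin, cout) {
  list(w = tg_param(kaiming_uniform(c(cout, cin), cin)),
       b = tg_param(rep(0, cout)))
}

new_cbam <- function(c, reduction) {
  r <- min(reduction, c)
  hidden <- max(c %/% r, 1L)
  ca0 <- new_dense(c, hidden)
  # the bottleneck sees nonnegative pooled activations; a nonnegative first
  # layer keeps every ReLU unit alive at initialization so attention
  # gradients flow from the first step
  ca0$w$value <- abs(ca0$w$value)
  list(ca0 = ca0, ca1 = new_dense(hidden, c), sa = new_conv(7, 7, 2, 1))
}

new_gate <- function(skip_c, gate_c) {
  inter <- max(skip_c %/% 2L, 4L)
  list(wg = new_conv(1, 1, gate_c, inter), ws = new_conv(1, 1, skip_c, inter),
       psi = new_conv(1, 1, inter, 1))
}

#' Initialize network weights
#'
#' Kaiming-uniform initialization of every convolution and dense layer,
#' reproducible per seed. The returned model is an environment holding the
#' parameter tree, batch-norm running statistics, and the configuration.
#'
#' @param cfg A [net_config()].
#' @param in_channels Number of input channels (4: three modalities plus the
#'   prior map).
#' @param seed Integer initialization seed.
#' @return Object of class `"net_model"`.
#' @export
net_init <- function(cfg, in_channels = 4L, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$in_channels <- as.integer(in_channels)
  m$seed <- as.integer(seed)
  bf <- cfg$base_filters
  n <- cfg$n_stages
  r <- cfg$cbam_reduction
  with_seed(seed, {
    m$stem <- list(conv = new_conv(7, 7, in_channels, bf), bn = new_bn(bf))
    m$enc <- lapply(seq_len(n), function(i) {
      cin <- if (i == 1) bf else stage_channels(cfg, i - 1)
      cout <- stage_channels(cfg, i)
      list(conv1 = new_conv(3, 3, cin, cout), bn1 = new_bn(cout),
           conv2 = new_conv(3, 3, cout, cout), bn2 = new_bn(cout),
           cbam = new_cbam(cout, r))
    })
    m$dec <- if (n > 1) lapply(seq_len(n - 1), function(l) {
      c_deep <- stage_channels(cfg, l + 1)
      c_skip <- stage_channels(cfg, l)
      c_cat <- c_deep + c_skip + (l - 1) * bf
      list(gate = new_gate(c_skip, c_deep),
           skipred = if (l > 1) lapply(seq_len(l - 1), function(i)
             new_conv(1, 1, stage_channels(cfg, i), bf)) else list(),
           fuse = new_conv(3, 3, c_cat, c_skip), bn = new_bn(c_skip),
           cbam = new_cbam(c_skip, r))
    }) else list()
    m$up1 <- list(conv = new_conv(3, 3, stage_channels(cfg, 1), bf), bn = new_bn(bf))
    m$up2 <- list(conv = new_conv(3, 3, bf, bf), bn = new_bn(bf))
    m$head <- new_conv(1, 1, bf, 1)
    m$aux1_head <- new_conv(1, 1, bf, 1)          # 1/2 resolution
    m$aux2_head <- new_conv(1, 1, stage_channels(cfg, 1), 1) # 1/4 resolution
  })
  class(m) <- "net_model"
  m
}

conv_bn_relu <- function(x, conv, bn, stride, pad, training) {
  tg_relu(tg_batchnorm(tg_conv2d(x, conv$w, conv$b, stride, pad),
                       bn$gamma, bn$beta, bn, training))
}

# CBAM channel attention: sigmoid(MLP(avgpool) + MLP(maxpool)) per channel.
channel_attention <- function(x, cb, record = NULL) {
  mlp <- function(v) tg_dense(tg_relu(tg_dense(v, cb$ca0$w, cb$ca0$b)),
                              cb$ca1$w, cb$ca1$b)
  s <- tg_sigmoid(tg_add(mlp(tg_gap(x)), mlp(tg_gmp(x))))
  if (!is.null(record)) record(s$value)
  tg_scale_channels(x, s)
}

# CBAM spatial attention: 7x7 conv over channelwise [avg; max], sigmoid gate.
spatial_attention <- function(x, cb, record = NULL) {
  desc <- tg_concat_c(list(tg_channel_mean(x), tg_channel_max(x)))
  mmap <- tg_sigmoid(tg_conv2d(desc, cb$sa$w, cb$sa$b, 1L, 3L))
  if (!is.null(record)) record(mmap$value)
  tg_scale_spatial(x, mmap)
}

cbam_block <- function(x, cb, record = NULL) {
  spatial_attention(channel_attention(x, cb, record), cb, record)
}

# Additive attention gate: skip is modulated by a sigmoid coefficient map
# computed from the skip itself and the coarser gating signal.
attention_gate <- function(skip, gate, gt, record = NULL) {
  d <- dim(skip$value)
  g_up <- tg_bilinear(gate, d[1], d[2])
  a <- tg_relu(tg_add(tg_conv2d(skip, gt$ws$w, gt$ws$b, 1L, 0L),
                      tg_conv2d(g_up, gt$wg$w, gt$wg$b, 1L, 0L)))
  alpha <- tg_sigmoid(tg_conv2d(a, gt$psi$w, gt$psi$b, 1L, 0L))
  if (!is.null(record)) record(alpha$value)
  tg_scale_spatial(skip, alpha)
}

#' Forward pass of the segmentation network
#'
#' @param model A [net_init()] model.
#' @param x Input array: H x W x 4 (one slice) or H x W x 4 x N batch;
#'   `H = W` and divisible by `2^(n_stages + 1)`.
#' @param training Logical; batch statistics and channel dropout are used
#'   only in training mode.
#' @param with_aux Return the two auxiliary deep-supervision heads
#'   (bilinearly upsampled to full resolution); defaults to `training`.
#' @param capture_attention Record all attention coefficient maps (CBAM
#'   channel and spatial gains, gate coefficients) in `model$attn`.
#' @return List with `main` (H x W x 1 x N array of probabilities) and, when
#'   `with_aux`, `aux1` and `aux2` of the same shape.
#' @export
net_forward <- function(model, x, training = FALSE, with_aux = training,
                        capture_attention = FALSE) {
  stopifnot(inherits(model, "net_model"))
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  d <- dim(x)
  cfg <- model$cfg
  if (d[3] != model$in_channels)
    stop("net_forward: expected ", model$in_channels, " input channels, got ", d[3])
  if (d[1] != d[2]) stop("net_forward: input must be square")
  div <- 2L^(cfg$n_stages + 1L)
  if (d[1] %% div != 0)
    stop("net_forward: input size must be a multiple of ", div)
  rec <- NULL
  if (capture_attention) {
    model$attn <- list()
    rec <- function(v) model$attn[[length(model$attn) + 1L]] <- v
  }
  owned_tape <- is.null(.tg$tape)
  if (owned_tape) tg_tape_start()
  on.exit(if (owned_tape) tg_tape_stop())
  xn <- tg_const(x)
  # stem: 7x7 stride-2 conv + BN + ReLU, then 2x2 max-pool -> H/4
  f0 <- tg_maxpool2(conv_bn_relu(xn, model$stem$conv, model$stem$bn, 2L, 3L, training))
  enc_out <- vector("list", cfg$n_stages)
  f <- f0
  for (i in seq_len(cfg$n_stages)) {
    st <- model$enc[[i]]
    s <- if (i == 1) 1L else 2L
    f <- conv_bn_relu(f, st$conv1, st$bn1, s, 1L, training)
    f <- conv_bn_relu(f, st$conv2, st$bn2, 1L, 1L, training)
    f <- cbam_block(f, st$cbam, rec)
    f <- tg_dropout_channels(f, cfg$dropout, training)
    enc_out[[i]] <- f
  }
  fd <- enc_out[[cfg$n_stages]]
  fd1 <- fd
  for (l in rev(seq_len(cfg$n_stages - 1L))) {
    dc <- model$dec[[l]]
    dskip <- dim(enc_out[[l]]$value)
    up <- tg_bilinear(fd, dskip[1], dskip[2])
    gated <- attention_gate(enc_out[[l]], fd, dc$gate, rec)
    parts <- list(up, gated)
    if (l > 1) for (i in seq_len(l - 1)) {
      pooled <- tg_avgpool(enc_out[[i]], 2L^(l - i))
      parts[[length(parts) + 1L]] <-
        tg_conv2d(pooled, dc$skipred[[i]]$w, dc$skipred[[i]]$b, 1L, 0L)
    }
    f <- tg_concat_c(parts)
    f <- conv_bn_relu(f, dc$fuse, dc$bn, 1L, 1L, training)
    fd <- cbam_block(f, dc$cbam, rec)
    if (l == 1) fd1 <- fd
  }
  # two upsampling blocks: H/4 -> H/2 -> H
  h2 <- dim(fd1$value)[1] * 2L
  u1 <- conv_bn_relu(tg_bilinear(fd1, h2, h2), model$up1$conv, model$up1$bn,
                     1L, 1L, training)
  u2 <- conv_bn_relu(tg_bilinear(u1, d[1], d[2]), model$up2$conv, model$up2$bn,
                     1L, 1L, training)
  main <- tg_sigmoid(tg_conv2d(u2, model$head$w, model$head$b, 1L, 0L))
  out <- list(main = main)
  if (with_aux) {
    a1 <- tg_sigmoid(tg_conv2d(u1, model$aux1_head$w, model$aux1_head$b, 1L, 0L))
    a2 <- tg_sigmoid(tg_conv2d(fd1, model$aux2_head$w, model$aux2_head$b, 1L, 0L))
    out$aux1 <- tg_bilinear(a1, d[1], d[2])
    out$aux2 <- tg_bilinear(a2, d[1], d[2])
  }
  if (owned_tape) {
    out <- lapply(out, function(nd) nd$value)
  }
  out
}

# Collect every trainable parameter node as a flat named list.
collect_params <- function(model) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.environment(x)) {
      if (!is.null(x$running_mean)) { # batch-norm state: gamma/beta trainable
        out[[paste0(prefix, ".gamma")]] <<- x$gamma
        out[[paste0(prefix, ".beta")]] <<- x$beta
      } else if (isTRUE(x$requires)) { # a parameter leaf
        out[[prefix]] <<- x
      }
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(x[[i]], paste0(prefix, ".", nm))
      }
    }
  }
  for (nm in c("stem", "enc", "dec", "up1", "up2", "head", "aux1_head", "aux2_head"))
    walk(model[[nm]], nm)
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Serialize a model to a plain list (weights, BN stats, config, seed).
model_state <- function(model) {
  params <- collect_params(model)
  bns <- list()
  grab_bn <- function(x, prefix) {
    if (is.environment(x) && !is.null(x$running_mean)) {
      bns[[prefix]] <<- list(mean = x$running_mean, var = x$running_var)
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        grab_bn(x[[i]], paste0(prefix, ".", nm))
      }
    }
  }
  for (nm in c("stem", "enc", "dec", "up1", "up2")) grab_bn(model[[nm]], nm)
  list(cfg = unclass(model$cfg), in_channels = model$in_channels,
       seed = model$seed,
       weights = lapply(params, function(p) p$value), bn = bns)
}

restore_model <- function(state) {
  cfg <- do.call(net_config, state$cfg)
  model <- net_init(cfg, state$in_channels, state$seed)
  params <- collect_params(model)
  stopifnot(setequal(names(params), names(state$weights)))
  for (nm in names(params)) params[[nm]]$value <- state$weights[[nm]]
  put_bn <- function(x, prefix) {
    if (is.environment(x) && !is.null(x$running_mean)) {
      st <- state$bn[[prefix]]
      x$running_mean <- st$mean
      x$running_var <- st$var
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        put_bn(x[[i]], paste0(prefix, ".", nm))
      }
    }
  }
  for (nm in c("stem", "enc", "dec", "up1", "up2")) put_bn(model[[nm]], nm)
  model
}
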