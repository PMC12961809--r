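gs <- asNamespace("gliomaseg")

test_that("shape contracts hold through stem, blocks and full forward", {
  cfg <- tiny_cfg(2)
  model <- net_init(cfg, seed = 1)
  x <- array(runif(64 * 64 * 4), c(64, 64, 4, 1))
  out <- net_forward(model, x)
  expect_equal(dim(out$main), c(64, 64, 1, 1))
  expect_true(all(out$main > 0 & out$main < 1))
  # wrong channel count names the expectation
  expect_error(net_forward(model, array(0.1, c(64, 64, 3, 1))), "4")
  # indivisible size names the required multiple
  expect_error(net_forward(model, array(0.1, c(60, 60, 4, 1))), "multiple of 8")
})

test_that("conv block and downsampling halve or preserve resolution", {
  # stride-1 3x3 conv + BN + ReLU preserves H x W; stride 2 halves it
  conv <- gs$new_conv(3, 3, 2, 5)
  bn <- gs$new_bn(5)
  x <- gs$tg_const(array(rnorm(32 * 32 * 2), c(32, 32, 2, 1)))
  y1 <- gs$conv_bn_relu(x, conv, bn, 1L, 1L, FALSE)
  expect_equal(dim(y1$value), c(32, 32, 5, 1))
  expect_true(all(y1$value >= 0)) # ReLU range
  y2 <- gs$conv_bn_relu(x, conv, bn, 2L, 1L, FALSE)
  expect_equal(dim(y2$value), c(16, 16, 5, 1))
})

test_that("CBAM attention coefficients are strictly in (0,1) and contract", {
  set.seed(2)
  cb <- gs$new_cbam(8L, 4L)
  x <- gs$tg_const(array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2)))
  model_rec <- list()
  rec <- function(v) model_rec[[length(model_rec) + 1]] <<- v
  y <- gs$cbam_block(x, cb, rec)
  expect_equal(dim(y$value), dim(x$value))
  expect_true(all(unlist(model_rec) > 0 & unlist(model_rec) < 1))
  expect_true(all(abs(y$value) <= abs(x$value) + 1e-12))
  # identical channels receive identical attention weights once the MLP is
  # channel-symmetric (tied input columns and output rows)
  xx <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  xdup <- array(0, c(16, 16, 2, 1)); xdup[, , 1, ] <- xx; xdup[, , 2, ] <- xx
  cb2 <- gs$new_cbam(2L, 2L)
  cb2$ca0$w$value[, 2] <- cb2$ca0$w$value[, 1]
  cb2$ca1$w$value[2, ] <- cb2$ca1$w$value[1, ]
  cb2$ca1$b$value[2] <- cb2$ca1$b$value[1]
  rec2 <- list()
  gs$channel_attention(gs$tg_const(xdup), cb2, function(v) rec2[[1]] <<- v)
  expect_equal(rec2[[1]][1, 1], rec2[[1]][2, 1], tolerance = 1e-12)
  # equals the manual composition of the two attention stages
  y2 <- gs$spatial_attention(gs$channel_attention(x, cb), cb)
  expect_equal(y$value, y2$value)
})

test_that("spatially constant input yields a spatially constant attention map", {
  cb <- gs$new_cbam(4L, 2L)
  x <- gs$tg_const(array(rep(c(0.2, 0.5, 0.8, 0.3), each = 400),
                         c(20, 20, 4, 1)))
  rec <- list()
  gs$spatial_attention(x, cb, function(v) rec[[length(rec) + 1]] <<- v)
  interior <- rec[[1]][5:16, 5:16, 1, 1] # away from conv border effects
  expect_lt(diff(range(interior)), 1e-12)
})

test_that("attention gate obeys its closed forms", {
  set.seed(3)
  gt <- gs$new_gate(8L, 16L)
  skip <- gs$tg_const(array(rnorm(16 * 16 * 8), c(16, 16, 8, 1)))
  gate <- gs$tg_const(array(rnorm(8 * 8 * 16), c(8, 8, 16, 1)))
  rec <- list()
  out <- gs$attention_gate(skip, gate, gt, function(v) rec[[1]] <<- v)
  expect_equal(dim(out$value), dim(skip$value))
  expect_true(all(rec[[1]] > 0 & rec[[1]] < 1))
  expect_true(all(abs(out$value) <= abs(skip$value) + 1e-12))
  # zero psi weights and bias -> sigmoid(0) = 0.5 everywhere
  gt$psi$w$value[] <- 0
  gt$psi$b$value[] <- 0
  rec0 <- list()
  out0 <- gs$attention_gate(skip, gate, gt, function(v) rec0[[1]] <<- v)
  expect_true(all(rec0[[1]] == 0.5))
  expect_equal(out0$value, 0.5 * skip$value)
})

test_that("inference output equals an aux-bearing forward under eval statistics", {
  cfg <- tiny_cfg(3)
  model <- net_init(cfg, seed = 4)
  ph <- generate_phantom(phantom_spec(seed = 41))
  x <- assemble_four_channel(ph$image, build_prior(ph$image, seed = 1))
  a <- net_forward(model, x, training = FALSE, with_aux = TRUE)
  b <- net_forward(model, x, training = FALSE, with_aux = FALSE)
  expect_identical(a$main, b$main)
  expect_null(b$aux1)
  expect_true(all(a$aux1 > 0 & a$aux1 < 1))
})

test_that("every parameter receives a nonzero gradient after one step", {
  cfg <- tiny_cfg(3)
  model <- net_init(cfg, seed = 5)
  params <- gs$collect_params(model)
  ph <- generate_phantom(phantom_spec(seed = 42))
  x <- array(assemble_four_channel(ph$image, build_prior(ph$image, seed = 1)),
             c(64, 64, 4, 1))
  G <- array(ph$mask, c(64, 64, 1, 1))
  w <- loss_weights()
  gs$tg_tape_start()
  out <- net_forward(model, x, training = TRUE, with_aux = TRUE)
  loss <- gs$tg_scalar_comb(
    list(gs$tg_composite_loss(out$main, G, w),
         gs$tg_composite_loss(out$aux1, G, w),
         gs$tg_composite_loss(out$aux2, G, w)),
    c(1, cfg$lambda1, cfg$lambda2))
  gs$tg_backward(loss)
  gs$tg_tape_stop()
  nz <- vapply(params, function(p) !is.null(p$grad) && any(p$grad != 0),
               logical(1))
  expect_true(all(nz), info = paste("zero-gradient params:",
                                    paste(names(nz)[!nz], collapse = ", ")))
})

test_that("network gradients match finite differences on sampled weights", {
  cfg <- net_config(base_filters = 4, n_stages = 2, cbam_reduction = 2,
                    dropout = 0)
  model <- net_init(cfg, seed = 6)
  params <- gs$collect_params(model)
  set.seed(7)
  x <- array(runif(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  G <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  w <- loss_weights()
  lossval <- function() {
    o <- net_forward(model, x, training = FALSE, with_aux = TRUE)
    composite_loss(o$main, G, w) + cfg$lambda1 * composite_loss(o$aux1, G, w) +
      cfg$lambda2 * composite_loss(o$aux2, G, w)
  }
  gs$tg_tape_start()
  o <- net_forward(model, x, training = FALSE, with_aux = TRUE)
  l <- gs$tg_scalar_comb(
    list(gs$tg_composite_loss(o$main, G, w),
         gs$tg_composite_loss(o$aux1, G, w),
         gs$tg_composite_loss(o$aux2, G, w)),
    c(1, cfg$lambda1, cfg$lambda2))
  gs$tg_backward(l)
  gs$tg_tape_stop()
  for (nm in sample(names(params), 8)) {
    p <- params[[nm]]
    i <- sample(length(p$value), 1)
    eps <- 1e-5
    v0 <- p$value[i]
    p$value[i] <- v0 + eps; f1 <- lossval()
    p$value[i] <- v0 - eps; f2 <- lossval()
    p$value[i] <- v0
    num <- (f1 - f2) / (2 * eps)
    expect_equal(p$grad[i], num, tolerance = 1e-4,
                 info = paste("param", nm))
  }
})

test_that("forward passes are deterministic for fixed weights", {
  model <- net_init(tiny_cfg(2), seed = 8)
  x <- array(runif(32 * 32 * 4), c(32, 32, 4, 1))
  expect_identical(net_forward(model, x)$main, net_forward(model, x)$main)
  # same seed, fresh model: identical weights
  m2 <- net_init(tiny_cfg(2), seed = 8)
  expect_identical(net_forward(m2, x)$main, net_forward(model, x)$main)
})
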