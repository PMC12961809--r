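# Training, prediction and evaluation around the attention encoder-decoder.
# gliomaseg_fit() is the model-fitting entry point and returns a classed
# object with the usual print/summary/predict/plot/coef methods.

#' Training configuration
#'
#' @param epochs Maximum number of epochs (default 50).
#' @param batch_size Slices per gradient step.
#' @param learning_rate Base step size.
#' @param optimizer_name `"adam"`, `"sgd"` or `"rmsprop"`.
#' @param weight_decay L2 penalty added to gradients.
#' @param momentum SGD momentum (ignored by the other optimizers).
#' @param lr_decay_step Halve the learning rate every this many epochs.
#' @param patience Early-stopping patience in non-improving epochs.
#' @param seed Integer seed covering shuffling, dropout and augmentation.
#' @return A `"train_config"` object.
#' @export
train_config <- function(epochs = 50L, batch_size = 8L, learning_rate = 1e-3,
                         optimizer_name = c("adam", "sgd", "rmsprop"),
                         weight_decay = 1e-5, momentum = 0.9,
                         lr_decay_step = 10L, patience = 5L, seed = 1L) {
  optimizer_name <- match.arg(optimizer_name)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            weight_decay >= 0, lr_decay_step >= 1, patience >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer_name = optimizer_name,
                 weight_decay = weight_decay, momentum = momentum,
                 lr_decay_step = as.integer(lr_decay_step),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

make_optimizer <- function(params, cfg) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0) # zeros with p's exact shape
  st$v <- st$m
  st$lr <- cfg$learning_rate
  list(
    step = function() {
      st$t <- st$t + 1L
      for (i in seq_along(params)) {
        p <- params[[i]]
        if (is.null(p$grad)) next
        g <- p$grad + cfg$weight_decay * p$value
        if (cfg$optimizer_name == "adam") {
          st$m[[i]] <- 0.9 * st$m[[i]] + 0.1 * g
          st$v[[i]] <- 0.999 * st$v[[i]] + 0.001 * g^2
          mh <- st$m[[i]] / (1 - 0.9^st$t)
          vh <- st$v[[i]] / (1 - 0.999^st$t)
          p$value <- p$value - st$lr * mh / (sqrt(vh) + 1e-8)
        } else if (cfg$optimizer_name == "sgd") {
          st$m[[i]] <- cfg$momentum * st$m[[i]] + g
          p$value <- p$value - st$lr * st$m[[i]]
        } else { # rmsprop
          st$v[[i]] <- 0.99 * st$v[[i]] + 0.01 * g^2
          p$value <- p$value - st$lr * g / (sqrt(st$v[[i]]) + 1e-8)
        }
      }
    },
    state = st
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

batch_array <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, dim = c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

prep_input <- function(image, prior_seed) {
  pr <- build_prior(image, seed = prior_seed)
  assemble_four_channel(image, pr)
}

val_dice_of <- function(model, xs, masks, threshold = 0.5) {
  ds <- vapply(seq_along(xs), function(i) {
    p <- net_forward(model, xs[[i]], training = FALSE)$main
    if (!all(is.finite(p)))
      stop("validation produced a non-finite network output (diverged weights)")
    pm <- matrix(as.integer(p[, , 1, 1] >= threshold), dim(p)[1], dim(p)[2])
    dice_coef(pm, masks[[i]])
  }, numeric(1))
  mean(ds)
}

#' Fit the attention segmentation network
#'
#' Trains with the deeply supervised composite loss (BCE + Dice + Focal on
#' the main head and both auxiliary heads, auxiliaries weighted by
#' `lambda1`/`lambda2`), step-decayed learning rate, per-epoch validation
#' Dice, best-checkpoint tracking and early stopping. The prior channel is
#' built for every slice before training (and rebuilt after augmentation).
#'
#' @param images List of H x W x 3 arrays in `[0, 1]`.
#' @param masks List of matching binary H x W matrices.
#' @param val_images,val_masks Validation slices (required; early stopping
#'   and checkpointing track validation Dice with auxiliary heads off).
#' @param net_cfg A [net_config()].
#' @param train_cfg A [train_config()].
#' @param weights A [loss_weights()].
#' @param augment Optional [augmentation_config()] applied on the fly to
#'   each training slice (the prior is then recomputed on the augmented
#'   slice).
#' @param prior_seed Seed of the prior-channel clustering.
#' @param verbose Print one line per epoch.
#' @return An object of class `"gliomaseg"`: the fitted model at its best
#'   validation epoch plus the training history.
#' @export
gliomaseg_fit <- function(images, masks, val_images, val_masks,
                          net_cfg = net_config(), train_cfg = train_config(),
                          weights = loss_weights(), augment = NULL,
                          prior_seed = 1L, verbose = FALSE) {
  stopifnot(length(images) == length(masks), length(images) >= 1,
            length(val_images) == length(val_masks), length(val_images) >= 1)
  model <- net_init(net_cfg, in_channels = 4L, seed = train_cfg$seed)
  params <- collect_params(model)
  opt <- make_optimizer(params, train_cfg)
  xs <- lapply(images, prep_input, prior_seed = prior_seed)
  val_xs <- lapply(val_images, prep_input, prior_seed = prior_seed)
  n <- length(xs)
  best <- list(epoch = 0L, dice = -Inf, state = NULL)
  hist <- NULL
  stall <- 0L
  with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      opt$state$lr <- train_cfg$learning_rate *
        0.5^((epoch - 1) %/% train_cfg$lr_decay_step)
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (b in split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))) {
        if (is.null(augment)) {
          xb <- batch_array(xs[b])
          gb <- lapply(masks[b], identity)
        } else {
          aug <- lapply(b, function(i) augment_pair(images[[i]], masks[[i]], augment))
          xb <- batch_array(lapply(aug, function(a) prep_input(a$image, prior_seed)))
          gb <- lapply(aug, `[[`, "mask")
        }
        G <- array(0, dim = c(dim(xb)[1], dim(xb)[2], 1, length(b)))
        for (i in seq_along(gb)) G[, , 1, i] <- gb[[i]]
        tg_tape_start()
        out <- net_forward(model, xb, training = TRUE, with_aux = TRUE)
        loss <- tg_scalar_comb(
          list(tg_composite_loss(out$main, G, weights),
               tg_composite_loss(out$aux1, G, weights),
               tg_composite_loss(out$aux2, G, weights)),
          c(1, weights$lambda1, weights$lambda2))
        if (!is.finite(loss$value))
          stop("gliomaseg_fit: non-finite loss at epoch ", epoch,
               " (lr = ", opt$state$lr, ")")
        tg_backward(loss)
        tg_tape_stop()
        opt$step()
        zero_grads(params)
        ep_loss <- ep_loss + loss$value
        nb <- nb + 1L
      }
      vd <- val_dice_of(model, val_xs, val_masks)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                     val_dice = vd))
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val dice %.4f", epoch,
                        ep_loss / nb, vd))
      if (vd > best$dice) {
        best <- list(epoch = epoch, dice = vd, state = model_state(model))
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= train_cfg$patience) break
      }
    }
  })
  structure(list(model = restore_model(best$state), net_cfg = net_cfg,
                 train_cfg = train_cfg, weights = weights,
                 history = hist, best_epoch = best$epoch,
                 best_val_dice = best$dice, prior_seed = prior_seed),
            class = "gliomaseg")
}

#' @export
print.gliomaseg <- function(x, ...) {
  cat("Attention encoder-decoder glioma segmenter\n")
  cat(sprintf("  stages: %d, base filters: %d, parameters: %s\n",
              x$net_cfg$n_stages, x$net_cfg$base_filters,
              format(sum(vapply(collect_params(x$model),
                                function(p) length(p$value), numeric(1))),
                     big.mark = ",")))
  cat(sprintf("  trained %d epoch(s); best validation Dice %.4f at epoch %d\n",
              nrow(x$history), x$best_val_dice, x$best_epoch))
  invisible(x)
}

#' @export
summary.gliomaseg <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.gliomaseg <- function(object, ...) {
  lapply(collect_params(object$model), function(p) p$value)
}

#' @export
plot.gliomaseg <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$val_dice, type = "b", xlab = "epoch",
                 ylab = "validation Dice", main = "validation Dice", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

reflect_pad_to <- function(image, mult) {
  d <- dim(image)
  target <- ceiling(max(d[1], d[2]) / mult) * mult
  if (d[1] == target && d[2] == target) return(list(image = image, orig = d[1:2]))
  refl <- function(n, target) {
    idx <- seq_len(target)
    period <- c(seq_len(n), rev(seq_len(n))) # reflect indices past the edge
    period[(idx - 1) %% (2 * n) + 1]
  }
  out <- image[refl(d[1], target), refl(d[2], target), , drop = FALSE]
  list(image = out, orig = d[1:2])
}

#' Predict tumor masks for new slices
#'
#' Builds the prior channel on the fly, pads inputs reflectively to the
#' model's resolution multiple when needed, and thresholds the sigmoid
#' output.
#'
#' @param object A fitted [gliomaseg_fit()] model.
#' @param images List of H x W x 3 arrays (or a single array).
#' @param threshold Probability cutoff in `(0, 1)` (default 0.5).
#' @param type `"mask"` for binary masks, `"prob"` for probability maps.
#' @param ... Unused.
#' @return List of H x W matrices (one per input slice).
#' @export
predict.gliomaseg <- function(object, images, threshold = 0.5,
                              type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  mult <- 2L^(object$net_cfg$n_stages + 1L)
  lapply(images, function(img) {
    pad <- reflect_pad_to(img, mult)
    x <- prep_input(pad$image, object$prior_seed)
    p <- net_forward(object$model, x, training = FALSE)$main[, , 1, 1]
    p <- p[seq_len(pad$orig[1]), seq_len(pad$orig[2])]
    if (type == "prob") p else matrix(as.integer(p >= threshold),
                                      pad$orig[1], pad$orig[2])
  })
}

#' Evaluate a fitted model on a test set
#'
#' @param object A fitted `"gliomaseg"` model.
#' @param images,masks Test slices and ground-truth masks.
#' @param threshold Probability cutoff.
#' @param file Optional CSV path; per-pair rows plus a mean row are written.
#' @return List with `per_pair` (data frame of metric rows) and `mean`
#'   (named list of column means; surface distances averaged over the pairs
#'   where they are defined).
#' @export
evaluate_model <- function(object, images, masks, threshold = 0.5, file = NULL) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  probs <- predict(object, images, type = "prob")
  rows <- lapply(seq_along(images), function(i) {
    P <- matrix(as.integer(probs[[i]] >= threshold), nrow(masks[[i]]))
    as.data.frame(metric_report(P, masks[[i]]))
  })
  per_pair <- do.call(rbind, rows)
  mean_row <- as.list(colMeans(per_pair, na.rm = TRUE))
  if (!is.null(file)) {
    out <- rbind(per_pair, as.data.frame(mean_row))
    out$case <- c(as.character(seq_len(nrow(per_pair))), "mean")
    utils::write.csv(out, file, row.names = FALSE)
  }
  list(per_pair = per_pair, mean = mean_row)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the weights, batch-norm statistics, network
#' configuration and seeds, plus the training history; the configuration is
#' additionally written next to it as YAML.
#'
#' @param object A fitted `"gliomaseg"` model.
#' @param path Checkpoint path (`.rds`).
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns the restored `"gliomaseg"` object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "gliomaseg"))
  st <- list(state = model_state(object$model), net_cfg = unclass(object$net_cfg),
             train_cfg = unclass(object$train_cfg), weights = unclass(object$weights),
             history = object$history, best_epoch = object$best_epoch,
             best_val_dice = object$best_val_dice, prior_seed = object$prior_seed)
  saveRDS(st, path)
  yaml::write_yaml(list(net = st$net_cfg, train = st$train_cfg,
                        loss = st$weights),
                   sub("\\.rds$", ".yaml", path))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  structure(list(model = restore_model(st$state),
                 net_cfg = do.call(net_config, st$net_cfg),
                 train_cfg = do.call(train_config, st$train_cfg),
                 weights = do.call(loss_weights, st$weights),
                 history = st$history, best_epoch = st$best_epoch,
                 best_val_dice = st$best_val_dice, prior_seed = st$prior_seed),
            class = "gliomaseg")
}

#' Build a validation-Dice fitness function for hyperparameter search
#'
#' Returns a closure suitable for [run_pbfo()]: it trains a proxy model for
#' `budget_epochs` under the decoded hyperparameters and returns the best
#' validation Dice (0 on training failure).
#'
#' @param images,masks Training slices.
#' @param val_images,val_masks Validation slices.
#' @param base_net A [net_config()] whose fields not covered by the search
#'   space are kept.
#' @param budget_epochs Proxy-training epoch budget per evaluation.
#' @param seed Training seed shared by all evaluations.
#' @return `function(hp) -> numeric` fitness in `[0, 1]`.
#' @export
make_dice_fitness <- function(images, masks, val_images, val_masks,
                              base_net = net_config(base_filters = 8,
                                                    n_stages = 2,
                                                    cbam_reduction = 4),
                              budget_epochs = 2L, seed = 1L) {
  force(images); force(masks); force(val_images); force(val_masks)
  function(hp) {
    ncfg <- net_config(
      base_filters = base_net$base_filters, n_stages = base_net$n_stages,
      cbam_reduction = base_net$cbam_reduction,
      dropout = hp$dropout %||% base_net$dropout,
      lambda1 = base_net$lambda1, lambda2 = base_net$lambda2)
    tcfg <- train_config(
      epochs = budget_epochs,
      batch_size = min(hp$batch_size %||% 8, length(images)),
      learning_rate = hp$learning_rate %||% 1e-3,
      optimizer_name = hp$optimizer %||% "adam",
      weight_decay = hp$weight_decay %||% 1e-5,
      momentum = hp$momentum %||% 0.9,
      lr_decay_step = hp$lr_decay_step %||% 10,
      patience = budget_epochs, seed = seed)
    w <- loss_weights(w_bce = hp$w_bce %||% 0.5, w_dice = hp$w_dice %||% 0.5,
                      w_focal = hp$w_focal %||% 0.2)
    fit <- gliomaseg_fit(images, masks, val_images, val_masks,
                         net_cfg = ncfg, train_cfg = tcfg, weights = w)
    fit$best_val_dice
  }
}
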