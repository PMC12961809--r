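# Segmentation losses: binary cross-entropy, soft Dice, focal, their
# weighted composite, and the deep-supervision total.

.eps <- 1e-7

#' Loss weighting configuration
#'
#' Weights of the BCE/Dice/Focal composite, the deep-supervision auxiliary
#' weights, and the focal-loss shape parameters. The composite weights are
#' the quantities the hyperparameter forager tunes in `[0.1, 0.9]`.
#'
#' @param w_bce,w_dice,w_focal Nonnegative composite weights.
#' @param lambda1,lambda2 Auxiliary-head loss weights (the deeper head gets
#'   the smaller default).
#' @param focal_gamma Focusing exponent (>= 0, default 2).
#' @param focal_alpha Positive-class weight in `[0, 1]` (default 0.25).
#' @return Object of class `"loss_weights"`.
#' @export
loss_weights <- function(w_bce = 0.5, w_dice = 0.5, w_focal = 0.2,
                         lambda1 = 0.4, lambda2 = 0.2,
                         focal_gamma = 2, focal_alpha = 0.25) {
  stopifnot(all(is.finite(c(w_bce, w_dice, w_focal, lambda1, lambda2))),
            w_bce >= 0, w_dice >= 0, w_focal >= 0, lambda1 >= 0, lambda2 >= 0,
            focal_gamma >= 0, focal_alpha >= 0, focal_alpha <= 1)
  structure(list(w_bce = w_bce, w_dice = w_dice, w_focal = w_focal,
                 lambda1 = lambda1, lambda2 = lambda2,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha),
            class = "loss_weights")
}

#' Binary cross-entropy loss
#'
#' Mean of `-[G log S + (1 - G) log(1 - S)]` with probabilities clamped at
#' `1e-7` for stability.
#'
#' @param S Predicted probabilities in `(0, 1)`.
#' @param G Binary ground truth of the same shape.
#' @return Scalar loss (>= 0).
#' @export
bce_loss <- function(S, G) {
  if (!all(dim(S) == dim(G)) && length(S) != length(G))
    stop("bce_loss: shape mismatch")
  Sc <- pmin(pmax(S, .eps), 1 - .eps)
  -mean(G * log(Sc) + (1 - G) * log(1 - Sc))
}

#' Soft Dice loss
#'
#' `1 - (2 sum(SG) + smooth) / (sum(S) + sum(G) + smooth)`; two empty masks
#' score 0 by the smoothing convention.
#'
#' @inheritParams bce_loss
#' @param smooth Smoothing constant (default 1).
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(S, G, smooth = 1) {
  if (!all(dim(S) == dim(G)) && length(S) != length(G))
    stop("dice_loss: shape mismatch")
  1 - (2 * sum(S * G) + smooth) / (sum(S) + sum(G) + smooth)
}

#' Focal loss
#'
#' Mean of `-alpha_t (1 - p_t)^gamma log(p_t)` with `p_t = S` on tumor
#' pixels and `1 - S` on background, `alpha_t = alpha` / `1 - alpha`
#' respectively. With `gamma = 0` and `alpha = 0.5` this reduces to half the
#' binary cross-entropy.
#'
#' @inheritParams bce_loss
#' @param gamma Focusing exponent (>= 0).
#' @param alpha Positive-class weight.
#' @return Scalar loss (>= 0).
#' @export
focal_loss <- function(S, G, gamma = 2, alpha = 0.25) {
  if (gamma < 0) stop("focal_loss: gamma must be >= 0")
  Sc <- pmin(pmax(S, .eps), 1 - .eps)
  pt <- ifelse(G == 1, Sc, 1 - Sc)
  at <- ifelse(G == 1, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

#' Weighted BCE + Dice + Focal composite loss
#'
#' @inheritParams bce_loss
#' @param w A [loss_weights()] object.
#' @return Scalar `w_bce * BCE + w_dice * Dice + w_focal * Focal`.
#' @export
composite_loss <- function(S, G, w = loss_weights()) {
  w$w_bce * bce_loss(S, G) + w$w_dice * dice_loss(S, G) +
    w$w_focal * focal_loss(S, G, w$focal_gamma, w$focal_alpha)
}

#' Deep-supervision total loss
#'
#' @param main_loss,aux1_loss,aux2_loss Scalar losses of the main and the
#'   two auxiliary heads.
#' @param lambda1,lambda2 Auxiliary weights.
#' @return `main + lambda1 * aux1 + lambda2 * aux2`.
#' @export
total_loss <- function(main_loss, aux1_loss, aux2_loss, lambda1 = 0.4,
                       lambda2 = 0.2) {
  main_loss + lambda1 * aux1_loss + lambda2 * aux2_loss
}

# --- autodiff composite loss (training path) -------------------------------
# Same arithmetic as the plain functions, with an analytic gradient in S.
tg_composite_loss <- function(Snode, G, w) {
  S <- Snode$value
  n <- length(S)
  Sc <- pmin(pmax(S, .eps), 1 - .eps)
  interior <- (S > .eps) & (S < 1 - .eps)
  val <- w$w_bce * bce_loss(S, G) + w$w_dice * dice_loss(S, G) +
    w$w_focal * focal_loss(S, G, w$focal_gamma, w$focal_alpha)
  # dice bookkeeping
  smooth <- 1
  Nu <- 2 * sum(S * G) + smooth
  De <- sum(S) + sum(G) + smooth
  tg_node(val, list(Snode), function(g) {
    g_bce <- (-G / Sc + (1 - G) / (1 - Sc)) / n
    g_dice <- (-2 * G * De + Nu) / De^2
    pt <- ifelse(G == 1, Sc, 1 - Sc)
    at <- ifelse(G == 1, w$focal_alpha, 1 - w$focal_alpha)
    gam <- w$focal_gamma
    dfdp <- -at * ((1 - pt)^gam / pt -
                     (if (gam > 0) gam * (1 - pt)^(gam - 1) * log(pt) else 0))
    g_focal <- dfdp * ifelse(G == 1, 1, -1) / n
    grad <- w$w_bce * g_bce * interior + w$w_dice * g_dice +
      w$w_focal * g_focal * interior
    dim(grad) <- dim(S)
    tg_acc(Snode, g * grad)
  })
}

tg_scalar_comb <- function(nodes, coefs) {
  val <- sum(vapply(seq_along(nodes), function(i) coefs[i] * nodes[[i]]$value,
                    numeric(1)))
  tg_node(val, nodes, function(g) {
    for (i in seq_along(nodes)) tg_acc(nodes[[i]], g * coefs[i])
  })
}
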