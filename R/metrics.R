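# Evaluation metrics: overlap/confusion ratios, boundary surface distances,
# and the structural similarity index.

check_binary <- function(m, name) {
  if (!all(m %in% c(0, 1)))
    stop(name, " must be binary (values in {0, 1})")
}

#' Pixelwise confusion counts between prediction and ground truth
#'
#' @param P,G Binary H x W matrices (prediction, ground truth).
#' @return List with integer `TP`, `TN`, `FP`, `FN` summing to `H * W`.
#' @export
confusion_counts <- function(P, G) {
  if (!all(dim(P) == dim(G))) stop("confusion_counts: shape mismatch")
  check_binary(P, "P"); check_binary(G, "G")
  tp <- sum(P == 1 & G == 1)
  tn <- sum(P == 0 & G == 0)
  fp <- sum(P == 1 & G == 0)
  fn <- sum(P == 0 & G == 1)
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Dice overlap coefficient
#'
#' `2|P n G| / (|P| + |G|)`; two empty masks agree perfectly and score 1.
#'
#' @inheritParams confusion_counts
#' @return Numeric in `[0, 1]`.
#' @export
dice_coef <- function(P, G) {
  check_binary(P, "P"); check_binary(G, "G")
  denom <- sum(P) + sum(G)
  if (denom == 0) return(1)
  2 * sum(P * G) / denom
}

#' Intersection-over-union (Jaccard index)
#'
#' `|P n G| / |P u G|`; two empty masks score 1.
#'
#' @inheritParams confusion_counts
#' @return Numeric in `[0, 1]`.
#' @export
iou_coef <- function(P, G) {
  check_binary(P, "P"); check_binary(G, "G")
  uni <- sum(P | G)
  if (uni == 0) return(1)
  sum(P & G) / uni
}

#' Confusion-derived rates
#'
#' Accuracy, precision, recall (sensitivity), specificity and the
#' precision/recall harmonic-mean F1. A zero denominator yields 0 and sets
#' the attribute `"undefined"` naming the affected rates (never `NaN`).
#'
#' @param counts A [confusion_counts()] result.
#' @return Named list of the five rates.
#' @export
basic_rates <- function(counts) {
  safe <- function(num, den, nm, undef) {
    if (den == 0) { undef(nm); 0 } else num / den
  }
  undefined <- character(0)
  note <- function(nm) undefined <<- c(undefined, nm)
  with(counts, {
    acc <- safe(TP + TN, TP + TN + FP + FN, "accuracy", note)
    prec <- safe(TP, TP + FP, "precision", note)
    rec <- safe(TP, TP + FN, "recall", note)
    spec <- safe(TN, TN + FP, "specificity", note)
    f1 <- if (prec + rec == 0) { note("f1"); 0 } else 2 * prec * rec / (prec + rec)
    out <- list(accuracy = acc, precision = prec, recall = rec,
                specificity = spec, f1 = f1)
    if (length(undefined)) attr(out, "undefined") <- undefined
    out
  })
}

# Boundary pixels: on-pixels with at least one off 4-neighbor (outside the
# image counts as off), i.e. the mask minus its 4-connectivity erosion.
boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  m <- matrix(0, h + 2, w + 2)
  m[2:(h + 1), 2:(w + 1)] <- mask
  core <- m[2:(h + 1), 2:(w + 1)]
  er <- core & m[1:h, 2:(w + 1)] & m[3:(h + 2), 2:(w + 1)] &
    m[2:(h + 1), 1:w] & m[2:(h + 1), 3:(w + 2)]
  which(core == 1 & !er, arr.ind = TRUE)
}

#' Boundary surface distances between two masks
#'
#' Boundaries are extracted as the 4-connectivity erosion difference and all
#' Euclidean distances between the two boundary point sets are measured in
#' pixel units. Reported are: `hd95`, the maximum of the two directed 95th
#' percentile distances; `assd`, the mean of the directed distances pooled
#' both ways; `msd`, the median of the same pooled distances (the pooled
#' mean is attached as `msd_mean`). All three are symmetric in `(P, G)`.
#'
#' @inheritParams confusion_counts
#' @return List with `hd95`, `assd`, `msd`, `msd_mean` (>= 0, pixels).
#' @export
surface_distances <- function(P, G) {
  check_binary(P, "P"); check_binary(G, "G")
  if (sum(P) == 0) stop("surface_distances: prediction mask P is empty")
  if (sum(G) == 0) stop("surface_distances: ground-truth mask G is empty")
  bp <- boundary_pixels(P)
  bg <- boundary_pixels(G)
  # all-pairs Euclidean distances between the two boundary coordinate sets
  d2 <- outer(bp[, 1], bg[, 1], "-")^2 + outer(bp[, 2], bg[, 2], "-")^2
  d_pg <- sqrt(apply(d2, 1, min)) # each P boundary point to nearest G point
  d_gp <- sqrt(apply(d2, 2, min))
  pooled <- c(d_pg, d_gp)
  list(hd95 = max(stats::quantile(d_pg, 0.95, names = FALSE),
                  stats::quantile(d_gp, 0.95, names = FALSE)),
       assd = mean(pooled),
       msd = stats::median(pooled),
       msd_mean = mean(pooled))
}

gaussian_kernel <- function(size = 7L, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity index between two images
#'
#' Standard SSIM with a 7 x 7 Gaussian window (sigma 1.5), constants
#' `k1 = 0.01`, `k2 = 0.03` and data range 1; local statistics use
#' replicated borders. Symmetric in its arguments.
#'
#' @param a,b Numeric H x W matrices with values in `[0, 1]`.
#' @return Numeric SSIM in `[-1, 1]`.
#' @export
ssim_index <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  k <- gaussian_kernel(7L, 1.5)
  f <- function(x) {
    y <- EBImage::filter2(EBImage::Image(x), k, boundary = "replicate")
    matrix(as.numeric(EBImage::imageData(y)), nrow(x), ncol(x))
  }
  c1 <- 0.01^2; c2 <- 0.03^2
  mu1 <- f(a); mu2 <- f(b)
  s11 <- f(a * a) - mu1^2
  s22 <- f(b * b) - mu2^2
  s12 <- f(a * b) - mu1 * mu2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

#' Full metric report for a prediction/truth pair
#'
#' @param P Binary predicted mask.
#' @param G Binary ground-truth mask.
#' @param P_soft Optional probability map in `[0, 1]` used for SSIM
#'   (defaults to the binary prediction).
#' @return List with dice, iou, accuracy, precision, recall, specificity,
#'   f1, hd95, assd, msd and ssim; surface distances are `NA` when either
#'   mask is empty.
#' @export
metric_report <- function(P, G, P_soft = NULL) {
  counts <- confusion_counts(P, G)
  rates <- basic_rates(counts)
  sd <- if (sum(P) > 0 && sum(G) > 0) surface_distances(P, G)
        else list(hd95 = NA_real_, assd = NA_real_, msd = NA_real_)
  soft <- if (is.null(P_soft)) matrix(as.numeric(P), nrow(P)) else P_soft
  c(list(dice = dice_coef(P, G), iou = iou_coef(P, G)), rates[1:5],
    list(hd95 = sd$hd95, assd = sd$assd, msd = sd$msd,
         ssim = ssim_index(soft, matrix(as.numeric(G), nrow(G)))))
}
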