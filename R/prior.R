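# Tumor-likelihood prior channel: brain masking, Z-score, intensity K-means,
# highest-mean cluster selection, morphological refinement, distance softening.

mean_channel <- function(image) {
  if (length(dim(image)) == 2) return(image)
  d <- dim(image)
  matrix(rowMeans(matrix(image, nrow = d[1] * d[2])), d[1], d[2])
}

#' Estimate the brain support of a slice
#'
#' A lightweight skull-stripping surrogate: Otsu threshold on the (min-max
#' normalized) channel-mean intensity, followed by largest connected
#' component extraction and hole filling.
#'
#' @param image H x W matrix or H x W x C array.
#' @return H x W integer matrix in `{0, 1}`; all-zero input yields an empty
#'   mask with a warning.
#' @export
brain_mask_estimate <- function(image) {
  x <- mean_channel(image)
  if (max(x) <= min(x)) {
    warning("brain_mask_estimate: constant image, returning empty mask")
    return(matrix(0L, nrow(x), ncol(x)))
  }
  xn <- minmax_normalize(x)
  thr <- EBImage::otsu(EBImage::Image(xn))
  bw <- xn > thr
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- matrix(as.numeric(EBImage::imageData(lab)), nrow(x), ncol(x))
  if (max(lab) < 1) {
    warning("brain_mask_estimate: no foreground component found")
    return(matrix(0L, nrow(x), ncol(x)))
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  bw <- (lab == keep) * 1
  filled <- EBImage::fillHull(EBImage::Image(bw))
  matrix(as.integer(as.numeric(EBImage::imageData(filled)) > 0.5), nrow(x), ncol(x))
}

#' Z-score normalize intensities within a brain mask
#'
#' Each channel is standardized to mean 0 and standard deviation 1 over the
#' in-mask pixels; out-of-mask pixels are set to 0. A channel that is
#' constant inside the mask becomes all zeros. The result is invariant to
#' positive affine rescaling of the input.
#'
#' @param image H x W matrix or H x W x C array.
#' @param brain_mask H x W binary matrix with at least one on-pixel.
#' @return Array of the same shape as `image`.
#' @export
zscore_normalize <- function(image, brain_mask) {
  if (sum(brain_mask) == 0) stop("zscore_normalize: empty brain mask")
  two_d <- length(dim(image)) == 2
  x <- if (two_d) array(image, dim = c(dim(image), 1)) else image
  out <- array(0, dim = dim(x))
  inside <- brain_mask == 1
  for (c in seq_len(dim(x)[3])) {
    ch <- x[, , c]
    v <- ch[inside]
    s <- stats::sd(v)
    o <- matrix(0, nrow(ch), ncol(ch))
    if (is.finite(s) && s > 0) o[inside] <- (v - mean(v)) / s
    out[, , c] <- o
  }
  if (two_d) out[, , 1] else out
}

# Deterministic k-means++ seeding on a 1-D feature vector.
kmeanspp_centers <- function(v, k) {
  centers <- numeric(k)
  centers[1] <- v[sample.int(length(v), 1)]
  d2 <- (v - centers[1])^2
  for (j in seq_len(k - 1) + 1) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / length(v), length(v))
    centers[j] <- v[sample.int(length(v), 1, prob = p)]
    d2 <- pmin(d2, (v - centers[j])^2)
  }
  centers
}

#' Intensity K-means clustering inside the brain mask
#'
#' Clusters the channel-mean intensity of in-mask pixels into `k` groups
#' (Lloyd iterations, k-means++ seeding, fixed seed). This is the
#' unsupervised stage that proposes a tumor candidate: on FLAIR-like
#' contrast the tumor is the high-intensity mode.
#'
#' @param image H x W matrix or H x W x C array.
#' @param brain_mask H x W binary matrix.
#' @param k Number of clusters (default 3).
#' @param seed Integer seed controlling the k-means++ initialization.
#' @return An object of class `"intensity_clusters"`: list with `labels`
#'   (integer vector over in-mask pixels), `mask` (logical H x W of in-mask
#'   support), `centers` (cluster mean intensities) and `values` (the
#'   clustered intensities).
#' @export
kmeans_intensity <- function(image, brain_mask, k = 3L, seed = 1L) {
  x <- mean_channel(image)
  inside <- brain_mask == 1
  v <- x[inside]
  if (length(unique(v)) < k)
    stop("kmeans_intensity: fewer than k = ", k, " distinct masked intensities")
  fit <- with_seed(seed, {
    best <- NULL
    for (r in 1:8) { # Lloyd restarts from k-means++ seedings; keep best WSS
      init <- kmeanspp_centers(v, k)
      while (anyDuplicated(init)) init <- kmeanspp_centers(v, k)
      cand <- suppressWarnings(
        stats::kmeans(v, centers = matrix(init, ncol = 1), iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || cand$tot.withinss < best$tot.withinss) best <- cand
    }
    best
  })
  structure(list(labels = fit$cluster, mask = inside,
                 centers = as.numeric(fit$centers), values = v),
            class = "intensity_clusters")
}

#' Select the highest-mean intensity cluster as tumor candidate
#'
#' @param clusters An [kmeans_intensity()] result.
#' @param image The image the clustering was computed on (used to recompute
#'   cluster mean intensities; ties break toward the lowest cluster index).
#' @return H x W integer candidate mask.
#' @export
select_tumor_candidate <- function(clusters, image) {
  stopifnot(inherits(clusters, "intensity_clusters"))
  x <- mean_channel(image)
  v <- x[clusters$mask]
  means <- tapply(v, clusters$labels, mean)
  best <- as.integer(names(means)[which.max(means)]) # which.max: first maximum
  m <- matrix(0L, nrow(x), ncol(x))
  m[which(clusters$mask)[clusters$labels == best]] <- 1L
  m
}

#' Morphologically refine a binary candidate mask
#'
#' Morphological closing with a 3 x 3 box structuring element, then a 3 x 3
#' median filter; fills small holes and removes isolated speckle without
#' increasing the number of connected components.
#'
#' @param mask H x W binary matrix.
#' @return H x W integer matrix in `{0, 1}`.
#' @export
refine_mask <- function(mask) {
  stopifnot(all(mask %in% c(0, 1)))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  k <- EBImage::makeBrush(3, shape = "box")
  cl <- EBImage::closing(EBImage::Image(m), k)
  md <- EBImage::medianFilter(cl, 1)
  matrix(as.integer(as.numeric(EBImage::imageData(md)) > 0.5), nrow(mask), ncol(mask))
}

#' Build the tumor-likelihood prior map for one slice
#'
#' Pipeline: brain mask -> per-channel Z-score -> intensity K-means (k = 3)
#' -> highest-mean cluster -> morphological refinement -> distance-to-boundary
#' softening inside the candidate -> min-max scaling to `[0, 1]`. The
#' composition is invariant to positive affine intensity changes of the
#' input and deterministic per seed.
#'
#' @param image H x W x C array (C = 3 for the usual three modalities).
#' @param seed Integer seed for the clustering stage.
#' @return H x W numeric prior map in `[0, 1]` (all zeros when no brain or
#'   candidate is found).
#' @export
build_prior <- function(image, seed = 1L) {
  brain <- brain_mask_estimate(image)
  h <- nrow(brain); w <- ncol(brain)
  if (sum(brain) == 0) return(matrix(0, h, w))
  z <- zscore_normalize(image, brain)
  cl <- kmeans_intensity(z, brain, k = 3L, seed = seed)
  cand <- select_tumor_candidate(cl, z)
  ref <- refine_mask(cand)
  ref <- ref * brain # prior support stays inside the brain
  if (sum(ref) == 0) return(matrix(0, h, w))
  d <- matrix(as.numeric(EBImage::imageData(
    EBImage::distmap(EBImage::Image(matrix(as.numeric(ref), h, w))))), h, w)
  minmax_normalize(d)
}

#' Stack three image channels and a prior map into a network input
#'
#' @param image H x W x 3 array.
#' @param prior H x W prior map in `[0, 1]`.
#' @return H x W x 4 array, prior last.
#' @export
assemble_four_channel <- function(image, prior) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("assemble_four_channel: image must be H x W x 3, got ",
         paste(d, collapse = " x "))
  if (!all(d[1:2] == dim(prior)))
    stop("assemble_four_channel: prior size does not match image")
  out <- array(0, dim = c(d[1], d[2], 4))
  out[, , 1:3] <- image
  out[, , 4] <- prior
  out
}
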