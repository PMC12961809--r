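# Synthetic glioma phantoms and slice-level dataset plumbing.
#
# Images are plain numeric arrays of dim (H, W, C) with values in [0, 1];
# masks are integer H x W matrices with values in {0, 1}.  Row-major thinking,
# origin at the top-left.

#' Specification of a synthetic glioma phantom slice
#'
#' Describes a brain-like 2-D slice: a bright elliptical "brain" on a dark
#' background carrying one or more hyperintense tumor blobs, plus additive
#' Gaussian noise. The defaults define the desk-scale study conditions used
#' throughout the package's tests and examples.
#'
#' @param height,width Output size in pixels (at least 8).
#' @param tumor_area_fraction Target fraction of the whole slice covered by
#'   tumor, in `[0, 0.3]`.
#' @param n_tumors Number of tumor blobs (>= 0).
#' @param noise_sd Standard deviation of additive Gaussian noise, on the
#'   intensity scale of the unnormalized slice.
#' @param tumor_contrast Additive hyperintensity of tumor over brain tissue
#'   (> 0); FLAIR-like abnormality appears bright.
#' @param seed Integer seed; phantoms are bit-reproducible per seed.
#' @return An object of class `"phantom_spec"` (a named list).
#' @export
phantom_spec <- function(height = 64L, width = 64L, tumor_area_fraction = 0.05,
                         n_tumors = 1L, noise_sd = 0.05, tumor_contrast = 0.5,
                         seed = 1L) {
  stopifnot(height >= 8, width >= 8,
            is.finite(tumor_area_fraction), tumor_area_fraction >= 0,
            tumor_area_fraction <= 0.3,
            n_tumors >= 0, is.finite(noise_sd), noise_sd >= 0,
            is.finite(tumor_contrast), tumor_contrast > 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 tumor_area_fraction = tumor_area_fraction,
                 n_tumors = as.integer(n_tumors), noise_sd = noise_sd,
                 tumor_contrast = tumor_contrast, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evaluate an ellipse support on the pixel grid.
ellipse_mask <- function(h, w, cy, cx, ry, rx, theta = 0) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  ct <- cos(theta); st <- sin(theta)
  u <- yy * ct + xx * st
  v <- -yy * st + xx * ct
  (u / ry)^2 + (v / rx)^2 <= 1
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic glioma phantom and its ground-truth mask
#'
#' Draws a brain ellipse over a dark background, places `n_tumors`
#' hyperintense elliptical blobs fully inside the brain, adds Gaussian noise
#' independently to three pseudo-modality channels, and min-max normalizes
#' the result to `[0, 1]`. The union of blob supports is returned as the
#' binary ground-truth mask.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `image` (H x W x 3 array in `[0, 1]`,
#'   carrying the brain support as attribute `"brain"`) and `mask`
#'   (H x W integer matrix in `{0, 1}`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    cy <- h / 2 + stats::runif(1, -0.03, 0.03) * h
    cx <- w / 2 + stats::runif(1, -0.03, 0.03) * w
    ry <- stats::runif(1, 0.34, 0.4) * h
    rx <- stats::runif(1, 0.38, 0.44) * w
    brain <- ellipse_mask(h, w, cy, cx, ry, rx)
    mask <- matrix(0L, h, w)
    if (spec$n_tumors > 0) {
      target <- spec$tumor_area_fraction * h * w / spec$n_tumors
      for (t in seq_len(spec$n_tumors)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          aspect <- stats::runif(1, 0.7, 1.4)
          a <- sqrt(target / pi * aspect)
          b <- sqrt(target / pi / aspect)
          tc_y <- cy + stats::runif(1, -0.6, 0.6) * (ry - a)
          tc_x <- cx + stats::runif(1, -0.6, 0.6) * (rx - b)
          th <- stats::runif(1, 0, pi)
          blob <- ellipse_mask(h, w, tc_y, tc_x, a, b, th)
          inside <- ellipse_mask(h, w, cy, cx, ry - 1, rx - 1)
          if (any(blob) && all(inside[blob])) {
            mask[blob] <- 1L
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("generate_phantom: could not place a tumor of area fraction ",
               spec$tumor_area_fraction, " inside the brain region")
      }
    }
    # channel base levels mimic three MRI weightings of the same anatomy
    base <- c(0.55, 0.5, 0.45)
    img <- array(0, dim = c(h, w, 3))
    # gentle radial shading inside the brain for texture
    rad <- sqrt(((matrix(seq_len(h), h, w) - cy) / ry)^2 +
                ((matrix(seq_len(w), h, w, byrow = TRUE) - cx) / rx)^2)
    shade <- 1 - 0.15 * pmin(rad, 1)
    for (c in 1:3) {
      ch <- matrix(0.02, h, w)
      ch[brain] <- (base[c] * shade)[brain]
      ch[mask == 1L] <- ch[mask == 1L] + spec$tumor_contrast * base[c]
      ch <- ch + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      img[, , c] <- ch
    }
    img <- minmax_normalize(img)
    attr(img, "brain") <- brain
    list(image = img, mask = mask)
  })
}

#' Resize an image/mask pair to a square size
#'
#' The image is resampled bilinearly, the mask by nearest neighbor so that it
#' stays binary; the same geometric transformation is applied to both.
#'
#' @param image H x W x C array (or H x W matrix).
#' @param mask H x W integer matrix in `{0, 1}`.
#' @param size Target side length in pixels (default 256).
#' @return List with resized `image` and `mask`.
#' @export
resize_pair <- function(image, mask, size = 256L) {
  di <- dim(image)
  if (!all(di[1:2] == dim(mask)))
    stop("resize_pair: image and mask sizes differ")
  if (all(di[1:2] == size)) return(list(image = image, mask = mask))
  x <- if (length(di) == 2) array(image, dim = c(di, 1)) else image
  x4 <- array(x, dim = c(dim(x), 1))
  y <- .bilinear_fwd(x4, as.integer(size), as.integer(size))
  out <- array(y, dim = c(size, size, dim(x)[3]))
  if (length(di) == 2) out <- out[, , 1]
  # nearest-neighbor index mapping for the mask (half-pixel centers)
  ri <- pmin(pmax(floor((seq_len(size) - 0.5) * di[1] / size) + 1, 1), di[1])
  ci <- pmin(pmax(floor((seq_len(size) - 0.5) * di[2] / size) + 1, 1), di[2])
  list(image = out, mask = mask[ri, ci, drop = FALSE])
}

#' Min-max normalize an image to [0, 1]
#'
#' Applies `(I - min(I)) / (max(I) - min(I))` over the whole image (all
#' channels jointly). A constant image maps to all zeros.
#'
#' @param image Numeric array.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(image) {
  stopifnot(all(is.finite(image)))
  lo <- min(image); hi <- max(image)
  if (hi <= lo) return(array(0, dim = dim(image)))
  out <- (image - lo) / (hi - lo)
  dim(out) <- dim(image)
  out
}

#' Augmentation configuration
#'
#' On-the-fly training augmentation: random rotation (up to +/- 20 degrees by
#' default), horizontal/vertical flips, isotropic rescaling about the image
#' center, and brightness/contrast jitter (image only).
#'
#' @param max_rotation_deg Maximum absolute rotation angle in degrees.
#' @param h_flip_prob,v_flip_prob Flip probabilities in `[0, 1]`.
#' @param scale_range Length-2 vector `(s_lo, s_hi)` with `s_lo <= 1 <= s_hi`.
#' @param brightness_delta,contrast_delta Intensity jitter half-ranges.
#' @return An object of class `"augmentation_config"`.
#' @export
augmentation_config <- function(max_rotation_deg = 20, h_flip_prob = 0.5,
                                v_flip_prob = 0.5, scale_range = c(0.9, 1.1),
                                brightness_delta = 0.1, contrast_delta = 0.1) {
  stopifnot(max_rotation_deg >= 0, h_flip_prob >= 0, h_flip_prob <= 1,
            v_flip_prob >= 0, v_flip_prob <= 1, length(scale_range) == 2,
            scale_range[1] <= 1, scale_range[2] >= 1,
            brightness_delta >= 0, contrast_delta >= 0)
  structure(list(max_rotation_deg = max_rotation_deg,
                 h_flip_prob = h_flip_prob, v_flip_prob = v_flip_prob,
                 scale_range = scale_range, brightness_delta = brightness_delta,
                 contrast_delta = contrast_delta),
            class = "augmentation_config")
}

# Inverse-mapped rotation + isotropic scale about the center.
# bilinear = FALSE gives nearest-neighbor sampling (masks).
affine_resample <- function(m, theta_deg, scale, bilinear = TRUE) {
  if (theta_deg == 0 && scale == 1) return(m)
  h <- nrow(m); w <- ncol(m)
  th <- theta_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse transform: rotate by -theta, scale by 1/scale
  sy <- (cos(th) * yy + sin(th) * xx) / scale + cy
  sx <- (-sin(th) * yy + cos(th) * xx) / scale + cx
  if (bilinear) {
    y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
    x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
    fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
    inb <- sy >= 0.5 & sy <= h + 0.5 & sx >= 0.5 & sx <= w + 0.5
    v <- m[cbind(c(y0), c(x0))] * (1 - c(fy)) * (1 - c(fx)) +
      m[cbind(c(y1), c(x0))] * c(fy) * (1 - c(fx)) +
      m[cbind(c(y0), c(x1))] * (1 - c(fy)) * c(fx) +
      m[cbind(c(y1), c(x1))] * c(fy) * c(fx)
    out <- matrix(v, h, w)
    out[!inb] <- 0
  } else {
    yn <- round(sy); xn <- round(sx)
    inb <- yn >= 1 & yn <= h & xn >= 1 & xn <= w
    out <- matrix(0, h, w)
    out[inb] <- m[cbind(c(yn)[inb], c(xn)[inb])]
  }
  out
}

#' Randomly augment an image/mask pair
#'
#' Draws one rotation/flip/scale/intensity transformation from `config` using
#' R's global random number stream and applies the geometric part identically
#' to image and mask (bilinear vs nearest-neighbor resampling); intensity
#' jitter touches the image only. The sampled draw is attached to the result
#' as attribute `"draw"`.
#'
#' @param image H x W x C array.
#' @param mask H x W binary matrix.
#' @param config An [augmentation_config()].
#' @return List with `image` and `mask`; the mask stays in `{0, 1}`.
#' @export
augment_pair <- function(image, mask, config) {
  stopifnot(inherits(config, "augmentation_config"),
            all(dim(image)[1:2] == dim(mask)))
  theta <- if (config$max_rotation_deg > 0)
    stats::runif(1, -config$max_rotation_deg, config$max_rotation_deg) else 0
  hflip <- stats::runif(1) < config$h_flip_prob
  vflip <- stats::runif(1) < config$v_flip_prob
  sc <- if (diff(config$scale_range) > 0)
    stats::runif(1, config$scale_range[1], config$scale_range[2]) else 1
  bshift <- if (config$brightness_delta > 0)
    stats::runif(1, -config$brightness_delta, config$brightness_delta) else 0
  cfac <- if (config$contrast_delta > 0)
    1 + stats::runif(1, -config$contrast_delta, config$contrast_delta) else 1
  img <- image
  mk <- mask
  for (c in seq_len(dim(image)[3]))
    img[, , c] <- affine_resample(image[, , c], theta, sc, bilinear = TRUE)
  mk <- affine_resample(mask, theta, sc, bilinear = FALSE)
  if (hflip) { img <- img[, rev(seq_len(ncol(mk))), , drop = FALSE]; mk <- mk[, rev(seq_len(ncol(mk)))] }
  if (vflip) { img <- img[rev(seq_len(nrow(mk))), , , drop = FALSE]; mk <- mk[rev(seq_len(nrow(mk))), ] }
  img <- pmin(pmax(img * cfac + bshift, 0), 1)
  dim(img) <- dim(image)
  mk <- matrix(as.integer(mk > 0.5), nrow(mask), ncol(mask))
  out <- list(image = img, mask = mk)
  attr(out, "draw") <- list(theta = theta, hflip = hflip, vflip = vflip,
                            scale = sc, brightness = bshift, contrast = cfac)
  out
}

#' Shuffled train/validation/test split
#'
#' The training partition receives `floor(ratios[1] * n_items)` items; the
#' remainder is divided between validation and test (validation takes the
#' extra item when the remainder is odd). With the default 80/10/10 ratios a
#' pool of 3,929 slices splits into 3,143 / 393 / 393.
#'
#' @param n_items Number of items (>= 3).
#' @param ratios Length-3 ratios summing to 1.
#' @param seed Integer shuffle seed.
#' @return List of class `"split_indices"` with disjoint 1-based index
#'   vectors `train`, `val`, `test` covering `1:n_items`.
#' @export
split_dataset <- function(n_items, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (n_items < 3) stop("split_dataset: need at least 3 items")
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8, all(ratios > 0))
  n_train <- floor(ratios[1] * n_items)
  rem <- n_items - n_train
  n_val <- ceiling(rem * ratios[2] / (ratios[2] + ratios[3]))
  n_test <- rem - n_val
  idx <- with_seed(seed, sample.int(n_items))
  structure(list(train = sort(idx[seq_len(n_train)]),
                 val = sort(idx[n_train + seq_len(n_val)]),
                 test = sort(idx[n_train + n_val + seq_len(n_test)])),
            class = "split_indices")
}

mask_sibling_path <- function(path) {
  ext <- tools::file_ext(path)
  sub(paste0("\\.", ext, "$"), paste0("_mask.", ext), path)
}

#' Save an image/mask pair to disk
#'
#' Writes the image to `path` and the mask to the sibling file
#' `<stem>_mask.<ext>`. PNG files are written 8-bit; TIFF files are written
#' as 32-bit float, masks always as `{0, 1}` times full scale.
#'
#' @param image H x W x C array in `[0, 1]`.
#' @param mask H x W binary matrix.
#' @param path Output image path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, the pair of paths written.
#' @export
save_pair <- function(image, mask, path) {
  ext <- tolower(tools::file_ext(path))
  mp <- mask_sibling_path(path)
  if (ext == "png") {
    png::writePNG(image, path)
    png::writePNG(matrix(as.numeric(mask), nrow(mask)), mp)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path, bits.per.sample = 32L)
    tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), mp, bits.per.sample = 32L)
  } else stop("save_pair: unsupported extension '", ext, "'")
  invisible(c(path, mp))
}

#' Load an image/mask pair from disk
#'
#' Reads `path` and its `<stem>_mask.<ext>` sibling. Mask pixels are
#' binarized at half full scale (8-bit values > 127 map to 1).
#'
#' @param path Image path written by [save_pair()] or following the same
#'   sibling convention.
#' @return List with `image` (H x W x C array) and `mask` (H x W integer
#'   matrix in `{0, 1}`).
#' @export
load_pair <- function(path) {
  mp <- mask_sibling_path(path)
  if (!file.exists(path)) stop("load_pair: missing image file ", path)
  if (!file.exists(mp))
    stop("load_pair: missing mask sibling; expected ", mp)
  ext <- tolower(tools::file_ext(path))
  rd <- function(p) {
    if (ext == "png") png::readPNG(p) else tiff::readTIFF(p)
  }
  img <- rd(path)
  if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 1))
  mk <- rd(mp)
  if (length(dim(mk)) == 3) mk <- mk[, , 1]
  list(image = img, mask = matrix(as.integer(mk > 0.5), nrow(mk), ncol(mk)))
}

#' Write a CSV manifest of image/mask pairs
#'
#' @param image_paths,mask_paths Character vectors of equal length.
#' @param split Character vector of `"train"`, `"val"` or `"test"` labels.
#' @param file Output CSV path.
#' @return Invisibly, the manifest data frame.
#' @export
write_pair_manifest <- function(image_paths, mask_paths, split, file) {
  stopifnot(length(image_paths) == length(mask_paths),
            length(split) == length(image_paths))
  df <- data.frame(image_path = image_paths, mask_path = mask_paths,
                   split = split, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
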