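test_that("brain mask surrogate recovers the phantom's brain ellipse", {
  ph <- generate_phantom(phantom_spec(seed = 31))
  brain_true <- attr(ph$image, "brain")
  est <- brain_mask_estimate(ph$image)
  expect_true(all(est %in% c(0L, 1L)))
  coverage <- sum(est[brain_true]) / sum(brain_true)
  expect_gte(coverage, 0.95)
  expect_warning(z <- brain_mask_estimate(matrix(0, 16, 16)), "constant|empty")
  expect_true(all(z == 0))
})

test_that("z-score normalization standardizes in-mask intensities", {
  ph <- generate_phantom(phantom_spec(seed = 32))
  br <- brain_mask_estimate(ph$image)
  z <- zscore_normalize(ph$image, br)
  for (c in 1:3) {
    v <- z[, , c][br == 1]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sd(v) - 1), 1e-6)
    expect_true(all(z[, , c][br == 0] == 0))
  }
  # affine invariance
  z2 <- zscore_normalize(2.5 * ph$image + 0.3, br)
  expect_equal(z, z2, tolerance = 1e-10)
  # constant masked region -> zeros
  zc <- zscore_normalize(matrix(5, 10, 10), matrix(1L, 10, 10))
  expect_true(all(zc == 0))
})

test_that("intensity k-means separates well-separated modes deterministically", {
  set.seed(1)
  img <- matrix(sample(c(0.1, 0.5, 0.9), 400, replace = TRUE), 20, 20)
  msk <- matrix(1L, 20, 20)
  cl <- kmeans_intensity(img, msk, k = 3, seed = 7)
  # three pure clusters: zero within-cluster variance
  for (lab in unique(cl$labels))
    expect_equal(var(cl$values[cl$labels == lab]), 0)
  cl2 <- kmeans_intensity(img, msk, k = 3, seed = 7)
  expect_identical(cl$labels, cl2$labels)
  expect_error(kmeans_intensity(matrix(0.5, 4, 4), matrix(1L, 4, 4), k = 3),
               "distinct")
})

test_that("k-means reaches the optimum of a tiny 1-D problem", {
  # brute-force oracle: best contiguous 3-partition of the sorted values
  set.seed(2)
  v <- runif(20)
  img <- matrix(v, 4, 5)
  cl <- kmeans_intensity(img, matrix(1L, 4, 5), k = 3, seed = 3)
  wss <- sum(tapply(cl$values, cl$labels,
                    function(g) sum((g - mean(g))^2)))
  sv <- sort(v)
  best <- Inf
  for (i in 1:18) for (j in (i + 1):19) {
    parts <- list(sv[1:i], sv[(i + 1):j], sv[(j + 1):20])
    w <- sum(vapply(parts, function(g) sum((g - mean(g))^2), numeric(1)))
    best <- min(best, w)
  }
  expect_lte(wss, best + 1e-10)
})

test_that("the highest-mean cluster is selected, ties to lowest index", {
  img <- matrix(c(rep(0.1, 8), rep(0.5, 8), rep(0.9, 4)), 4, 5)
  cl <- kmeans_intensity(img, matrix(1L, 4, 5), k = 3, seed = 1)
  cand <- select_tumor_candidate(cl, img)
  expect_true(all(img[cand == 1] == 0.9))
  expect_equal(sum(cand), 4)
  # tie in means: construct labels by hand
  fake <- structure(list(labels = c(1L, 2L, 1L, 2L, 3L),
                         mask = matrix(c(rep(TRUE, 5), rep(FALSE, 0)), 1, 5),
                         centers = c(0.5, 0.5, 0.1),
                         values = c(0.5, 0.5, 0.5, 0.5, 0.1)),
                    class = "intensity_clusters")
  img2 <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.1), 1, 5)
  cand2 <- select_tumor_candidate(fake, img2)
  expect_equal(which(cand2 == 1), c(1L, 3L)) # cluster 1 wins the tie
})

test_that("phantom tumor is recovered by the clustering stage", {
  ph <- generate_phantom(phantom_spec(seed = 33, tumor_contrast = 0.8))
  br <- brain_mask_estimate(ph$image)
  z <- zscore_normalize(ph$image, br)
  cl <- kmeans_intensity(z, br, k = 3, seed = 1)
  cand <- select_tumor_candidate(cl, z)
  coverage <- sum(cand[ph$mask == 1]) / sum(ph$mask)
  expect_gte(coverage, 0.8)
})

test_that("mask refinement fills holes and removes speckle", {
  # solid square spanning the whole canvas: fixed point of closing + median
  solid <- matrix(1L, 10, 10)
  expect_identical(refine_mask(solid), solid)
  # isolated on-pixel vanishes under the median filter
  dot <- matrix(0L, 9, 9); dot[5, 5] <- 1L
  expect_true(all(refine_mask(dot) == 0))
  # interior hole in a centered 10x10 square is filled; the median filter
  # additionally rounds the four convex corners, identically for the holed
  # and the solid square
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  holed <- sq; holed[7, 7] <- 0L
  ref <- refine_mask(holed)
  expect_equal(ref[7, 7], 1L) # hole filled
  expect_identical(ref, refine_mask(sq))
  expect_true(all(sq[ref == 1] == 1)) # refinement stays inside the square
  # refinement never increases the number of connected components
  set.seed(6)
  for (i in 1:10) {
    m <- random_mask(24, 0.4)
    ncomp <- function(x) max(EBImage::bwlabel(EBImage::Image(x * 1)))
    expect_lte(ncomp(refine_mask(m)), ncomp(m))
  }
})

test_that("the prior map is in range, seeded, brain-supported and contrasted", {
  ph <- generate_phantom(phantom_spec(seed = 34))
  pr <- build_prior(ph$image, seed = 2)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_identical(pr, build_prior(ph$image, seed = 2))
  br <- brain_mask_estimate(ph$image)
  expect_true(all(pr[br == 0] == 0))
  # mean prior inside the true tumor clearly exceeds the outside mean
  diffs <- vapply(1:20, function(s) {
    p <- generate_phantom(phantom_spec(seed = s))
    m <- build_prior(p$image, seed = s)
    mean(m[p$mask == 1]) - mean(m[p$mask == 0])
  }, numeric(1))
  expect_true(all(diffs >= 0.3))
})

test_that("the prior pipeline is invariant to affine intensity changes", {
  for (s in 1:10) {
    ph <- generate_phantom(phantom_spec(seed = s))
    p1 <- build_prior(ph$image, seed = 1)
    p2 <- build_prior(1.7 * ph$image + 0.05, seed = 1)
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("four-channel assembly stacks the prior last", {
  ph <- generate_phantom(phantom_spec(seed = 35))
  pr <- build_prior(ph$image, seed = 1)
  x <- assemble_four_channel(ph$image, pr)
  expect_equal(dim(x), c(64, 64, 4))
  expect_identical(x[, , 1:3], ph$image[, , 1:3])
  expect_identical(x[, , 4], pr)
  expect_error(assemble_four_channel(ph$image[, , 1:2], pr), "H x W x 3")
  expect_error(assemble_four_channel(ph$image, pr[1:10, 1:10]), "size")
})
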