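test_that("phantom generation is deterministic and respects its spec", {
  sp <- phantom_spec(seed = 11)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_equal(dim(a$image), c(64, 64, 3))
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(a$mask %in% c(0L, 1L)))
  # no tumors -> empty mask
  z <- generate_phantom(phantom_spec(n_tumors = 0, seed = 2))
  expect_true(all(z$mask == 0))
  # tumor pixels sit inside the brain support
  brain <- attr(a$image, "brain")
  expect_true(all(brain[a$mask == 1]))
})

test_that("generated mask area tracks the requested fraction", {
  fr <- vapply(1:100, function(s) {
    mean(generate_phantom(phantom_spec(tumor_area_fraction = 0.05, seed = s))$mask)
  }, numeric(1))
  expect_gt(mean(fr), 0.03)
  expect_lt(mean(fr), 0.07)
})

test_that("an oversized tumor triggers a placement error", {
  # a narrow slice cannot hold a blob of 30% of the pixel area
  expect_error(generate_phantom(phantom_spec(height = 64, width = 16,
                                             tumor_area_fraction = 0.3,
                                             n_tumors = 1, seed = 1)),
               "could not place")
})

test_that("resize_pair follows the contract", {
  ph <- generate_phantom(phantom_spec(height = 32, width = 32, seed = 5))
  out <- resize_pair(ph$image, ph$mask, 64)
  expect_equal(dim(out$image), c(64, 64, 3))
  expect_equal(dim(out$mask), c(64, 64))
  # identity when already at target size
  id <- resize_pair(out$image, out$mask, 64)
  expect_identical(id$image, out$image)
  # masks stay binary under upsampling (checkerboard worst case)
  cb <- matrix(rep(c(0L, 1L), length.out = 64 * 64), 64, 64)
  up <- resize_pair(array(runif(64 * 64 * 3), c(64, 64, 3)), cb, 256)
  expect_true(all(up$mask %in% c(0L, 1L)))
  expect_error(resize_pair(ph$image, matrix(0L, 8, 8)), "differ")
})

test_that("min-max normalization maps to [0,1] with exact extremes", {
  x <- array(0:255, dim = c(16, 16, 1))
  n <- minmax_normalize(x)
  expect_equal(min(n), 0)
  expect_equal(max(n), 1)
  expect_equal(minmax_normalize(array(100, c(4, 4)))[1, 1], 0) # constant -> zeros
  # value 100 on range [0, 200] -> 0.5
  y <- array(c(0, 100, 200, 50), c(2, 2))
  expect_equal(minmax_normalize(y)[2, 1], 0.5)
  # property: any non-constant image
  for (s in 1:5) {
    set.seed(s)
    v <- minmax_normalize(array(rnorm(48), c(4, 4, 3)))
    expect_equal(range(v), c(0, 1))
  }
})

test_that("augmentation identity, involution and angle bounds hold", {
  ph <- generate_phantom(phantom_spec(seed = 9))
  off <- augmentation_config(max_rotation_deg = 0, h_flip_prob = 0,
                             v_flip_prob = 0, scale_range = c(1, 1),
                             brightness_delta = 0, contrast_delta = 0)
  set.seed(1)
  a <- augment_pair(ph$image, ph$mask, off)
  expect_equal(a$image, ph$image, ignore_attr = TRUE)
  expect_identical(a$mask, ph$mask)
  # two forced horizontal flips restore the original
  hf <- augmentation_config(max_rotation_deg = 0, h_flip_prob = 1,
                            v_flip_prob = 0, scale_range = c(1, 1),
                            brightness_delta = 0, contrast_delta = 0)
  set.seed(2)
  once <- augment_pair(ph$image, ph$mask, hf)
  twice <- augment_pair(once$image, once$mask, hf)
  expect_equal(twice$image, ph$image, ignore_attr = TRUE)
  expect_identical(twice$mask, ph$mask)
  # sampled angles stay inside the +/- 20 degree bound
  set.seed(3)
  cfg <- augmentation_config()
  angles <- replicate(1000, {
    attr(augment_pair(ph$image[1:8, 1:8, , drop = FALSE],
                      ph$mask[1:8, 1:8], cfg), "draw")$theta
  })
  expect_true(all(abs(angles) <= 20))
})

test_that("geometric-only augmentation approximately preserves mask area", {
  ph <- generate_phantom(phantom_spec(seed = 21, tumor_area_fraction = 0.08))
  geo <- augmentation_config(max_rotation_deg = 20, h_flip_prob = 0.5,
                             v_flip_prob = 0.5, scale_range = c(1, 1),
                             brightness_delta = 0, contrast_delta = 0)
  set.seed(4)
  for (i in 1:20) {
    a <- augment_pair(ph$image, ph$mask, geo)
    expect_lte(abs(sum(a$mask) - sum(ph$mask)) / sum(ph$mask), 0.05)
  }
})

test_that("dataset splitting is exact, disjoint and exhaustive", {
  s <- split_dataset(3929, seed = 1)
  expect_equal(lengths(s[c("train", "val", "test")]),
               c(train = 3143, val = 393, test = 393))
  s10 <- split_dataset(10, seed = 2)
  expect_equal(lengths(s10[c("train", "val", "test")]),
               c(train = 8, val = 1, test = 1))
  expect_error(split_dataset(2), "at least 3")
  set.seed(5)
  for (i in 1:100) {
    n <- sample(10:10000, 1)
    sp <- split_dataset(n, seed = i)
    all_idx <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(length(all_idx), length(unique(all_idx)))
    expect_equal(length(sp$train), floor(0.8 * n))
  }
})

test_that("image/mask pairs round-trip through PNG and TIFF", {
  ph <- generate_phantom(phantom_spec(seed = 13))
  img8 <- round(ph$image * 255) / 255 # 8-bit grid
  d <- withr::local_tempdir()
  p <- file.path(d, "slice.png")
  save_pair(img8, ph$mask, p)
  back <- load_pair(p)
  expect_equal(back$image, img8, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$mask, ph$mask)
  # TIFF float path
  pt <- file.path(d, "slice.tif")
  save_pair(ph$image, ph$mask, pt)
  backt <- load_pair(pt)
  expect_equal(backt$image, ph$image, ignore_attr = TRUE, tolerance = 1e-6)
  # 8-bit mask convention: {0, 255} loads as {0, 1}
  m255 <- matrix(c(0, 1), 8, 8)
  png::writePNG(m255, file.path(d, "conv.png"))
  png::writePNG(m255, file.path(d, "conv_mask.png"))
  expect_true(all(load_pair(file.path(d, "conv.png"))$mask %in% c(0L, 1L)))
  # missing sibling errors with the expected path
  file.remove(file.path(d, "slice_mask.png"))
  expect_error(load_pair(p), "slice_mask.png")
})

test_that("the pair manifest is written with the expected columns", {
  d <- withr::local_tempdir()
  f <- file.path(d, "manifest.csv")
  df <- write_pair_manifest(c("a.png", "b.png"), c("a_mask.png", "b_mask.png"),
                            c("train", "val"), f)
  back <- read.csv(f)
  expect_equal(names(back), c("image_path", "mask_path", "split"))
  expect_equal(back$split, c("train", "val"))
})
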