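test_that("rgb_to_lab matches the sRGB/D65 reference at anchor colors", {
  white <- array(255, c(1, 1, 3))
  lab <- rgb_to_lab(white)
  expect_equal(lab[1, 1, 1], 100, tolerance = 1e-3)
  expect_lt(abs(lab[1, 1, 2]), 0.5)
  expect_lt(abs(lab[1, 1, 3]), 0.5)

  black <- array(0, c(1, 1, 3))
  expect_equal(as.vector(rgb_to_lab(black)), c(0, 0, 0), tolerance = 1e-6)

  gray <- array(119, c(1, 1, 3))
  expect_lt(abs(rgb_to_lab(gray)[1, 1, 1] - 50), 1.0)

  expect_error(rgb_to_lab(matrix(1, 4, 4)), "3-channel")
})

test_that("otsu_threshold maximizes between-class variance (brute-force oracle)", {
  # two-delta histogram: any split between the deltas is maximal; smallest wins
  h <- rep(0, 256); h[c(1, 256)] <- 50          # bins 0 and 255
  t2 <- otsu_threshold(h)
  expect_true(t2 >= 0 && t2 < 255)
  expect_identical(t2, otsu_brute(h))

  # bimodal Gaussian histogram: threshold strictly between the modes
  set.seed(42)
  x <- c(rnorm(5000, 60, 10), rnorm(5000, 200, 10))
  hb <- tabulate(findInterval(pmin(pmax(x, 0), 255), 0:256,
                              rightmost.closed = TRUE), 256)
  tb <- otsu_threshold(hb)
  expect_gt(tb, 60); expect_lt(tb, 200)
  expect_identical(tb, otsu_brute(hb))

  # random histograms agree with exhaustive search
  set.seed(7)
  for (i in 1:25) {
    h <- rpois(256, lambda = runif(1, 0.5, 20))
    if (sum(h > 0) < 2) next
    expect_identical(otsu_threshold(h), otsu_brute(h))
  }

  expect_error(otsu_threshold(rep(0, 256)), "zero total")
  d <- rep(0, 256); d[100] <- 10
  expect_error(otsu_threshold(d), class = "gliopatch_degenerate_histogram")
})

test_that("segment_tissue separates chromatic tissue from white background", {
  # pure white slide: degenerate histogram -> empty mask with warning
  white <- array(255, c(64, 64, 3))
  expect_warning(m <- segment_tissue(slide_record("w", "w", white), 2),
                 "degenerate")
  expect_equal(mean(m$mask), 0)

  # half white, half saturated pink: mask covers the pink half within 2%
  img <- array(255, c(64, 128, 3))
  img[, 65:128, 1] <- 255; img[, 65:128, 2] <- 60; img[, 65:128, 3] <- 150
  m <- segment_tissue(slide_record("hp", "hp", img), 1)
  expect_lt(abs(mean(m$mask) - 0.5), 0.02)
  expect_true(all(m$mask[, 65:128]))

  # invariant to uniform white padding of the border
  pad <- array(255, c(96, 160, 3)); pad[1:64, 1:128, ] <- img
  mp <- segment_tissue(slide_record("pad", "pad", pad), 1)
  expect_identical(mp$mask[1:64, 1:128], m$mask)
})

test_that("segmentation recovers the generator's ground-truth tissue map", {
  cfg <- synthetic_config(patches_per_slide = 16, patch_size = 128)
  g <- gen_slide(cfg, "A2", seed = 11)
  m <- segment_tissue(slide_record("s", "p", g$image), 4)
  truth_px <- kronecker(g$truth$tissue_map, matrix(1, 32, 32)) > 0
  iou <- sum(m$mask & truth_px) / sum(m$mask | truth_px)
  expect_gte(iou, 0.95)
})

test_that("tile_patches follows the floor-division grid contract", {
  all_tissue <- function(H, W, ds = 1)
    structure(list(mask = matrix(TRUE, ceiling(H / ds), ceiling(W / ds)),
                   downsample = ds, threshold_used = 1),
              class = "tissue_mask")
  sl <- function(H, W) slide_record("s", "p", array(128, c(H, W, 3)), label = "GBM")

  p <- tile_patches(sl(512, 512), all_tissue(512, 512), 128, 0.5)
  expect_equal(nrow(p), 16)                       # 4 x 4 grid
  expect_equal(p$label, rep("GBM", 16))           # weak label inherited
  # row-major order, anchored at the origin, non-overlapping
  expect_equal(p$y[1:4], rep(0, 4))
  expect_equal(p$x[1:4], c(0, 128, 256, 384))
  expect_false(any(duplicated(p[, c("x", "y")])))
  expect_true(all(p$x + p$size <= 512 & p$y + p$size <= 512))

  # no full row of patches fits in 127 rows of pixels
  expect_equal(nrow(tile_patches(sl(127, 512), all_tissue(127, 512), 128, 0.5)), 0)

  # random rectangles: retained count = floor(W/s) * floor(H/s) on all-tissue
  set.seed(3)
  for (i in 1:5) {
    H <- sample(100:400, 1); W <- sample(100:400, 1); s <- sample(c(32, 64, 96), 1)
    p <- tile_patches(sl(H, W), all_tissue(H, W), s, 0.5)
    expect_equal(nrow(p), (H %/% s) * (W %/% s))
  }

  # mask covering the left half at threshold 0.5 -> left column only
  half <- structure(list(mask = cbind(matrix(TRUE, 256, 128),
                                      matrix(FALSE, 256, 128)),
                         downsample = 1, threshold_used = 1),
                    class = "tissue_mask")
  p <- tile_patches(sl(256, 256), half, 128, 0.5)
  expect_equal(nrow(p), 2)
  expect_true(all(p$x == 0))
})

test_that("patch manifests and tissue masks round-trip through files", {
  cfg <- synthetic_config(patches_per_slide = 9, patch_size = 64)
  g <- gen_slide(cfg, "O3", seed = 2)
  sl <- slide_record("sA", "pA", g$image, label = "O3")
  m <- segment_tissue(sl, 4)
  p <- tile_patches(sl, m, 64, 0.5)

  f <- tempfile(fileext = ".csv")
  write_patch_manifest(p, f)
  expect_equal(read_patch_manifest(f), p)

  mf <- tempfile(fileext = ".png")
  write_tissue_mask(m, mf)
  m2 <- read_tissue_mask(mf)
  expect_identical(m2$mask, m$mask)
  expect_equal(m2$threshold_used, m$threshold_used, tolerance = 1e-9)

  imgf <- tempfile(fileext = ".png")
  write_slide_image(g$image, imgf)
  expect_lt(max(abs(read_slide_image(imgf) - g$image)), 0.51)  # 8-bit rounding
})

test_that("slide_record validates its metadata", {
  img <- array(0, c(4, 4, 3))
  expect_error(slide_record("s", "p", img, mpp = -1), "mpp")
  expect_error(slide_record("s", "p", img, label = "X9"), "label")
  expect_error(slide_record("s", "p", array(0, c(4, 4))), "path")
})
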