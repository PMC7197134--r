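test_that("loadScene normalises bit depth to [0,1]", {
  # 8-bit PNG with full-scale pixel -> max 1.0
  px <- array(0, c(20, 24, 3))
  px[1, 1, ] <- 1
  f <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(aperm(px, c(2, 1, 3)),
                                     colormode = "Color"), f, bits.per.sample = 8)
  sc <- loadScene(f)
  expect_equal(max(pixels(sc)), 1.0)
  expect_identical(scaleFactor(sc), 1L)

  # all-zero image -> all pixels 0
  f0 <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(array(0, c(24, 20, 3)),
                                     colormode = "Color"), f0)
  expect_true(all(pixels(loadScene(f0)) == 0))

  # 14-bit data in a 16-bit container, uniform mid-scale value 8191 -> ~0.5
  f14 <- tempfile(fileext = ".tif")
  EBImage::writeImage(EBImage::Image(matrix(8191 / 65535, 24, 20)), f14,
                      bits.per.sample = 16)
  sc14 <- loadScene(f14, bitDepth = 14)
  expect_equal(mean(pixels(sc14)), 8191 / 16383, tolerance = 1e-4)

  expect_error(loadScene(tempfile()), "no such file")
  fbad <- tempfile(fileext = ".tif")
  writeLines("not an image", fbad)
  expect_error(loadScene(fbad), "format")
})

test_that("downscaleScene does block means and tracks scale", {
  const <- SceneImage(array(0.4, c(16, 24, 3)))
  d <- downscaleScene(const, 16)
  expect_identical(dim(pixels(d)), c(4L, 6L, 3L))
  expect_true(all(abs(pixels(d) - 0.4) < 1e-12))
  expect_identical(scaleFactor(d), 4L)

  expect_identical(pixels(downscaleScene(const, 1)), pixels(const))

  # 8x8 checkerboard, factor 16 -> 2x2 of 0.5 (oracle: explicit block means)
  chk <- array(0, c(8, 8, 3))
  pattern <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  for (ch in 1:3) chk[, , ch] <- pattern
  d2 <- downscaleScene(SceneImage(chk), 16)
  expect_identical(dim(pixels(d2))[1:2], c(2L, 2L))
  expect_true(all(abs(pixels(d2) - 0.5) < 1e-12))

  expect_error(downscaleScene(const, 12), "perfect square")
})

test_that("segmentLightTable finds the bright table and rejects dark scenes", {
  flat <- SceneImage(array(0.85, c(32, 40, 3)))
  bg <- segmentLightTable(flat)
  expect_true(all(bg@mask))
  expect_equal(bg@coverageFraction, 1.0)

  ell <- brightFieldWithEllipse()
  bg2 <- segmentLightTable(ell$scene)
  # oracle: threshold at the midpoint of the two known intensities
  oracle <- (pixels(ell$scene)[, , 1]) > 0.6
  expect_gt(mean(bg2@mask == oracle), 0.99)
  expect_equal(bg2@coverageFraction, 1 - mean(ell$ellipse), tolerance = 0.02)

  expect_error(segmentLightTable(SceneImage(array(0.05, c(32, 40, 3)))),
               "no light table")
})

test_that("light-table mask is invariant to global intensity scaling", {
  ell <- brightFieldWithEllipse()
  ref <- segmentLightTable(ell$scene)@mask
  for (s in c(0.6, 0.8, 1.0)) {
    scaled <- SceneImage(pixels(ell$scene) * s)
    expect_identical(segmentLightTable(scaled)@mask, ref)
  }
})

test_that("detectSceneObjects classifies leaf, marker and barcode holes", {
  # one hole -> leaf only
  m <- matrix(TRUE, 60, 80)
  m[20:40, 20:50] <- FALSE
  lay <- detectSceneObjects(new("BackgroundMask", mask = m,
                                coverageFraction = mean(m)), margin = 2L)
  expect_length(lay@markerRegion, 0)
  expect_length(lay@barcodeRegion, 0)
  # 0-based half-open with margin 2: rows [17,40), cols [17,50)
  expect_identical(lay@leafRegion, c(17L, 42L, 17L, 52L))

  # big hole + small square hole -> leaf + marker (oracle: area ranking)
  m2 <- matrix(TRUE, 120, 160)
  m2[20:90, 20:100] <- FALSE          # 71 x 81 leaf
  m2[100:109, 130:139] <- FALSE       # 10 x 10 square marker
  lay2 <- detectSceneObjects(new("BackgroundMask", mask = m2,
                                 coverageFraction = mean(m2)))
  expect_identical(lay2@leafRegion[1:2], c(11L, 98L))
  expect_length(lay2@markerRegion, 4)
  expect_length(lay2@barcodeRegion, 0)

  expect_error(detectSceneObjects(new("BackgroundMask",
                                      mask = matrix(TRUE, 20, 20),
                                      coverageFraction = 1)), "no leaf")
})

test_that("synthetic scene layout matches truth regions", {
  sc <- generateScene(syntheticSpec(), seed = 9)
  down <- downscaleScene(sc$scene, 16)
  bg <- segmentLightTable(down)
  lay <- detectSceneObjects(bg, scaleFactor = scaleFactor(down))
  tight <- detectSceneObjects(bg, margin = 0L, scaleFactor = scaleFactor(down))
  expect_length(lay@markerRegion, 4)
  expect_length(lay@barcodeRegion, 4)
  # marker rectangle contains the truth marker within the 8 px margin (x4)
  mr <- lay@markerRegion * scaleFactor(lay)
  tr <- sc$truth@markerRegion
  expect_true(mr[1] <= tr[1] && mr[2] >= tr[2] && mr[3] <= tr[3] &&
              mr[4] >= tr[4])
  # leaf region IoU with the truth leaf bounding box >= 0.9
  idx <- which(sc$truth@leafMask, arr.ind = TRUE)
  tbb <- c(min(idx[, 1]) - 1L, max(idx[, 1]), min(idx[, 2]) - 1L,
           max(idx[, 2]))
  lr <- tight@leafRegion * scaleFactor(tight)
  inter <- max(0, min(lr[2], tbb[2]) - max(lr[1], tbb[1])) *
           max(0, min(lr[4], tbb[4]) - max(lr[3], tbb[3]))
  uni <- (lr[2] - lr[1]) * (lr[4] - lr[3]) +
         (tbb[2] - tbb[1]) * (tbb[4] - tbb[3]) - inter
  expect_gte(inter / uni, 0.9)
})

test_that("hole areas and background area account for the full image", {
  m <- matrix(TRUE, 50, 60)
  m[10:20, 10:25] <- FALSE
  m[30:42, 35:50] <- FALSE
  holes <- sum(!m)
  expect_identical(holes + sum(m), 50L * 60L)
  lay <- detectSceneObjects(new("BackgroundMask", mask = m,
                                coverageFraction = mean(m)), margin = 0L)
  areas <- (lay@leafRegion[2] - lay@leafRegion[1]) *
           (lay@leafRegion[4] - lay@leafRegion[3])
  expect_identical(areas, 13L * 16L)
})

test_that("cropLeaf rescales regions and preserves all leaf pixels", {
  # layout at linear scale 4, rows [10,20) -> full-res rows [40,80)
  lay <- new("SceneLayout", leafRegion = c(10L, 20L, 5L, 15L),
             markerRegion = integer(0), barcodeRegion = integer(0),
             otherRegions = list(), scaleFactor = 4L)
  full <- SceneImage(array(0.7, c(100, 100, 3)))
  crop <- cropLeaf(full, lay)
  expect_identical(dim(pixels(crop))[1:2], c(40L, 40L))
  expect_true(all(pixels(crop) == 0.7))

  sc <- generateScene(smallSceneSpec(), seed = 4)
  down <- downscaleScene(sc$scene, 16)
  lay2 <- detectSceneObjects(segmentLightTable(down),
                             scaleFactor = scaleFactor(down))
  r <- lay2@leafRegion * scaleFactor(lay2)
  inCrop <- matrix(FALSE, nrow(pixels(sc$scene)), ncol(pixels(sc$scene)))
  inCrop[(r[1] + 1):min(r[2], nrow(inCrop)),
         (r[3] + 1):min(r[4], ncol(inCrop))] <- TRUE
  expect_true(all(inCrop[sc$truth@leafMask]))

  # downscale/upscale round trip stays within one block
  for (v in c(3L, 7L, 11L)) {
    expect_lte(abs((v %/% 4L) * 4L - v), 4L)
  }
})

test_that("bayer mosaics demosaic close to the underlying RGB image", {
  sc <- generateScene(smallSceneSpec(noiseSd = 0), seed = 12)
  px <- pixels(sc$scene)
  H <- nrow(px); W <- ncol(px)
  oR <- outer(seq_len(H) %% 2 == 1, seq_len(W) %% 2 == 1) > 0
  oB <- outer(seq_len(H) %% 2 == 0, seq_len(W) %% 2 == 0) > 0
  oG <- !(oR | oB)
  mos <- matrix(0, H, W)
  mos[oR] <- px[, , 1][oR]; mos[oG] <- px[, , 2][oG]; mos[oB] <- px[, , 3][oB]
  f <- tempfile(fileext = ".tif")
  EBImage::writeImage(EBImage::Image(t(mos)), f, bits.per.sample = 16)
  sb <- loadScene(f, sourceKind = "bayer_raw")
  expect_identical(dim(pixels(sb)), dim(px))
  expect_lt(mean(abs(pixels(sb) - px)), 0.02)   # bilinear edge error only
})
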