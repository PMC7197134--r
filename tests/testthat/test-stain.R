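test_that("stain transform closed forms hold", {
  mk <- function(r, g, b) {
    px <- array(0, c(1, 1, 3)); px[1, 1, ] <- c(r, g, b)
    norm <- new("NormImage", pixels = px)
    computeStainMap(norm, leafMaskFrom(matrix(TRUE, 1, 1)))
  }
  # white pixel: zero absorbance, zero stain
  w <- mk(1, 1, 1)
  expect_equal(w@amplitude[1, 1], 0)
  expect_equal(w@theta[1, 1], 0)
  expect_equal(w@stain[1, 1], 0)

  # achromatic pixels: theta = acos(1/sqrt(3)) independent of gray level
  for (g in c(0.1, 0.37, 0.8)) {
    expect_equal(mk(g, g, g)@theta[1, 1], acos(1 / sqrt(3)), tolerance = 1e-12)
  }

  # hand-computed blue pixel (oracle: direct arithmetic of the formulas)
  s <- mk(0.1, 0.1, 0.9)
  a <- -log(c(0.1, 0.1, 0.9))
  rho <- sqrt(sum(a^2))
  th <- acos(a[3] / rho)
  expect_equal(s@amplitude[1, 1], rho, tolerance = 1e-12)
  expect_equal(s@theta[1, 1], th, tolerance = 1e-12)
  expect_equal(s@stain[1, 1], th * rho, tolerance = 1e-12)
  expect_equal(rho, 3.2580, tolerance = 1e-4)
  expect_equal(th, 1.5384, tolerance = 1e-4)
  expect_equal(th * rho, 5.012, tolerance = 1e-3)
})

test_that("stain is zeroed outside the leaf and theta stays in range", {
  px <- array(runif(20 * 20 * 3, 0.05, 1), c(20, 20, 3))
  leaf <- matrix(FALSE, 20, 20); leaf[5:15, 5:15] <- TRUE
  sm <- computeStainMap(new("NormImage", pixels = px), leafMaskFrom(leaf))
  expect_true(all(sm@stain[!leaf] == 0))
  expect_true(all(sm@theta >= 0 & sm@theta <= pi / 2 + 1e-12))
  expect_true(all(abs(sm@stain[leaf] -
                      (sm@theta * sm@amplitude)[leaf]) < 1e-12))
  expect_error(computeStainMap(new("NormImage", pixels = px),
                               leafMaskFrom(leaf), eps = 0.5), "eps")
})

test_that("center-surround kernels are zero-sum with the right support", {
  for (r in c(1L, 3L, 7L, 13L)) {
    for (sh in c("disc", "square")) {
      k <- makeCenterSurroundKernel(r, shape = sh)
      expect_lte(abs(sum(k@weights)), 1e-9)
      expect_identical(k@surroundRadius, 2L * r)
      # positive weights exactly on the inner element
      pos <- k@weights > 0
      d <- nrow(k@weights); ctr <- (d + 1) / 2
      dist <- sqrt(outer((1:d - ctr)^2, (1:d - ctr)^2, "+"))
      if (sh == "disc") expect_identical(pos, dist <= r + 1e-9)
    }
  }
  # r=1 disc: inner cross of 5 px; impulse response at center = 1/5
  k1 <- makeCenterSurroundKernel(1)
  expect_identical(sum(k1@weights > 0), 5L)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  resp <- bruteConvolve(imp, k1@weights)
  expect_equal(resp[5, 5], 1 / 5, tolerance = 1e-12)
  expect_error(makeCenterSurroundKernel(2, surroundFactor = 1), "annulus")
})

test_that("convolution matches the brute-force oracle and kills constants", {
  set.seed(101)
  for (i in 1:8) {
    H <- sample(8:32, 1); W <- sample(8:32, 1)
    x <- matrix(runif(H * W), H, W)
    k <- makeCenterSurroundKernel(sample(1:4, 1))@weights
    expect_lt(max(abs(LesionQuant:::.convolve2(x, k) - bruteConvolve(x, k))),
              1e-8)
  }
  # zero response to constants at every radius
  cst <- matrix(0.7, 30, 30)
  for (r in c(1, 5, 13)) {
    k <- makeCenterSurroundKernel(r)@weights
    expect_lt(max(abs(LesionQuant:::.convolve2(cst, k))), 1e-9)
  }
})

test_that("multiscaleDetect returns one labelled image per radius", {
  blank <- stainMapExact(matrix(0, 40, 40))
  out <- multiscaleDetect(blank, radii = 1:13)
  expect_length(out, 13)
  expect_true(all(vapply(out, max, numeric(1)) == 0))

  # a single isotropic blob is found at every responding scale
  st <- matrix(0, 60, 60)
  st[.blob <- which(LesionQuant:::.discMask(60, 60, 30, 30, 5))] <- 3
  sm <- stainMapExact(st)
  per <- multiscaleDetect(sm)
  expect_length(per, 13)
  responding <- vapply(per, max, numeric(1)) > 0
  expect_true(any(responding))
  for (lab in per[responding]) {
    expect_identical(max(lab), 1L)          # exactly one segment
    expect_gt(lab[30, 30], 0L)              # containing the blob peak
  }
})

test_that("thresholding is at 0.1 of each scale's own maximum", {
  st <- matrix(0, 50, 50)
  st[LesionQuant:::.discMask(50, 50, 25, 25, 4)] <- 2
  sm <- stainMapExact(st)
  r <- 4L
  lab <- multiscaleDetect(sm, radii = r)[[1]]
  resp <- bruteConvolve(st, makeCenterSurroundKernel(r)@weights)
  core <- resp >= 0.1 * max(resp)
  expect_true(all(lab[core] > 0L))          # dilation/fill only grows the set
})

test_that("refineAndCombine applies the 60% range rule and merges scales", {
  # constant stain in the segment: degenerate range keeps everything
  st <- matrix(0, 20, 20); st[8:12, 8:12] <- 2
  lab <- matrix(0L, 20, 20); lab[8:12, 8:12] <- 1L
  out <- refineAndCombine(list(lab), stainMapExact(st))
  expect_identical(sum(out@labels > 0L), 25L)

  # linear ramp 0..1 over the segment: ~40% of pixels kept
  n <- 1000
  ramp <- matrix(seq(0, 1, length.out = n), 1, n)
  labr <- matrix(1L, 1, n)
  outr <- refineAndCombine(list(labr), stainMapExact(ramp))
  expect_equal(sum(outr@labels > 0L) / n, 0.4, tolerance = 0.01)

  # two scales detecting the same blob: OR yields one lesion
  out2 <- refineAndCombine(list(lab, lab), stainMapExact(st))
  expect_identical(nLesions(out2), 1L)
})

test_that("final lesion pixels lie in the leaf at/above a refinement level", {
  sc <- generateScene(smallSceneSpec(), seed = 6)
  res <- processScene(sc$scene, runConfig(list(), seed = 6))
  lab <- res$table@labels@labels
  expect_true(all(res$stain@leaf[lab > 0L]))
  per <- multiscaleDetect(res$stain)
  st <- res$stain@stain
  levels <- list()
  ok <- matrix(FALSE, nrow(st), ncol(st))
  for (pl in per) {
    idx <- which(pl > 0L)
    for (px in split(idx, pl[idx])) {
      s <- st[px]
      lev <- min(s) + 0.6 * (max(s) - min(s))
      ok[px[s >= lev]] <- TRUE
    }
  }
  expect_true(all(ok[lab > 0L]))
})

test_that("an isolated bright single pixel is detected at radius 1", {
  st <- matrix(0.05, 40, 40)   # faint residual background
  st[20, 20] <- 1              # 1-px lesion, 20x the residual
  sm <- stainMapExact(st)
  lab1 <- multiscaleDetect(sm, radii = 1L)[[1]]
  expect_gt(lab1[20, 20], 0L)
  final <- refineAndCombine(multiscaleDetect(sm), sm)
  expect_gte(nLesions(final), 1L)
  expect_gt(final@labels[20, 20], 0L)
})

test_that("adding a disjoint lesion never decreases count or area", {
  set.seed(77)
  for (rep in 1:4) {
    st <- matrix(0.02, 80, 80)
    centers <- cbind(sample(15:65, 4), sample(15:65, 4))
    while (min(dist(centers)) < 20) centers <- cbind(sample(15:65, 4),
                                                     sample(15:65, 4))
    for (i in 1:3)
      st[LesionQuant:::.discMask(80, 80, centers[i, 1], centers[i, 2], 4)] <- 3
    base <- refineAndCombine(multiscaleDetect(stainMapExact(st)),
                             stainMapExact(st))
    st2 <- st
    st2[LesionQuant:::.discMask(80, 80, centers[4, 1], centers[4, 2], 4)] <- 3
    more <- refineAndCombine(multiscaleDetect(stainMapExact(st2)),
                             stainMapExact(st2))
    expect_gte(nLesions(more), nLesions(base))
    expect_gte(sum(more@labels > 0L), sum(base@labels > 0L))
  }
})
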