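test_that("calibration converts marker pixels to physical scale", {
  expect_equal(calibrate(10000)@um2PerPx, 10000)      # 1e8 / 1e4
  expect_identical(calibrate(10000)@source, "marker")
  expect_equal(calibrate(NULL)@um2PerPx, 1800)
  expect_identical(calibrate(NULL)@source, "config")
  expect_error(calibrate(0), "positive")
  expect_error(calibrate(NULL, fallbackUm2PerPx = NULL), "no size marker")
})

test_that("lesion size classes partition areas at 1 and 200 px", {
  expect_identical(classifyLesion(1L), "micro")
  expect_identical(classifyLesion(2L), "meso")
  expect_identical(classifyLesion(200L), "meso")
  expect_identical(classifyLesion(201L), "macro")
  expect_identical(classifyLesion(c(1, 150, 5000)),
                   c("micro", "meso", "macro"))
  expect_error(classifyLesion(0L), ">= 1")
})

.measureFixture <- function(labels, leaf = NULL) {
  H <- nrow(labels); W <- ncol(labels)
  if (is.null(leaf)) leaf <- matrix(TRUE, H, W)
  st <- new("StainMap", theta = matrix(1.2, H, W),
            amplitude = matrix(2, H, W),
            stain = matrix(2.4, H, W) * leaf, leaf = leaf)
  measureLesions(labelMapFrom(labels), st, leafMaskFrom(leaf),
                 calibrate(NULL), imageId = "fixture")
}

test_that("measureLesions computes closed-form morphometrics", {
  # single-pixel lesion
  lab <- matrix(0L, 30, 30); lab[15, 15] <- 1L
  t1 <- .measureFixture(lab)
  r <- t1@records
  expect_identical(r$area_px, 1L)
  expect_equal(r$area_um2, 1800)
  expect_equal(r$eccentricity, 0)
  expect_equal(r$log_sqrt_area, log10(1.1), tolerance = 1e-12)
  expect_identical(r$class, "micro")
  expect_equal(r$perimeter_px, 4)

  # 5x5 square lesion
  lab2 <- matrix(0L, 30, 30); lab2[10:14, 12:16] <- 1L
  t2 <- .measureFixture(lab2)
  r2 <- t2@records
  expect_identical(r2$area_px, 25L)
  expect_identical(c(r2$bbox_h, r2$bbox_w), c(5L, 5L))
  expect_equal(r2$equiv_diameter_px, sqrt(4 * 25 / pi), tolerance = 1e-12)
  expect_equal(r2$equiv_diameter_px, 5.64, tolerance = 1e-2)
  expect_equal(r2$perimeter_px, 20)
  expect_equal(r2$circularity, min(1, 4 * pi * 25 / 400), tolerance = 1e-12)
  expect_equal(r2$centroid_row, 12)
  expect_identical(r2$class, "meso")

  # an elongated lesion is more eccentric than a square one
  lab3 <- matrix(0L, 30, 30); lab3[10, 5:25] <- 1L
  expect_gt(.measureFixture(lab3)@records$eccentricity, 0.95)
})

test_that("location features follow the leaf geometry", {
  # horizontal elliptical leaf: principal axis is the horizontal centreline
  leaf <- LesionQuant:::.discMask(61, 101, 31, 51, 0)  # placeholder
  r <- matrix(seq_len(61), 61, 101); c <- matrix(seq_len(101), 61, 101,
                                                 byrow = TRUE)
  leaf <- ((r - 31) / 20)^2 + ((c - 51) / 45)^2 <= 1
  lab <- matrix(0L, 61, 101)
  lab[30:32, 70:72] <- 1L   # centered on the axis row 31
  lab[20:22, 40:42] <- 2L   # 10 px off the axis
  st <- new("StainMap", theta = matrix(1, 61, 101),
            amplitude = matrix(1, 61, 101), stain = 1 * leaf, leaf = leaf)
  tb <- measureLesions(labelMapFrom(lab), st, leafMaskFrom(leaf),
                       calibrate(NULL))
  expect_lt(tb@records$dist_centreline_px[1], 0.5)
  expect_equal(tb@records$dist_centreline_px[2], 10, tolerance = 0.5)
  # edge distance: interior lesion is farther from the edge than a rim one
  expect_gt(tb@records$dist_edge_px[1], 5)
})

test_that("damageSummary aggregates kept lesions", {
  lab <- matrix(0L, 40, 50)
  lab[5:9, 5:14] <- 1L     # 50 px
  leaf <- matrix(TRUE, 40, 50)
  st <- new("StainMap", theta = matrix(1, 40, 50),
            amplitude = matrix(1, 40, 50), stain = matrix(1, 40, 50),
            leaf = leaf)
  tb <- measureLesions(labelMapFrom(lab), st, leafMaskFrom(leaf),
                       calibrate(NULL))
  expect_equal(damagePercent(tb), 100 * 50 / 2000)
  s <- damageSummary(tb)
  expect_identical(s$n_meso, 1L)
  expect_equal(s$damage_percent, 2.5)
  expect_equal(s$lesion_area_um2, 50 * 1800)

  # no lesions -> 0%
  t0 <- measureLesions(labelMapFrom(matrix(0L, 40, 50)), st,
                       leafMaskFrom(leaf), calibrate(NULL))
  expect_equal(damagePercent(t0), 0)
  expect_identical(damageSummary(t0)$n_lesions, 0L)

  # lesion area equal to leaf area -> 100%
  lab2 <- matrix(1L, 40, 50)
  expect_equal(damagePercent(measureLesions(labelMapFrom(lab2), st,
                                            leafMaskFrom(leaf),
                                            calibrate(NULL))), 100)
})

test_that("damage is bounded and decreases when lesions are unkept", {
  sc <- generateScene(smallSceneSpec(), seed = 13)
  res <- processScene(sc$scene, runConfig(list(), seed = 13))
  tb <- res$table
  expect_gte(damagePercent(tb), 0)
  expect_lte(damagePercent(tb), 100)
  expect_equal(tb@records$area_um2, tb@records$area_px * res$cal@um2PerPx)
  if (nrow(tb@records) >= 1) {
    asg <- new("ClusterAssignment", k = nrow(tb@records),
               labels = seq_len(nrow(tb@records)), seed = 1L, inertia = 0)
    dropped <- applyFilter(tb, asg, 1L)
    expect_lt(damagePercent(dropped), damagePercent(tb))
  }
})

test_that("per-lesion area recovery is accurate on noiseless scenes", {
  sc <- generateScene(smallSceneSpec(noiseSd = 0), seed = 17)
  res <- processScene(sc$scene, runConfig(list(), seed = 17))
  cr <- res$cropRect
  tr <- sc$truth@lesionLabels[(cr[1] + 1):cr[2], (cr[3] + 1):cr[4]]
  det <- res$table@labels@labels
  for (tid in seq_len(max(tr))) {
    tmask <- tr == tid
    dl <- unique(det[tmask]); dl <- dl[dl > 0]
    got <- sum(det %in% dl)
    expect_lt(abs(got - sum(tmask)) / sum(tmask), 0.2)
  }
  # total damage within 10% relative of truth
  rep <- scoreAgainstTruth(res$table, sc$truth, cropRect = cr)
  expect_lt(abs(rep$leafAreaError), 0.02)
})
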