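# Synthetic light-table scenes with full ground truth: a bright uneven
# background, a cream cleared leaf with midrib, blue-absorbing lesions
# with darker cores, achromatic-dark confounder patches (uneven
# clearing), real holes, a square 1-cm^2 size marker and a barcode label.

#' Specify a synthetic scene
#'
#' Defaults emulate a backlit light table photographed from a fixed
#' height: near-white background with a smooth uneven-illumination field,
#' a cream/yellow cleared leaf (`leafColor`) with a darker midrib band,
#' disc lesions whose red/green transmission drops to `lesionRimFactor`
#' at the rim and `lesionCoreFactor` in the darker core (blue largely
#' transmitted, so they look blue), optional elongated "cut" lesions,
#' achromatic-dark confounder patches, real holes, a dark square size
#' marker and an elongated barcode region, plus Gaussian pixel noise.
#'
#' @param width,height scene size in px (default 420 x 320).
#' @param backgroundBase per-channel background transmission.
#' @param backgroundGradient relative amplitude of the illumination field.
#' @param leafCenter fractional (row, col) position of the leaf center.
#' @param leafRadii leaf semi-axes (row, col) in px.
#' @param leafColor per-channel leaf transmission.
#' @param midribFactor transmission multiplier of the midrib band.
#' @param nLesions number of disc lesions.
#' @param lesionRadiusRange min/max disc radius in px; radius 0 renders a
#'   single-pixel lesion.
#' @param lesionCoreFactor,lesionRimFactor red/green transmission
#'   multipliers of the core and rim.
#' @param nCuts number of elongated cut lesions (capsules).
#' @param cutLength,cutHalfWidth capsule length and half-width in px.
#' @param nConfounders number of achromatic-dark patches.
#' @param confounderFactor their all-channel transmission multiplier.
#' @param confounderRadiusRange min/max confounder radius in px.
#' @param nHoles number of real holes in the leaf.
#' @param holeRadiusRange min/max hole radius in px.
#' @param marker include the 1-cm^2 size marker square.
#' @param markerSide marker side in px.
#' @param barcode include the barcode label region.
#' @param noiseSd Gaussian noise standard deviation.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(width = 420L, height = 320L,
                          backgroundBase = c(0.93, 0.92, 0.90),
                          backgroundGradient = 0.06,
                          leafCenter = c(0.5, 0.42),
                          leafRadii = c(105, 125),
                          leafColor = c(0.75, 0.70, 0.55),
                          midribFactor = 0.8,
                          nLesions = 12L,
                          lesionRadiusRange = c(3, 20),
                          lesionCoreFactor = 0.10,
                          lesionRimFactor = 0.16,
                          nCuts = 0L, cutLength = 80, cutHalfWidth = 3,
                          nConfounders = 0L, confounderFactor = 0.45,
                          confounderRadiusRange = c(4, 9),
                          nHoles = 0L, holeRadiusRange = c(4, 8),
                          marker = TRUE, markerSide = 36L,
                          barcode = TRUE, noiseSd = 0.01) {
  new("SyntheticSpec", width = as.integer(width), height = as.integer(height),
      backgroundBase = backgroundBase, backgroundGradient = backgroundGradient,
      leafCenter = leafCenter, leafRadii = leafRadii, leafColor = leafColor,
      midribFactor = midribFactor, nLesions = as.integer(nLesions),
      lesionRadiusRange = lesionRadiusRange,
      lesionCoreFactor = lesionCoreFactor, lesionRimFactor = lesionRimFactor,
      nCuts = as.integer(nCuts), cutLength = cutLength,
      cutHalfWidth = cutHalfWidth,
      nConfounders = as.integer(nConfounders),
      confounderFactor = confounderFactor,
      confounderRadiusRange = confounderRadiusRange,
      nHoles = as.integer(nHoles), holeRadiusRange = holeRadiusRange,
      marker = marker, markerSide = as.integer(markerSide),
      barcode = barcode, noiseSd = noiseSd)
}

#' Standardised artificial damage presets
#'
#' Six severity levels of standardised artificial damage: level 0 is an
#' undamaged (negative-control) leaf; levels 1-2 carry few small lesions
#' (low severity), levels 3-4 many/larger ones (high severity), and level
#' 5 adds elongated cuts that render as macrolesions (> 200 px).
#'
#' @param level integer 0-5.
#' @param ... overrides passed on to [syntheticSpec()].
#' @return A [SyntheticSpec-class].
#' @export
damagePreset <- function(level, ...) {
  if (!level %in% 0:5) .stopf("damage level must be in 0..5")
  args <- switch(as.character(level),
    "0" = list(nLesions = 0L,  lesionRadiusRange = c(2, 4)),
    "1" = list(nLesions = 6L,  lesionRadiusRange = c(2, 4)),
    "2" = list(nLesions = 12L, lesionRadiusRange = c(2, 6)),
    "3" = list(nLesions = 18L, lesionRadiusRange = c(4, 10)),
    "4" = list(nLesions = 26L, lesionRadiusRange = c(5, 12)),
    "5" = list(nLesions = 22L, lesionRadiusRange = c(6, 13),
               nCuts = 3L, cutLength = 80, cutHalfWidth = 3))
  do.call(syntheticSpec, utils::modifyList(args, list(...)))
}

# Place discs inside `allowed` (logical matrix), keeping `gap` px between
# footprints; returns a data.frame(row, col, radius). Radii are shrunk
# and eventually dropped when space runs out.
.placeDiscs <- function(allowed, radii, gap = 6L, dm = NULL) {
  H <- nrow(allowed); W <- ncol(allowed)
  if (is.null(dm))
    dm <- EBImage::distmap(matrix(as.numeric(allowed), H, W))
  placed <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
  for (r in radii) {
    rr <- r
    repeat {
      ok <- FALSE
      for (attempt in seq_len(200L)) {
        i <- sample.int(H * W, 1L)
        pr <- .rowOf(i, H); pc <- .colOf(i, H)
        if (dm[pr, pc] < rr + 3) next
        if (nrow(placed)) {
          dmin <- min(sqrt((placed$row - pr)^2 + (placed$col - pc)^2) -
                        placed$radius)
          if (dmin < rr + gap) next
        }
        placed <- rbind(placed, data.frame(row = pr, col = pc, radius = rr))
        ok <- TRUE
        break
      }
      if (ok || rr <= 0) break
      rr <- rr - 1   # shrink and retry; drop once radius underflows
      if (rr < 0) break
    }
  }
  placed
}

.discMask <- function(H, W, row, col, radius) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  (r - row)^2 + (c - col)^2 <= radius^2 + 1e-9
}

# Capsule (stadium): all pixels within halfWidth of a segment.
.capsuleMask <- function(H, W, r0, c0, r1, c1, halfWidth) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  vr <- r1 - r0; vc <- c1 - c0
  len2 <- vr^2 + vc^2
  t <- .clamp(((r - r0) * vr + (c - c0) * vc) / max(len2, 1e-9), 0, 1)
  (r - (r0 + t * vr))^2 + (c - (c0 + t * vc))^2 <= halfWidth^2 + 1e-9
}

#' Generate a synthetic scene with ground truth
#'
#' Renders the scene described by `spec` deterministically for the given
#' seed: transmission of each object multiplies the smooth background
#' illumination field, Gaussian noise is added last, and every truth mask
#' is consistent with the rendered image by construction.
#'
#' @param spec a [SyntheticSpec-class].
#' @param seed RNG seed; the same (spec, seed) pair reproduces the scene
#'   bit for bit.
#' @return A list with elements `scene` ([SceneImage-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
generateScene <- function(spec, seed = 1L) {
  .withSeed(seed, .renderScene(spec, seed))
}

.renderScene <- function(spec, seed) {
  H <- spec@height; W <- spec@width
  rn <- matrix(seq_len(H), H, W) / H - 0.5
  cn <- matrix(seq_len(W), H, W, byrow = TRUE) / W - 0.5
  g <- spec@backgroundGradient
  field <- 1 + g * (runif(1, -1, 1) * rn + runif(1, -1, 1) * cn +
                    0.5 * sin(2 * pi * (runif(1) + rn * runif(1, 0.5, 1.5))) *
                    cos(2 * pi * (runif(1) + cn * runif(1, 0.5, 1.5))))
  bg <- array(0, c(H, W, 3))
  for (ch in 1:3) bg[, , ch] <- .clamp(spec@backgroundBase[ch] * field,
                                       0.2, 0.995)

  # leaf: wobbled ellipse
  ctr <- c(spec@leafCenter[1] * H, spec@leafCenter[2] * W)
  dr <- matrix(seq_len(H), H, W) - ctr[1]
  dc <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2]
  phi <- atan2(dr, dc)
  wob <- 1 + 0.04 * sin(3 * phi + runif(1, 0, 2 * pi)) +
             0.03 * sin(5 * phi + runif(1, 0, 2 * pi))
  rad <- sqrt((dr / spec@leafRadii[1])^2 + (dc / spec@leafRadii[2])^2)
  leafAll <- rad <= wob
  # midrib: darker band along the (horizontal) major axis, tapering
  halfLen <- spec@leafRadii[2]
  taper <- pmax(0, 1 - abs(dc) / (1.05 * halfLen))
  midrib <- leafAll & abs(dr) <= 2.5 * taper + 0.5

  trans <- array(1, c(H, W, 3))
  for (ch in 1:3) {
    plane <- trans[, , ch]
    plane[leafAll] <- spec@leafColor[ch]
    plane[midrib] <- plane[midrib] * spec@midribFactor
    trans[, , ch] <- plane
  }

  # real holes: punched out of the leaf, transmission back to 1
  holeMask <- matrix(FALSE, H, W)
  if (spec@nHoles > 0L) {
    interior <- EBImage::distmap(matrix(as.numeric(leafAll), H, W)) >
      max(spec@holeRadiusRange) + 6
    hp <- .placeDiscs(matrix(interior, H, W),
                      round(runif(spec@nHoles, spec@holeRadiusRange[1],
                                  spec@holeRadiusRange[2])))
    for (i in seq_len(nrow(hp)))
      holeMask <- holeMask | .discMask(H, W, hp$row[i], hp$col[i], hp$radius[i])
    for (ch in 1:3) {
      plane <- trans[, , ch]; plane[holeMask] <- 1; trans[, , ch] <- plane
    }
  }
  leafTissue <- leafAll & !holeMask

  # lesions: discs (+ capsule cuts), blue-transmitting with darker core
  lesionLabels <- matrix(0L, H, W)
  nextLab <- 0L
  allowed <- leafTissue
  radii <- if (spec@nLesions > 0L)
    round(runif(spec@nLesions, spec@lesionRadiusRange[1],
                spec@lesionRadiusRange[2])) else integer(0)
  pl <- .placeDiscs(allowed, radii)
  lesionMasks <- list()
  for (i in seq_len(nrow(pl))) {
    m <- .discMask(H, W, pl$row[i], pl$col[i], pl$radius[i]) & leafTissue
    if (!any(m)) next
    core <- .discMask(H, W, pl$row[i], pl$col[i],
                      max(0.55 * pl$radius[i], 0)) & m
    if (!any(core)) core <- m   # 1-px lesions are all core
    lesionMasks <- c(lesionMasks, list(list(m = m, core = core)))
  }
  if (spec@nCuts > 0L) {
    dmLeaf <- EBImage::distmap(matrix(as.numeric(leafTissue), H, W))
    for (i in seq_len(spec@nCuts)) {
      for (attempt in seq_len(200L)) {
        j <- sample.int(H * W, 1L)
        pr <- .rowOf(j, H); pc <- .colOf(j, H)
        if (dmLeaf[pr, pc] < spec@cutHalfWidth + 4) next
        ang <- runif(1, 0, pi)
        er <- pr + spec@cutLength * sin(ang); ec <- pc + spec@cutLength * cos(ang)
        m <- .capsuleMask(H, W, pr, pc, er, ec, spec@cutHalfWidth) & leafTissue
        if (sum(m) < 0.7 * spec@cutLength * 2 * spec@cutHalfWidth) next
        if (.anyOverlap(m, lesionMasks)) next
        core <- .capsuleMask(H, W, pr, pc, er, ec,
                             max(1, 0.55 * spec@cutHalfWidth)) & m
        lesionMasks <- c(lesionMasks, list(list(m = m, core = core)))
        break
      }
    }
  }
  for (les in lesionMasks) {
    nextLab <- nextLab + 1L
    lesionLabels[les$m] <- nextLab
    for (ch in 1:2) {
      plane <- trans[, , ch]
      plane[les$m] <- spec@leafColor[ch] * spec@lesionRimFactor
      plane[les$core] <- spec@leafColor[ch] * spec@lesionCoreFactor
      trans[, , ch] <- plane
    }
    plane <- trans[, , 3]
    plane[les$m] <- spec@leafColor[3] * 0.95
    trans[, , 3] <- plane
  }

  # confounders: achromatic dark patches, away from lesions
  confMask <- matrix(FALSE, H, W)
  if (spec@nConfounders > 0L) {
    away <- leafTissue & !.dilate3(lesionLabels > 0L)
    cp <- .placeDiscs(away,
                      round(runif(spec@nConfounders,
                                  spec@confounderRadiusRange[1],
                                  spec@confounderRadiusRange[2])))
    for (i in seq_len(nrow(cp))) {
      m <- .discMask(H, W, cp$row[i], cp$col[i], cp$radius[i]) & leafTissue &
        !(lesionLabels > 0L)
      confMask <- confMask | m
    }
    for (ch in 1:3) {
      plane <- trans[, , ch]
      plane[confMask] <- plane[confMask] * spec@confounderFactor
      trans[, , ch] <- plane
    }
  }

  # size marker: dark square on clear background, right of the leaf
  markerRegion <- integer(0)
  if (spec@marker) {
    s <- spec@markerSide
    mr0 <- round(0.55 * H); mc0 <- round(0.82 * W)
    if (mr0 + s <= H && mc0 + s <= W) {
      rows <- mr0 + seq_len(s); cols <- mc0 + seq_len(s)
      for (ch in 1:3) trans[rows, cols, ch] <- 0.05
      markerRegion <- as.integer(c(mr0, mr0 + s, mc0, mc0 + s))
    }
  }
  # barcode: elongated dark striped label, bottom right
  if (spec@barcode) {
    bh <- round(0.08 * H); bw <- round(0.3 * W)
    br0 <- round(0.02 * H); bc0 <- round(0.55 * W)
    if (br0 + bh <= H && bc0 + bw <= W) {
      rows <- br0 + seq_len(bh); cols <- bc0 + seq_len(bw)
      stripes <- 0.10 + 0.15 * (seq_len(bw) %% 5 < 2)
      for (ch in 1:3)
        trans[rows, cols, ch] <- matrix(stripes, bh, bw, byrow = TRUE)
    }
  }

  px <- bg * trans
  if (spec@noiseSd > 0)
    px <- px + array(rnorm(length(px), 0, spec@noiseSd), dim(px))
  px <- .clamp(px, 0, 1)

  nLes <- max(lesionLabels)
  areas <- if (nLes > 0L) tabulate(lesionLabels[lesionLabels > 0L], nLes)
           else integer(0)
  truth <- new("GroundTruth",
    leafMask = leafTissue, lesionLabels = lesionLabels,
    lesionAreas = as.integer(areas),
    lesionClasses = if (nLes) classifyLesion(areas) else character(0),
    confounderMask = confMask, holeMask = holeMask,
    markerRegion = markerRegion,
    damagePercentTrue = 100 * sum(areas) / sum(leafTissue))
  list(scene = SceneImage(px, scaleFactor = 1L, sourceKind = "synthetic",
                          id = sprintf("synthetic_seed%d", seed)),
       truth = truth)
}

.anyOverlap <- function(m, lesionMasks) {
  for (l in lesionMasks) if (any(m & l$m)) return(TRUE)
  FALSE
}

#' Score detections against synthetic ground truth
#'
#' Matches detected lesions to truth lesions greedily by decreasing
#' intersection-over-union (IoU >= `iouMin`; each lesion matched at most
#' once). A detection is *merged* if it covers at least half of two or
#' more truth lesions; a truth lesion is *split* if two or more
#' detections lie mostly (>= half their own area) inside it. False
#' negatives are truths neither matched nor half-covered by any
#' detection; false positives are detections neither matched nor lying
#' mostly within any truth.
#'
#' @param table a [LesionTable-class] from the pipeline (its label map is
#'   used); only kept lesions are scored.
#' @param truth the [GroundTruth-class] of the same scene.
#' @param iouMin IoU threshold for matching (default 0.3; strict IoU is
#'   unstable for 1-px lesions).
#' @param cropRect optional 0-based half-open `c(row0, row1, col0, col1)`
#'   rectangle (e.g. `cropRect` from [processScene()]) locating the
#'   detection label map inside the full truth scene.
#' @return A list with counts (`matched`, `falseNegative`,
#'   `falsePositive`, `merged`, `split`, `nTruth`, `nDetected`) and
#'   relative errors (`leafAreaError`, `damageError`, both signed,
#'   detected minus truth over truth).
#' @export
scoreAgainstTruth <- function(table, truth, iouMin = 0.3, cropRect = NULL) {
  det <- table@labels@labels
  tru <- truth@lesionLabels
  truLeafMask <- truth@leafMask
  if (!is.null(cropRect)) {
    rows <- (cropRect[1] + 1L):cropRect[2]
    cols <- (cropRect[3] + 1L):cropRect[4]
    tru <- tru[rows, cols]
    truLeafMask <- truLeafMask[rows, cols]
  }
  if (!identical(dim(det), dim(tru)))
    .stopf("detection and truth label maps differ in shape")
  kept <- table@records$label[table@records$kept]
  det[!(det %in% kept)] <- 0L
  detIds <- sort(unique(det[det > 0L]))
  truIds <- seq_len(max(tru))
  nD <- length(detIds); nT <- length(truIds)
  detArea <- tabulate(det[det > 0L], max(det, 1L))[detIds]
  truArea <- truth@lesionAreas
  inter <- matrix(0, nT, max(nD, 1))
  if (nD && nT) {
    both <- det > 0L & tru > 0L
    if (any(both)) {
      tab <- table(factor(tru[both], levels = truIds),
                   factor(det[both], levels = detIds))
      inter <- matrix(as.numeric(tab), nT, nD)
    }
  }
  matchedT <- logical(nT); matchedD <- logical(max(nD, 1)); matched <- 0L
  if (nD && nT && any(inter > 0)) {
    iou <- inter / (outer(truArea, detArea, "+") - inter)
    ord <- order(-iou)
    for (o in ord) {
      if (iou[o] < iouMin) break
      ti <- (o - 1) %% nT + 1; di <- (o - 1) %/% nT + 1
      if (matchedT[ti] || matchedD[di]) next
      matchedT[ti] <- TRUE; matchedD[di] <- TRUE; matched <- matched + 1L
    }
  }
  coverT <- if (nT && nD) inter / truArea else matrix(0, max(nT, 1), max(nD, 1))
  coverD <- if (nT && nD) t(t(inter) / detArea) else matrix(0, max(nT, 1), max(nD, 1))
  mergedCount <- if (nD && nT) sum(colSums(coverT >= 0.5) >= 2) else 0L
  splitCount <- if (nD && nT) sum(rowSums(coverD >= 0.5) >= 2) else 0L
  fn <- if (nT) sum(!matchedT &
                    (if (nD) apply(coverT, 1, max) else 0) < 0.5) else 0L
  fp <- if (nD) sum(!matchedD[seq_len(nD)] &
                    (if (nT) apply(coverD, 2, max) else 0) < 0.5) else 0L
  detLeaf <- table@leafAreaPx
  truLeaf <- sum(truLeafMask)
  detDamage <- table@damagePercent
  list(matched = matched, falseNegative = as.integer(fn),
       falsePositive = as.integer(fp), merged = as.integer(mergedCount),
       split = as.integer(splitCount), nTruth = nT, nDetected = nD,
       leafAreaError = (detLeaf - truLeaf) / truLeaf,
       damageError = if (truth@damagePercentTrue > 0)
         (detDamage - truth@damagePercentTrue) / truth@damagePercentTrue
       else detDamage)
}
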