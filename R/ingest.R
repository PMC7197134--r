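# Scene ingestion: loading, downscaling, light-table segmentation and
# leaf/marker/barcode localisation on the downscaled scene.

#' Load a light-table scene image
#'
#' Reads a raster image and linearly scales pixel values to `[0,1]`.
#' `sourceKind = "rgb_file"` accepts TIFF/PNG/JPEG; grayscale input is
#' replicated to three channels. `sourceKind = "bayer_raw"` reads a
#' single-channel RGGB colour-filter-array mosaic (stored as TIFF/PNG) and
#' demosaics it bilinearly. For sensors that fill only part of the stored
#' container (e.g. 14-bit data in a 16-bit file), `bitDepth` rescales so
#' that sensor full scale maps to 1.
#'
#' @param path image file path.
#' @param sourceKind `"rgb_file"` (default) or `"bayer_raw"`.
#' @param bitDepth optional true sensor bit depth of data stored in a
#'   16-bit container.
#' @return A [SceneImage-class] at full resolution (`scaleFactor = 1`).
#' @export
loadScene <- function(path, sourceKind = c("rgb_file", "bayer_raw"),
                      bitDepth = NULL) {
  sourceKind <- match.arg(sourceKind)
  if (!file.exists(path)) .stopf("cannot read scene image '%s': no such file", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) .stopf(
                    "unsupported or corrupt image format in '%s': %s",
                    path, conditionMessage(e)))
  a <- as.array(img)
  if (!is.null(bitDepth)) {
    # 16-bit container: readImage divided by 65535, renormalise to sensor range
    a <- .clamp(a * (65535 / (2^bitDepth - 1)), 0, 1)
  }
  if (sourceKind == "bayer_raw") {
    if (length(dim(a)) == 3L) a <- a[, , 1]
    mosaic <- t(a)   # EBImage stores x,y; use row,col
    px <- .demosaicBilinear(mosaic)
  } else {
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    px <- aperm(a, c(2, 1, 3))
  }
  px <- .clamp(px, 0, 1)
  if (nrow(px) < 16L || ncol(px) < 16L)
    .stopf("scene '%s' is smaller than 16 x 16 px", path)
  SceneImage(px, scaleFactor = 1L, sourceKind = sourceKind, id = path)
}

# Bilinear demosaicing of an RGGB mosaic (row, col indexed, 1-based:
# odd/odd = R, odd/even = G, even/odd = G, even/even = B).
.demosaicBilinear <- function(m) {
  H <- nrow(m); W <- ncol(m)
  kDiag <- matrix(c(1, 0, 1, 0, 0, 0, 1, 0, 1) / 4, 3, 3)
  kPlus <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0) / 4, 3, 3)
  oddR <- (seq_len(H) %% 2L) == 1L
  oddC <- (seq_len(W) %% 2L) == 1L
  maskR <- outer(oddR, oddC) > 0
  maskG <- xor(matrix(oddR, H, W), matrix(oddC, H, W, byrow = TRUE))
  maskB <- outer(!oddR, !oddC) > 0
  interp <- function(mask) {
    v <- m * mask
    w <- matrix(as.numeric(mask), H, W)
    # spread sample values/weights until every pixel has support (<= 2 passes
    # needed for a Bayer lattice)
    num <- v; den <- w
    for (k in list(kPlus, kDiag)) {
      num <- num + .convolve2(v, k)
      den <- den + .convolve2(w, k)
    }
    out <- num / pmax(den, 1e-12)
    out[mask] <- m[mask]
    out
  }
  px <- array(0, c(H, W, 3L))
  px[, , 1] <- interp(maskR)
  px[, , 2] <- interp(maskG)
  px[, , 3] <- interp(maskB)
  .clamp(px, 0, 1)
}

#' Downscale a scene by block averaging
#'
#' `factor` counts total pixels by default (`mode = "total"`), so the
#' customary factor 16 means 4 x 4 block means; `mode = "linear"` treats it
#' as the block side instead. Trailing rows/columns that do not fill a
#' block are dropped.
#'
#' @param img a [SceneImage-class].
#' @param factor positive integer downscale factor.
#' @param mode `"total"` (pixel-count factor, must be a perfect square) or
#'   `"linear"` (block side).
#' @return A downscaled [SceneImage-class]; `scaleFactor` is multiplied by
#'   the linear block side.
#' @export
downscaleScene <- function(img, factor = 16L, mode = c("total", "linear")) {
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (factor < 1L) .stopf("downscale factor must be >= 1")
  side <- if (mode == "total") {
    s <- as.integer(round(sqrt(factor)))
    if (s * s != factor)
      .stopf("total downscale factor %d is not a perfect square", factor)
    s
  } else factor
  if (side == 1L) return(img)
  px <- img@pixels
  H2 <- nrow(px) %/% side; W2 <- ncol(px) %/% side
  if (H2 < 1L || W2 < 1L) .stopf("image smaller than one %dx%d block", side, side)
  out <- array(0, c(H2, W2, 3L))
  for (ch in 1:3) {
    x <- px[seq_len(H2 * side), seq_len(W2 * side), ch]
    m1 <- colMeans(array(x, c(side, H2, W2 * side)))        # H2 x (W2*side)
    out[, , ch] <- t(colMeans(array(t(m1), c(side, W2, H2))))
  }
  SceneImage(out, scaleFactor = img@scaleFactor * side,
             sourceKind = img@sourceKind, id = img@id)
}

#' Segment the backlit light table
#'
#' Applies a non-linear intensity correction (gamma), selects bright
#' candidate pixels relative to the bright reference level (the 95th
#' percentile of the corrected intensity, so the rule is invariant to a
#' global intensity scale), clusters a seeded subsample of their
#' coordinates with density-based spatial clustering, and keeps the
#' connected components of the candidate mask that carry the largest
#' cluster (ties broken by higher mean intensity).
#'
#' @param img the downscaled [SceneImage-class].
#' @param gamma exponent of the intensity correction (default 0.5).
#' @param brightFrac candidate cut as a fraction of the bright reference
#'   level (default 0.9; must exceed the leaf/table contrast after gamma
#'   correction plus the unevenness of the illumination).
#' @param minBrightness absolute intensity floor for candidates.
#' @param minBackgroundFraction minimum scene fraction the table must cover.
#' @param subsampleSize maximum number of candidate pixels clustered.
#' @param seed RNG seed for the subsample.
#' @return A [BackgroundMask-class].
#' @export
segmentLightTable <- function(img, gamma = 0.5, brightFrac = 0.9,
                              minBrightness = 0.15,
                              minBackgroundFraction = 0.2,
                              subsampleSize = 50000L, seed = 1L) {
  inten <- .intensity(img@pixels)
  corr <- inten^gamma
  ref <- quantile(corr, 0.95, names = FALSE)
  cand <- corr >= brightFrac * ref & inten >= minBrightness
  if (!any(cand))
    .stopf("no light table found: no pixels brighter than %.2f", minBrightness)
  idx <- which(cand)
  sub <- if (length(idx) > subsampleSize)
    .withSeed(seed, sort(sample(idx, subsampleSize))) else idx
  H <- nrow(inten)
  pts <- cbind(.rowOf(sub, H), .colOf(sub, H))
  # eps scaled to the sampling density so a contiguous bright area stays one
  # cluster even after subsampling
  eps <- max(2, 2.5 * sqrt(length(idx) / length(sub)))
  cl <- .dbscan(pts, eps = eps, minPts = 5L)
  if (!any(cl > 0L)) .stopf("no light table found: bright pixels too sparse")
  sizes <- tabulate(cl)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {   # tie: higher mean intensity wins
    mi <- vapply(best, function(b) mean(inten[sub[cl == b]]), numeric(1))
    best <- best[which.max(mi)]
  }
  comps <- .label8(cand)
  keep <- unique(comps[sub[cl == best]])
  keep <- keep[keep > 0L]
  mask <- matrix(comps %in% keep, nrow(comps), ncol(comps))
  cov <- mean(mask)
  if (cov < minBackgroundFraction)
    .stopf("no light table found: bright area covers %.1f%% < %.1f%% of scene",
           100 * cov, 100 * minBackgroundFraction)
  new("BackgroundMask", mask = mask, coverageFraction = cov)
}

#' Locate and classify objects lying on the light table
#'
#' Connected non-background components fully enclosed by the scene (not
#' touching the image border) are ranked by area. The largest is the leaf;
#' among the rest, a compact region with near-square bounding box (aspect
#' ratio in \[0.8, 1.25\], bounding-box fill >= 0.9) is the size marker and
#' an elongated region (aspect ratio >= 2 either way) the barcode label.
#'
#' @param bg a [BackgroundMask-class] from the downscaled scene.
#' @param margin bounding-box expansion in px at the downscaled resolution.
#' @param scaleFactor linear scale of `bg` (propagated into the layout).
#' @return A [SceneLayout-class] with 0-based, half-open rectangles.
#' @export
detectSceneObjects <- function(bg, margin = 8L, scaleFactor = 1L) {
  holes <- !bg@mask
  comps <- .label8(holes)
  if (max(comps) > 0L) {
    H <- nrow(comps); W <- ncol(comps)
    border <- unique(c(comps[1, ], comps[H, ], comps[, 1], comps[, W]))
    comps[comps %in% border[border > 0L]] <- 0L
    comps <- .label8(comps > 0L)
  }
  if (max(comps) == 0L) .stopf("no leaf found: background contains no holes")
  bb <- .labelBBoxes(comps)
  bb <- bb[order(-bb$area), ]
  H <- nrow(comps); W <- ncol(comps)
  rect <- function(row) {
    r <- as.integer(c(max(row$r0 - 1L - margin, 0L),
                      min(row$r1 + margin, H),
                      max(row$c0 - 1L - margin, 0L),
                      min(row$c1 + margin, W)))
    r
  }
  leaf <- rect(bb[1, ])
  marker <- integer(0); barcode <- integer(0); other <- list()
  if (nrow(bb) > 1L) {
    for (i in 2:nrow(bb)) {
      row <- bb[i, ]
      bw <- row$c1 - row$c0 + 1L; bh <- row$r1 - row$r0 + 1L
      ar <- bw / bh
      fill <- row$area / (bw * bh)
      if (length(marker) == 0L && ar >= 0.8 && ar <= 1.25 && fill >= 0.9) {
        marker <- rect(row)
      } else if (length(barcode) == 0L && (ar >= 2 || ar <= 0.5)) {
        barcode <- rect(row)
      } else {
        other <- c(other, list(rect(row)))
      }
    }
  }
  new("SceneLayout", leafRegion = leaf, markerRegion = marker,
      barcodeRegion = barcode, otherRegions = other,
      scaleFactor = as.integer(scaleFactor))
}

# Rescale a 0-based half-open rectangle between linear scales and clip.
.rescaleRect <- function(r, ratio, H, W, snapEven = FALSE) {
  out <- as.integer(c(floor(r[1] * ratio), ceiling(r[2] * ratio),
                      floor(r[3] * ratio), ceiling(r[4] * ratio)))
  out <- c(max(out[1], 0L), min(out[2], H), max(out[3], 0L), min(out[4], W))
  if (snapEven) {  # preserve Bayer mosaic phase
    out[c(1, 3)] <- out[c(1, 3)] - out[c(1, 3)] %% 2L
    out[c(2, 4)] <- out[c(2, 4)] + out[c(2, 4)] %% 2L
    out <- c(out[1], min(out[2], H), out[3], min(out[4], W))
  }
  as.integer(out)
}

#' Crop the leaf region from the full-resolution scene
#'
#' Rescales the downscaled-layout leaf rectangle to the resolution of
#' `full`, clips it to the image, and crops. For `bayer_raw` sources the
#' bounds are snapped to even coordinates so the mosaic phase would be
#' preserved upstream of demosaicing.
#'
#' @param full the full-resolution [SceneImage-class].
#' @param layout a [SceneLayout-class] from [detectSceneObjects()].
#' @return The cropped [SceneImage-class] (leaf plus surrounding background).
#' @export
cropLeaf <- function(full, layout) {
  ratio <- layout@scaleFactor / full@scaleFactor
  H <- nrow(full@pixels); W <- ncol(full@pixels)
  r <- .rescaleRect(layout@leafRegion, ratio, H, W,
                    snapEven = identical(full@sourceKind, "bayer_raw"))
  if (r[2] <= r[1] || r[4] <= r[3])
    .stopf("leaf region maps outside the full-resolution scene")
  px <- full@pixels[(r[1] + 1L):r[2], (r[3] + 1L):r[4], , drop = FALSE]
  SceneImage(px, scaleFactor = full@scaleFactor, sourceKind = full@sourceKind,
             id = full@id)
}
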