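# Leaf segmentation: crude foreground, white-image reconstruction,
# white balancing, and the final Otsu-based leaf mask with true holes.

#' Crude foreground (leaf) mask by joint space-colour clustering
#'
#' Clusters a seeded subsample of pixels on joint (row, col, R, G, B)
#' features (coordinates scaled to `[0,1]`) with density-based spatial
#' clustering. The largest cluster is the light-table background, the
#' second largest the leaf. All pixels are then assigned to the nearest
#' cluster centroid in feature space and the foreground is morphologically
#' closed (3 x 3).
#'
#' @param leafImg the leaf crop as a [SceneImage-class].
#' @param eps DBSCAN neighbourhood radius in the scaled feature space.
#' @param minPts DBSCAN core-point threshold.
#' @param subsampleSize maximum number of pixels clustered.
#' @param seed RNG seed for the subsample.
#' @return H x W logical matrix, `TRUE` on the leaf.
#' @export
crudeForegroundMask <- function(leafImg, eps = 0.08, minPts = 8L,
                                subsampleSize = 4000L, seed = 1L) {
  px <- leafImg@pixels
  H <- nrow(px); W <- ncol(px)
  n <- H * W
  idx <- if (n > subsampleSize)
    .withSeed(seed, sort(sample(n, subsampleSize))) else seq_len(n)
  r <- .rowOf(idx, H); c <- .colOf(idx, H)
  feats <- cbind((r - 1) / max(H - 1, 1), (c - 1) / max(W - 1, 1),
                 px[, , 1][idx], px[, , 2][idx], px[, , 3][idx])
  cl <- .dbscan(feats, eps = eps, minPts = minPts)
  sizes <- tabulate(cl)
  if (length(sizes) < 2L)
    .stopf("leaf/background not separable: found %d cluster(s)", length(sizes))
  ord <- order(-sizes)
  bgId <- ord[1]; fgId <- ord[2]
  cent <- rbind(colMeans(feats[cl == bgId, , drop = FALSE]),
                colMeans(feats[cl == fgId, , drop = FALSE]))
  # assign every pixel to the nearer of the two centroids
  rr <- (.rowOf(seq_len(n), H) - 1) / max(H - 1, 1)
  cc <- (.colOf(seq_len(n), H) - 1) / max(W - 1, 1)
  all5 <- cbind(rr, cc, as.vector(px[, , 1]), as.vector(px[, , 2]),
                as.vector(px[, , 3]))
  d1 <- rowSums(sweep(all5, 2, cent[1, ])^2)
  d2 <- rowSums(sweep(all5, 2, cent[2, ])^2)
  mask <- matrix(d2 < d1, H, W)
  .close3(mask)
}

#' Reconstruct the background white image
#'
#' Background pixels are copied; pixels under the crude foreground are
#' infilled per channel by 1-D linear interpolation across the gap along
#' rows and along columns, averaged. Interpolated values therefore stay
#' within the range of the surrounding background samples and continue any
#' linear illumination gradient exactly.
#'
#' @param leafImg the leaf crop as a [SceneImage-class].
#' @param crudeFg logical foreground mask from [crudeForegroundMask()].
#' @param floor minimum admissible white value (default 1e-3).
#' @return A [WhiteImage-class].
#' @export
reconstructWhite <- function(leafImg, crudeFg, floor = 1e-3) {
  px <- leafImg@pixels
  H <- nrow(px); W <- ncol(px)
  bg <- !crudeFg
  if (mean(bg) < 0.05)
    .stopf("insufficient background: only %.1f%% of the crop", 100 * mean(bg))
  if (all(bg)) return(new("WhiteImage", pixels = pmax(px, floor)))
  out <- px
  fgIdx <- which(crudeFg)
  fallback <- vapply(1:3, function(ch) mean(px[, , ch][bg]), numeric(1))
  interpLine <- function(vals, known) {
    if (sum(known) == 0L) return(rep(NA_real_, length(vals)))
    if (sum(known) == 1L) return(rep(vals[known], length(vals)))
    approx(x = which(known), y = vals[known], xout = seq_along(vals),
           rule = 2)$y
  }
  for (ch in 1:3) {
    v <- px[, , ch]
    byRow <- t(vapply(seq_len(H), function(i) interpLine(v[i, ], bg[i, ]),
                      numeric(W)))
    byCol <- vapply(seq_len(W), function(j) interpLine(v[, j], bg[, j]),
                    numeric(H))
    comb <- ifelse(is.na(byRow), byCol,
                   ifelse(is.na(byCol), byRow, (byRow + byCol) / 2))
    comb[is.na(comb)] <- fallback[ch]
    plane <- v
    plane[fgIdx] <- comb[fgIdx]
    out[, , ch] <- pmax(plane, floor)
  }
  new("WhiteImage", pixels = out)
}

#' White-balance the leaf crop
#'
#' Divides the scene by the reconstructed white image per pixel and
#' channel. Ratios above 1 (specular noise) are clipped to 1 and values
#' are floored at `epsilon` so the log-absorbance transform stays finite.
#'
#' @param leafImg the leaf crop as a [SceneImage-class].
#' @param white a [WhiteImage-class] of the same size.
#' @param epsilon lower clip bound (default 1e-4).
#' @return A [NormImage-class] with background approximately 1.
#' @export
whiteBalance <- function(leafImg, white, epsilon = 1e-4) {
  if (!identical(dim(leafImg@pixels), dim(white@pixels)))
    .stopf("scene and white image shapes differ")
  ratio <- .clamp(leafImg@pixels / white@pixels, epsilon, 1)
  new("NormImage", pixels = ratio)
}

#' Compute the leaf mask with true holes
#'
#' Otsu-thresholds the grayscale (unweighted channel mean) of the
#' white-balanced image; the largest dark 8-connected component is the
#' leaf, and bright regions fully enclosed by it are recorded as real
#' holes. The leaf area excludes holes.
#'
#' @param norm a [NormImage-class].
#' @param minLeafFraction minimum image fraction the leaf must cover.
#' @param minContrast minimum grayscale separation between the dark and
#'   bright Otsu classes; below it the leaf is deemed not separable from
#'   the background (very thin, bright leaves).
#' @return A [LeafMask-class].
#' @export
computeLeafMask <- function(norm, minLeafFraction = 0.005, minContrast = 0.1) {
  gray <- .intensity(norm@pixels)
  thr <- tryCatch(EBImage::otsu(EBImage::Image(gray), range = c(0, 1)),
                  error = function(e) NA_real_)
  if (is.na(thr)) .stopf("leaf mask failed: degenerate grayscale histogram")
  dark <- gray < thr
  if (!any(dark) || mean(dark) < minLeafFraction)
    .stopf("leaf mask failed: dark area covers %.2f%% of crop", 100 * mean(dark))
  contrast <- mean(gray[!dark]) - mean(gray[dark])
  if (!is.finite(contrast) || contrast < minContrast)
    .stopf(paste0("leaf mask failed: leaf/background contrast %.3f below %.3f",
                  " (leaf mistaken for background?)"), contrast, minContrast)
  comps <- .label8(dark)
  areas <- tabulate(comps)
  leaf <- comps == which.max(areas)
  filled <- .fillHoles(leaf)
  holes <- filled & !leaf
  new("LeafMask", leaf = leaf, holes = holes,
      leafAreaPx = as.integer(sum(leaf)), holeAreaPx = as.integer(sum(holes)))
}
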