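# Lesion segmentation: absorbance/stain transform and multiscale
# zero-sum center-surround detection with per-segment refinement.

#' Compute the stain map (blueness x darkness)
#'
#' Per pixel the absorbance vector is `a = -log(max(norm, eps))` per
#' channel. Its Euclidean norm is the `amplitude` (darkness); the angle of
#' the vector away from the blue absorbance axis,
#' `theta = acos(a_B / amplitude)`, is the blueness: pixels that absorb
#' red/green but transmit blue (i.e. look blue) score high, achromatic
#' pixels score `acos(1/sqrt(3))`, and white pixels 0. The stain score is
#' `theta * amplitude`, zeroed outside the leaf.
#'
#' @param norm a [NormImage-class].
#' @param mask a [LeafMask-class] of the same size.
#' @param eps log-transform floor in (0, 0.01\].
#' @return A [StainMap-class].
#' @export
computeStainMap <- function(norm, mask, eps = 1e-4) {
  if (eps <= 0 || eps > 0.01) .stopf("eps must lie in (0, 0.01]")
  px <- norm@pixels
  if (!identical(dim(px)[1:2], dim(mask@leaf)))
    .stopf("norm image and leaf mask shapes differ")
  if (min(px) <= 0) .stopf("normalised image contains non-positive values")
  a <- -log(pmax(px, eps))
  H <- dim(px)[1]; W <- dim(px)[2]
  amp <- matrix(sqrt(a[, , 1]^2 + a[, , 2]^2 + a[, , 3]^2), H, W)
  theta <- matrix(0, H, W)
  pos <- amp > 0
  aB <- matrix(a[, , 3], H, W)
  theta[pos] <- acos(.clamp(aB[pos] / amp[pos], -1, 1))
  stain <- theta * amp
  stain[!mask@leaf] <- 0
  new("StainMap", theta = theta, amplitude = amp, stain = stain,
      leaf = mask@leaf)
}

#' Build a zero-sum center-surround kernel
#'
#' The inner element (disc of the given radius, or a
#' `(2 radius + 1)`-sided square) carries weight `+1/N_in`; the surrounding
#' annulus out to `surroundFactor * radius` carries `-1/N_out`, so the
#' kernel sums to zero and responds only to local contrast.
#'
#' @param radius inner radius in pixels (>= 1).
#' @param shape `"disc"` (default) or `"square"`.
#' @param surroundFactor outer radius as a multiple of `radius`.
#' @return A [KernelSpec-class].
#' @export
makeCenterSurroundKernel <- function(radius, shape = c("disc", "square"),
                                     surroundFactor = 2) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 1L) .stopf("kernel radius must be >= 1")
  rOut <- as.integer(ceiling(surroundFactor * radius))
  if (rOut <= radius) .stopf("empty surround annulus: outer radius %d <= %d",
                             rOut, radius)
  d <- 2L * rOut + 1L
  dx <- matrix(rep(-rOut:rOut, d), d, d)
  dy <- t(dx)
  if (shape == "disc") {
    dist <- sqrt(dx^2 + dy^2)
    inner <- dist <= radius + 1e-9
    annulus <- !inner & dist <= rOut + 1e-9
  } else {
    cheb <- pmax(abs(dx), abs(dy))
    inner <- cheb <= radius
    annulus <- !inner & cheb <= rOut
  }
  w <- matrix(0, d, d)
  w[inner] <- 1 / sum(inner)
  w[annulus] <- -1 / sum(annulus)
  new("KernelSpec", radius = radius, shape = shape,
      surroundRadius = rOut, weights = w)
}

#' Multiscale lesion detection on the stain map
#'
#' Convolves the stain image with a zero-sum center-surround kernel at
#' each radius (reflective boundary), thresholds each response at
#' `responseFrac` of its own maximum (keeping `>=`), dilates once with a
#' 3 x 3 square, fills enclosed holes, and labels 8-connected segments.
#'
#' @param stain a [StainMap-class].
#' @param radii integer vector of kernel radii (default `1:13`).
#' @param responseFrac relative response threshold (default 0.1).
#' @param shape kernel shape, `"disc"` or `"square"`.
#' @param surroundFactor outer radius multiple (default 2).
#' @return A list with one labelled integer matrix per radius, in order;
#'   an all-zero stain map yields all-empty label images.
#' @export
multiscaleDetect <- function(stain, radii = 1:13, responseFrac = 0.1,
                             shape = c("disc", "square"), surroundFactor = 2) {
  shape <- match.arg(shape)
  if (length(radii) == 0L) .stopf("radii must be non-empty")
  st <- stain@stain
  if (!all(is.finite(st))) .stopf("stain map contains non-finite values")
  lapply(radii, function(r) {
    k <- makeCenterSurroundKernel(r, shape = shape,
                                  surroundFactor = surroundFactor)
    resp <- .convolve2(st, k@weights)
    mx <- max(resp)
    if (mx <= 0) return(matrix(0L, nrow(st), ncol(st)))
    bin <- resp >= responseFrac * mx
    bin <- .dilate3(bin)
    bin <- .fillHoles(bin)
    .label8(bin)
  })
}

#' Refine per-scale segments and combine across scales
#'
#' Within each labelled segment, keeps the pixels whose stain value is at
#' least `min + refineFrac * (max - min)` of the stain range over that
#' segment (a degenerate range keeps the whole segment). The refined
#' binaries of all scales are OR-ed, restricted to the leaf, relabelled
#' 8-connected, and empty segments dropped.
#'
#' @param perScale list of label matrices from [multiscaleDetect()].
#' @param stain the same [StainMap-class] the detections came from.
#' @param refineFrac within-segment range fraction (default 0.6).
#' @return A [LesionLabelMap-class].
#' @export
refineAndCombine <- function(perScale, stain, refineFrac = 0.6) {
  st <- stain@stain
  acc <- matrix(FALSE, nrow(st), ncol(st))
  for (lab in perScale) {
    if (max(lab) == 0L) next
    idx <- which(lab > 0L)
    segs <- split(idx, lab[idx])
    for (px in segs) {
      s <- st[px]
      lev <- min(s) + refineFrac * (max(s) - min(s))
      acc[px[s >= lev]] <- TRUE
    }
  }
  acc <- acc & stain@leaf
  labels <- .label8(acc)
  new("LesionLabelMap", labels = labels, nLesions = max(labels))
}
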