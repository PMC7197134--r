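#' @import methods
#' @importFrom stats approx rnorm runif sd quantile setNames
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom tools file_path_sans_ext
NULL

.checkPixels <- function(px, what = "pixels", tol = 1e-8) {
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L)
    return(sprintf("%s must be an H x W x 3 array", what))
  if (anyNA(px)) return(sprintf("%s contains NA", what))
  rng <- range(px)
  if (rng[1] < -tol || rng[2] > 1 + tol)
    return(sprintf("%s values outside [0,1] (range %.4g..%.4g)", what, rng[1], rng[2]))
  NULL
}

#' SceneImage: a linear RGB raster of the light-table scene
#'
#' Pixel values are linear transmission in `[0,1]`, stored as an
#' `H x W x 3` array in row/column (top-left origin) order.
#' `scaleFactor` is the linear downscaling factor relative to the original
#' capture (1 = full resolution).
#'
#' @slot pixels H x W x 3 numeric array in \[0,1\].
#' @slot scaleFactor positive integer, linear downscale factor.
#' @slot sourceKind `"rgb_file"`, `"bayer_raw"` or `"synthetic"`.
#' @slot id free-text identifier (usually the file path or scene id).
#' @exportClass SceneImage
setClass("SceneImage",
  representation(pixels = "array", scaleFactor = "integer",
                 sourceKind = "character", id = "character"),
  validity = function(object) {
    msg <- .checkPixels(object@pixels)
    if (!is.null(msg)) return(msg)
    if (length(object@scaleFactor) != 1L || object@scaleFactor < 1L)
      return("scaleFactor must be a single integer >= 1")
    TRUE
  })

#' Construct a SceneImage
#'
#' @param pixels H x W x 3 numeric array in \[0,1\].
#' @param scaleFactor linear downscale factor (1 = full resolution).
#' @param sourceKind provenance tag.
#' @param id scene identifier.
#' @return A [SceneImage-class] object.
#' @export
SceneImage <- function(pixels, scaleFactor = 1L, sourceKind = "synthetic",
                       id = "scene") {
  new("SceneImage", pixels = pixels, scaleFactor = as.integer(scaleFactor),
      sourceKind = sourceKind, id = id)
}

#' BackgroundMask: pixels belonging to the backlit light table
#'
#' @slot mask H x W logical matrix, `TRUE` on the light table.
#' @slot coverageFraction fraction of scene pixels covered by the table.
#' @exportClass BackgroundMask
setClass("BackgroundMask",
  representation(mask = "matrix", coverageFraction = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (abs(object@coverageFraction - mean(object@mask)) > 1e-9)
      return("coverageFraction must equal mean(mask)")
    TRUE
  })

#' SceneLayout: classified rectangular regions of the scene
#'
#' Rectangles are 0-based, half-open `c(row0, row1, col0, col1)` integer
#' vectors expressed at the resolution given by `scaleFactor` (the
#' downscaled pass they were detected in).
#'
#' @slot leafRegion rectangle of the leaf (largest background hole).
#' @slot markerRegion rectangle of the square size marker, or `integer(0)`.
#' @slot barcodeRegion rectangle of the barcode label, or `integer(0)`.
#' @slot otherRegions list of unclassified hole rectangles.
#' @slot scaleFactor linear scale the rectangles are expressed at.
#' @exportClass SceneLayout
setClass("SceneLayout",
  representation(leafRegion = "integer", markerRegion = "integer",
                 barcodeRegion = "integer", otherRegions = "list",
                 scaleFactor = "integer"),
  validity = function(object) {
    ok <- function(r) length(r) == 0L ||
      (length(r) == 4L && r[2] > r[1] && r[4] > r[3] && all(r >= 0L))
    if (length(object@leafRegion) != 4L || !ok(object@leafRegion))
      return("leafRegion must be a valid c(row0,row1,col0,col1) rectangle")
    if (!ok(object@markerRegion)) return("invalid markerRegion")
    if (!ok(object@barcodeRegion)) return("invalid barcodeRegion")
    TRUE
  })

#' WhiteImage: reconstructed background illumination field
#'
#' @slot pixels H x W x 3 strictly positive numeric array.
#' @exportClass WhiteImage
setClass("WhiteImage",
  representation(pixels = "array"),
  validity = function(object) {
    if (!is.array(object@pixels) || length(dim(object@pixels)) != 3L)
      return("pixels must be H x W x 3")
    if (min(object@pixels) <= 0) return("white image must be strictly positive")
    TRUE
  })

#' NormImage: white-balanced transmission image
#'
#' Per-pixel ratio of the scene to the reconstructed white image, clipped
#' to `(epsilon, 1]` so the downstream log-absorbance transform is finite.
#'
#' @slot pixels H x W x 3 numeric array in (0,1\].
#' @exportClass NormImage
setClass("NormImage",
  representation(pixels = "array"),
  validity = function(object) {
    if (!is.array(object@pixels) || length(dim(object@pixels)) != 3L)
      return("pixels must be H x W x 3")
    rng <- range(object@pixels)
    if (rng[1] <= 0 || rng[2] > 1 + 1e-9)
      return("normalised values must lie in (0,1]")
    TRUE
  })

#' LeafMask: leaf foreground with true holes
#'
#' @slot leaf H x W logical, `TRUE` on leaf tissue (holes excluded).
#' @slot holes H x W logical, `TRUE` on real holes enclosed by the leaf.
#' @slot leafAreaPx integer, `sum(leaf)`.
#' @slot holeAreaPx integer, `sum(holes)`.
#' @exportClass LeafMask
setClass("LeafMask",
  representation(leaf = "matrix", holes = "matrix",
                 leafAreaPx = "integer", holeAreaPx = "integer"),
  validity = function(object) {
    if (any(object@leaf & object@holes)) return("leaf and holes must be disjoint")
    if (object@leafAreaPx != sum(object@leaf)) return("leafAreaPx != sum(leaf)")
    if (object@holeAreaPx != sum(object@holes)) return("holeAreaPx != sum(holes)")
    TRUE
  })

#' StainMap: per-pixel blueness, darkness and stain score
#'
#' The absorbance vector `a = -log(norm)` is expressed in spherical form:
#' `amplitude` is its Euclidean norm (overall darkness) and `theta` the
#' angle away from the blue absorbance axis (`acos(a_B / amplitude)`), so
#' blue-looking pixels (absorbing red/green, transmitting blue) score high.
#' `stain = theta * amplitude`, zeroed outside the leaf.
#'
#' @slot theta H x W blueness angle in radians, in \[0, pi/2\].
#' @slot amplitude H x W nonnegative absorbance magnitude.
#' @slot stain H x W stain score, zero outside the leaf.
#' @slot leaf H x W logical leaf mask the map is valid on.
#' @exportClass StainMap
setClass("StainMap",
  representation(theta = "matrix", amplitude = "matrix",
                 stain = "matrix", leaf = "matrix"),
  validity = function(object) {
    if (min(object@theta) < -1e-9 || max(object@theta) > pi / 2 + 1e-9)
      return("theta must lie in [0, pi/2]")
    if (min(object@amplitude) < -1e-9) return("amplitude must be nonnegative")
    if (any(object@stain[!object@leaf] != 0))
      return("stain must be zero outside the leaf")
    TRUE
  })

#' KernelSpec: zero-sum center-surround convolution kernel
#'
#' @slot radius inner element radius in pixels.
#' @slot shape `"disc"` or `"square"`.
#' @slot surroundRadius outer radius of the negative annulus.
#' @slot weights square weight matrix summing to zero.
#' @exportClass KernelSpec
setClass("KernelSpec",
  representation(radius = "integer", shape = "character",
                 surroundRadius = "integer", weights = "matrix"),
  validity = function(object) {
    if (abs(sum(object@weights)) > 1e-9) return("kernel weights must sum to 0")
    if (object@surroundRadius <= object@radius)
      return("surroundRadius must exceed radius")
    TRUE
  })

#' LesionLabelMap: labelled lesion segments
#'
#' @slot labels H x W integer matrix, 0 = no lesion, 1..nLesions otherwise.
#' @slot nLesions number of labelled lesions.
#' @exportClass LesionLabelMap
setClass("LesionLabelMap",
  representation(labels = "matrix", nLesions = "integer"),
  validity = function(object) {
    if (max(object@labels) > object@nLesions) return("labels exceed nLesions")
    if (min(object@labels) < 0L) return("labels must be nonnegative")
    TRUE
  })

#' Calibration: pixel-to-area conversion
#'
#' A 1-cm^2 reference marker of `A` pixels gives `1e8 / A` square microns
#' per pixel; without a marker a configured value is used.
#'
#' @slot um2PerPx square microns per pixel.
#' @slot source `"marker"` or `"config"`.
#' @exportClass Calibration
setClass("Calibration",
  representation(um2PerPx = "numeric", source = "character"),
  validity = function(object) {
    if (object@um2PerPx <= 0) return("um2PerPx must be positive")
    TRUE
  })

#' LesionTable: per-lesion morphometrics for one leaf image
#'
#' `records` has one row per lesion with columns documented in
#' [measureLesions()]. `damagePercent` is
#' `100 * sum(area_px over kept lesions) / leafAreaPx`.
#'
#' @slot imageId scene identifier.
#' @slot records data.frame of per-lesion measurements.
#' @slot leafAreaPx leaf area in pixels (holes excluded).
#' @slot damagePercent leaf-scale damage over kept lesions.
#' @slot labels the [LesionLabelMap-class] the records were measured on.
#' @exportClass LesionTable
setClass("LesionTable",
  representation(imageId = "character", records = "data.frame",
                 leafAreaPx = "integer", damagePercent = "numeric",
                 labels = "LesionLabelMap"),
  validity = function(object) {
    if (object@leafAreaPx <= 0L) return("leafAreaPx must be positive")
    if (nrow(object@records)) {
      dp <- 100 * sum(object@records$area_px[object@records$kept]) /
        object@leafAreaPx
      if (abs(dp - object@damagePercent) > 1e-6)
        return("damagePercent inconsistent with kept lesion areas")
    } else if (object@damagePercent != 0) {
      return("damagePercent must be 0 for an empty table")
    }
    TRUE
  })

#' FeatureMatrix: standardized lesion descriptors for clustering
#'
#' Columns, in fixed order: `area_px`, `theta_max`, `theta_range`,
#' `amp_max`, `amp_range`, `eccentricity`, `log_sqrt_area`;
#' z-standardized per column with the centering/scaling retained.
#'
#' @slot features n x 7 numeric matrix.
#' @slot center per-column means of the raw features.
#' @slot scale per-column standard deviations (floored at 1e-9).
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(features = "matrix", center = "numeric", scale = "numeric"),
  validity = function(object) {
    if (ncol(object@features) != 7L) return("exactly 7 feature columns required")
    if (anyNA(object@features)) return("features contain NA")
    TRUE
  })

#' ClusterAssignment: lesion cluster labels from mini-batch k-means
#'
#' @slot k number of clusters actually used (`min(k, n)`).
#' @slot labels 1-based cluster label per lesion.
#' @slot seed RNG seed the assignment was computed under.
#' @slot inertia total within-cluster sum of squared distances.
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(k = "integer", labels = "integer", seed = "integer",
                 inertia = "numeric"),
  validity = function(object) {
    if (length(object@labels) &&
        (min(object@labels) < 1L || max(object@labels) > object@k))
      return("labels must lie in 1..k")
    TRUE
  })

#' GroundTruth: synthetic-scene truth masks and parameters
#'
#' @slot leafMask H x W logical leaf tissue mask (holes excluded).
#' @slot lesionLabels H x W integer matrix labelling each true lesion.
#' @slot lesionAreas integer vector of true per-lesion areas (px).
#' @slot lesionClasses character vector micro/meso/macro.
#' @slot confounderMask H x W logical mask of achromatic-dark patches.
#' @slot holeMask H x W logical mask of real holes in the leaf.
#' @slot markerRegion marker rectangle (0-based half-open) or `integer(0)`.
#' @slot damagePercentTrue 100 * lesion area / leaf area.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(leafMask = "matrix", lesionLabels = "matrix",
                 lesionAreas = "integer", lesionClasses = "character",
                 confounderMask = "matrix", holeMask = "matrix",
                 markerRegion = "integer", damagePercentTrue = "numeric"),
  validity = function(object) {
    la <- sum(object@leafMask)
    if (la > 0) {
      dp <- 100 * sum(object@lesionAreas) / la
      if (abs(dp - object@damagePercentTrue) > 1e-6)
        return("damagePercentTrue inconsistent with masks")
    }
    if (max(object@lesionLabels) != length(object@lesionAreas))
      return("lesionLabels inconsistent with lesionAreas")
    TRUE
  })

#' SyntheticSpec: parameters of a synthetic light-table scene
#'
#' See [syntheticSpec()] for field semantics and defaults.
#'
#' @slot width,height scene size in pixels.
#' @slot backgroundBase per-channel light-table transmission (near white).
#' @slot backgroundGradient relative amplitude of the smooth uneven-light field.
#' @slot leafCenter fractional (row, col) leaf center.
#' @slot leafRadii (row, col) leaf semi-axes in pixels.
#' @slot leafColor per-channel leaf transmission (cream/yellow).
#' @slot midribFactor transmission multiplier along the midrib band.
#' @slot nLesions number of disc lesions to place.
#' @slot lesionRadiusRange min/max lesion radius in px (0 = single pixel).
#' @slot lesionCoreFactor,lesionRimFactor R/G transmission multipliers of
#'   lesion core and rim.
#' @slot nCuts number of elongated cut lesions (capsules).
#' @slot cutLength,cutHalfWidth geometry of cut lesions in px.
#' @slot nConfounders number of achromatic-dark patches (uneven clearing).
#' @slot confounderFactor all-channel transmission multiplier of confounders.
#' @slot confounderRadiusRange min/max confounder radius in px.
#' @slot nHoles number of real holes punched in the leaf.
#' @slot holeRadiusRange min/max hole radius in px.
#' @slot marker logical, include the 1-cm^2 size marker.
#' @slot markerSide marker side length in px.
#' @slot barcode logical, include a barcode label region.
#' @slot noiseSd Gaussian pixel noise standard deviation.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(width = "integer", height = "integer",
                 backgroundBase = "numeric", backgroundGradient = "numeric",
                 leafCenter = "numeric", leafRadii = "numeric",
                 leafColor = "numeric", midribFactor = "numeric",
                 nLesions = "integer", lesionRadiusRange = "numeric",
                 lesionCoreFactor = "numeric", lesionRimFactor = "numeric",
                 nCuts = "integer", cutLength = "numeric",
                 cutHalfWidth = "numeric",
                 nConfounders = "integer", confounderFactor = "numeric",
                 confounderRadiusRange = "numeric",
                 nHoles = "integer", holeRadiusRange = "numeric",
                 marker = "logical", markerSide = "integer",
                 barcode = "logical", noiseSd = "numeric"),
  validity = function(object) {
    if (object@width < 64L || object@height < 64L)
      return("scene must be at least 64 x 64")
    if (any(object@lesionRadiusRange < 0)) return("lesion radii must be >= 0")
    if (any(object@leafColor <= 0 | object@leafColor > 1))
      return("leafColor must lie in (0,1]")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })
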