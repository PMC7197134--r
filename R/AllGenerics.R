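#' Accessors for LesionQuant classes
#'
#' `pixels()` returns the raw pixel array of an image-like object;
#' `scaleFactor()` its linear downscale factor; `leafArea()` and
#' `holeArea()` the pixel areas of a [LeafMask-class]; `nLesions()` the
#' number of labelled lesions; `lesionRecords()` the per-lesion
#' measurement data.frame (with an `image_id` column prepended);
#' `damagePercent()` the leaf-scale damage of a [LesionTable-class].
#'
#' @param x the object.
#' @return See the individual accessor descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "SceneImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "WhiteImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "NormImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("scaleFactor", function(x) standardGeneric("scaleFactor"))
#' @rdname accessors
#' @export
setMethod("scaleFactor", "SceneImage", function(x) x@scaleFactor)
#' @rdname accessors
#' @export
setMethod("scaleFactor", "SceneLayout", function(x) x@scaleFactor)

#' @rdname accessors
#' @export
setGeneric("leafArea", function(x) standardGeneric("leafArea"))
#' @rdname accessors
#' @export
setMethod("leafArea", "LeafMask", function(x) x@leafAreaPx)
#' @rdname accessors
#' @export
setMethod("leafArea", "LesionTable", function(x) x@leafAreaPx)

#' @rdname accessors
#' @export
setGeneric("holeArea", function(x) standardGeneric("holeArea"))
#' @rdname accessors
#' @export
setMethod("holeArea", "LeafMask", function(x) x@holeAreaPx)

#' @rdname accessors
#' @export
setGeneric("nLesions", function(x) standardGeneric("nLesions"))
#' @rdname accessors
#' @export
setMethod("nLesions", "LesionLabelMap", function(x) x@nLesions)
#' @rdname accessors
#' @export
setMethod("nLesions", "LesionTable", function(x) nrow(x@records))

#' @rdname accessors
#' @export
setGeneric("lesionRecords", function(x) standardGeneric("lesionRecords"))
#' @rdname accessors
#' @export
setMethod("lesionRecords", "LesionTable", function(x) {
  if (!nrow(x@records)) return(x@records)
  cbind(data.frame(image_id = x@imageId, stringsAsFactors = FALSE), x@records)
})

#' @rdname accessors
#' @export
setGeneric("damagePercent", function(x) standardGeneric("damagePercent"))
#' @rdname accessors
#' @export
setMethod("damagePercent", "LesionTable", function(x) x@damagePercent)
#' @rdname accessors
#' @export
setMethod("damagePercent", "GroundTruth", function(x) x@damagePercentTrue)

setMethod("show", "SceneImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SceneImage '%s': %d x %d px, scale %dx, source %s\n",
              object@id, d[1], d[2], object@scaleFactor, object@sourceKind))
})

setMethod("show", "SceneLayout", function(object) {
  fmt <- function(r) if (length(r)) sprintf("[%d,%d) x [%d,%d)", r[1], r[2], r[3], r[4]) else "absent"
  cat("SceneLayout (scale ", object@scaleFactor, "x)\n",
      "  leaf:    ", fmt(object@leafRegion), "\n",
      "  marker:  ", fmt(object@markerRegion), "\n",
      "  barcode: ", fmt(object@barcodeRegion), "\n",
      "  other:   ", length(object@otherRegions), " region(s)\n", sep = "")
})

setMethod("show", "LeafMask", function(object) {
  cat(sprintf("LeafMask: %d leaf px, %d hole px (%d x %d image)\n",
              object@leafAreaPx, object@holeAreaPx,
              nrow(object@leaf), ncol(object@leaf)))
})

setMethod("show", "StainMap", function(object) {
  cat(sprintf("StainMap: %d x %d, max stain %.3f on %d leaf px\n",
              nrow(object@stain), ncol(object@stain), max(object@stain),
              sum(object@leaf)))
})

setMethod("show", "LesionLabelMap", function(object) {
  cat(sprintf("LesionLabelMap: %d lesion(s) on %d x %d image\n",
              object@nLesions, nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "LesionTable", function(object) {
  kept <- if (nrow(object@records)) sum(object@records$kept) else 0L
  cat(sprintf(
    "LesionTable '%s': %d lesion(s) (%d kept), leaf %d px, damage %.3f%%\n",
    object@imageId, nrow(object@records), kept, object@leafAreaPx,
    object@damagePercent))
})

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %.2f um^2/px (%s)\n",
              object@um2PerPx, object@source))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d lesions in %d cluster(s), inertia %.3f\n",
              length(object@labels), object@k, object@inertia))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d lesion(s), leaf %d px, true damage %.3f%%\n",
    length(object@lesionAreas), sum(object@leafMask),
    object@damagePercentTrue))
})
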