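# Per-lesion and per-leaf quantification: physical calibration, region
# morphometrics, size classes and leaf-scale damage.

#' Pixel-to-area calibration
#'
#' With a 1-cm^2 size marker of `markerAreaPx` pixels, one pixel covers
#' `1e8 / markerAreaPx` square microns. Without a marker the configured
#' fallback is used (default 1800 um^2/px, the scale of a typical
#' fixed-height light-table setup).
#'
#' @param markerAreaPx marker area in pixels, or `NULL` when absent.
#' @param fallbackUm2PerPx configured um^2/px used without a marker; set
#'   to `NULL` to require a marker.
#' @return A [Calibration-class].
#' @export
calibrate <- function(markerAreaPx = NULL, fallbackUm2PerPx = 1800) {
  if (!is.null(markerAreaPx)) {
    if (markerAreaPx <= 0) .stopf("marker area must be positive")
    return(new("Calibration", um2PerPx = 1e8 / markerAreaPx,
               source = "marker"))
  }
  if (is.null(fallbackUm2PerPx))
    .stopf("no size marker and no configured um^2/px value")
  new("Calibration", um2PerPx = fallbackUm2PerPx, source = "config")
}

#' Classify lesions by area
#'
#' Single-pixel lesions are `micro` (the smallest detectable area),
#' lesions of 2-200 px `meso`, and larger ones `macro`.
#'
#' @param areaPx integer vector of lesion areas in pixels (>= 1).
#' @return Character vector of classes.
#' @export
classifyLesion <- function(areaPx) {
  if (any(areaPx < 1)) .stopf("lesion area must be >= 1 px")
  ifelse(areaPx == 1, "micro", ifelse(areaPx <= 200, "meso", "macro"))
}

# Boundary length as the number of exposed pixel edges (4-neighbour
# label mismatches, image border counts as exposed).
.labelPerimeters <- function(lab) {
  n <- max(lab)
  H <- nrow(lab); W <- ncol(lab)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- lab
  per <- numeric(n)
  for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- pad[2:(H + 1L) + sh[1], 2:(W + 1L) + sh[2]]
    mism <- lab > 0L & nb != lab
    per <- per + tabulate(lab[mism], n)
  }
  per
}

# Eccentricity from second central moments of the pixel coordinates;
# a single pixel (zero spread) has eccentricity 0.
.momentEccentricity <- function(r, c) {
  if (length(r) < 2L) return(0)
  mu20 <- mean(r^2) - mean(r)^2
  mu02 <- mean(c^2) - mean(c)^2
  mu11 <- mean(r * c) - mean(r) * mean(c)
  tr <- mu20 + mu02
  det <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (tr + det) / 2; l2 <- (tr - det) / 2
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

# Principal (major) axis of the leaf mask: centroid and unit direction.
.leafPrincipalAxis <- function(leaf) {
  idx <- which(leaf)
  H <- nrow(leaf)
  r <- .rowOf(idx, H); c <- .colOf(idx, H)
  c0 <- c(mean(r), mean(c))
  mu20 <- mean(r^2) - c0[1]^2
  mu02 <- mean(c^2) - c0[2]^2
  mu11 <- mean(r * c) - c0[1] * c0[2]
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2), symmetric = TRUE)
  list(centroid = c0, dir = ev$vectors[, 1])
}

#' Measure per-lesion morphometrics
#'
#' Produces one record per labelled lesion with: pixel and physical area;
#' min/max/range of blueness (theta) and darkness (amplitude) over the
#' lesion; centroid; moments-based eccentricity (a 1-px lesion scores 0);
#' boundary perimeter (exposed pixel edges); circularity `4*pi*A/P^2`
#' capped at 1; bounding box; equivalent diameter `sqrt(4A/pi)`; distance
#' from the centroid to the nearest non-leaf pixel (Euclidean distance
#' transform of the leaf mask) and to the leaf centreline (principal axis
#' through the leaf-mask centroid); `log10(sqrt(area) + 0.1)`; and the
#' size class from [classifyLesion()].
#'
#' @param labels a [LesionLabelMap-class].
#' @param stain the [StainMap-class] of the same scene.
#' @param mask the [LeafMask-class] of the same scene.
#' @param cal a [Calibration-class].
#' @param imageId scene identifier stored in the table.
#' @return A [LesionTable-class].
#' @export
measureLesions <- function(labels, stain, mask, cal, imageId = "image") {
  lab <- labels@labels
  n <- labels@nLesions
  cols <- c("label", "area_px", "area_um2", "theta_max", "theta_min",
            "theta_range", "amp_max", "amp_min", "amp_range", "eccentricity",
            "perimeter_px", "circularity", "centroid_row", "centroid_col",
            "dist_edge_px", "dist_centreline_px", "bbox_h", "bbox_w",
            "equiv_diameter_px", "log_sqrt_area", "class", "cluster_id",
            "kept")
  if (n == 0L) {
    rec <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(rec) <- cols
    return(new("LesionTable", imageId = imageId, records = rec,
               leafAreaPx = mask@leafAreaPx, damagePercent = 0,
               labels = labels))
  }
  H <- nrow(lab)
  idx <- which(lab > 0L)
  lb <- lab[idx]
  area <- tabulate(lb, n)
  if (any(area == 0L)) .stopf("internal error: label with zero pixels")
  rows <- .rowOf(idx, H); colsIdx <- .colOf(idx, H)
  th <- stain@theta[idx]; am <- stain@amplitude[idx]
  f <- factor(lb, levels = seq_len(n))
  agg <- function(v, fun) as.vector(tapply(v, f, fun))
  thetaMax <- agg(th, max); thetaMin <- agg(th, min)
  ampMax <- agg(am, max); ampMin <- agg(am, min)
  cr <- agg(rows, mean); cc <- agg(colsIdx, mean)
  r0 <- agg(rows, min); r1 <- agg(rows, max)
  c0 <- agg(colsIdx, min); c1 <- agg(colsIdx, max)
  splitIdx <- split(seq_along(idx), lb)
  ecc <- vapply(splitIdx, function(s)
    .momentEccentricity(rows[s], colsIdx[s]), numeric(1))
  per <- .labelPerimeters(lab)
  dm <- EBImage::distmap(matrix(as.numeric(mask@leaf), H, ncol(lab)))
  dEdge <- dm[cbind(.clamp(round(cr), 1, H),
                    .clamp(round(cc), 1, ncol(lab)))]
  ax <- .leafPrincipalAxis(mask@leaf)
  nrm <- c(-ax$dir[2], ax$dir[1])
  dCentre <- abs((cr - ax$centroid[1]) * nrm[1] + (cc - ax$centroid[2]) * nrm[2])
  rec <- data.frame(
    label = seq_len(n),
    area_px = as.integer(area),
    area_um2 = area * cal@um2PerPx,
    theta_max = thetaMax, theta_min = thetaMin,
    theta_range = thetaMax - thetaMin,
    amp_max = ampMax, amp_min = ampMin, amp_range = ampMax - ampMin,
    eccentricity = as.vector(ecc),
    perimeter_px = per,
    circularity = pmin(1, 4 * pi * area / pmax(per, 1)^2),
    centroid_row = cr, centroid_col = cc,
    dist_edge_px = as.vector(dEdge),
    dist_centreline_px = dCentre,
    bbox_h = as.integer(r1 - r0 + 1L), bbox_w = as.integer(c1 - c0 + 1L),
    equiv_diameter_px = sqrt(4 * area / pi),
    log_sqrt_area = log10(sqrt(area) + 0.1),
    class = classifyLesion(area),
    cluster_id = NA_integer_,
    kept = TRUE,
    stringsAsFactors = FALSE)
  new("LesionTable", imageId = imageId, records = rec,
      leafAreaPx = mask@leafAreaPx,
      damagePercent = 100 * sum(area) / mask@leafAreaPx,
      labels = labels)
}

#' Summarise leaf-scale damage
#'
#' @param table a [LesionTable-class].
#' @return A one-row data.frame with the damage percentage over kept
#'   lesions, per-class lesion counts and areas, and totals in px and um^2.
#' @export
damageSummary <- function(table) {
  if (table@leafAreaPx <= 0L) .stopf("leaf area must be positive")
  rec <- table@records
  kept <- rec[rec$kept, , drop = FALSE]
  cnt <- function(cl) sum(kept$class == cl)
  are <- function(cl) sum(kept$area_px[kept$class == cl])
  data.frame(
    image_id = table@imageId,
    leaf_area_px = table@leafAreaPx,
    n_lesions = nrow(kept),
    n_micro = cnt("micro"), n_meso = cnt("meso"), n_macro = cnt("macro"),
    area_micro_px = are("micro"), area_meso_px = are("meso"),
    area_macro_px = are("macro"),
    lesion_area_px = sum(kept$area_px),
    lesion_area_um2 = sum(kept$area_um2),
    damage_percent = 100 * sum(kept$area_px) / table@leafAreaPx,
    stringsAsFactors = FALSE)
}
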