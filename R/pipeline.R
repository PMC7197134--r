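# Batch orchestration: run configuration, the per-scene pipeline, lesion
# table round-trips, overlays and batch summaries.

#' Build a run configuration
#'
#' Collects every stage parameter with its standard default: downscale
#' factor 16 (total), gamma 0.5, disc radii 1-13, response threshold 0.1
#' of each scale's maximum, within-segment refinement at 60% of the stain
#' range, 30 post-filter clusters. All randomness in a run flows from the
#' single `seed`.
#'
#' @param inputs character vector of image paths, or a list of
#'   [SceneImage-class] objects (e.g. synthetic scenes).
#' @param outputDir directory for TSV/CSV/PNG outputs (`NULL` = no files).
#' @param downscaleFactor total pixel-count downscale factor.
#' @param gamma light-table intensity correction exponent.
#' @param radii center-surround kernel radii.
#' @param responseFrac relative response threshold.
#' @param refineFrac within-segment refinement fraction.
#' @param kernelShape `"disc"` or `"square"`.
#' @param k number of post-filter clusters (0 disables clustering).
#' @param dropClusters cluster ids to drop in post-filtering.
#' @param um2PerPx fallback calibration when no marker is found.
#' @param seed master RNG seed.
#' @param writeOverlay write a lesion-outline overlay PNG per image.
#' @param filenamePattern optional named-group regex applied to input
#'   file names to extract metadata columns (e.g. barcode-style
#'   `"(?<year>\\d{4})_(?<species>[a-z]+)"`).
#' @return A classed list of configuration values.
#' @export
runConfig <- function(inputs, outputDir = NULL, downscaleFactor = 16L,
                      gamma = 0.5, radii = 1:13, responseFrac = 0.1,
                      refineFrac = 0.6, kernelShape = "disc", k = 30L,
                      dropClusters = integer(0), um2PerPx = 1800,
                      seed = 1L, writeOverlay = TRUE,
                      filenamePattern = NULL) {
  stopifnot(responseFrac > 0, responseFrac <= 1, refineFrac > 0,
            refineFrac <= 1, all(diff(radii) > 0), all(radii >= 1))
  structure(list(inputs = inputs, outputDir = outputDir,
                 downscaleFactor = as.integer(downscaleFactor), gamma = gamma,
                 radii = as.integer(radii), responseFrac = responseFrac,
                 refineFrac = refineFrac, kernelShape = kernelShape,
                 k = as.integer(k), dropClusters = as.integer(dropClusters),
                 um2PerPx = um2PerPx, seed = as.integer(seed),
                 writeOverlay = writeOverlay,
                 filenamePattern = filenamePattern),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [runConfig()].
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}

# Marker area at full resolution: crop the marker rectangle and count
# pixels darker than the midpoint between marker and surrounding table.
.measureMarkerArea <- function(full, layout) {
  if (!length(layout@markerRegion)) return(NULL)
  ratio <- layout@scaleFactor / full@scaleFactor
  H <- nrow(full@pixels); W <- ncol(full@pixels)
  r <- .rescaleRect(layout@markerRegion, ratio, H, W)
  crop <- full@pixels[(r[1] + 1L):r[2], (r[3] + 1L):r[4], , drop = FALSE]
  inten <- .intensity(crop)
  thr <- (min(inten) + max(inten)) / 2
  as.integer(sum(inten < thr))
}

#' Process a single scene through the full pipeline
#'
#' Runs light-table segmentation on the downscaled scene, crops the leaf,
#' reconstructs the white image, white-balances, masks the leaf, computes
#' the stain map, detects and refines lesions at all scales, and measures
#' them. Calibration uses the size marker when one is found, else the
#' configured fallback.
#'
#' @param scene a [SceneImage-class] (full resolution).
#' @param cfg a `RunConfig` from [runConfig()].
#' @return A list: `table` ([LesionTable-class]), `norm`, `mask`,
#'   `stain`, `layout`, `cal`, and `cropRect` (the 0-based half-open
#'   full-resolution rectangle the leaf crop was taken from).
#' @export
processScene <- function(scene, cfg = runConfig(list())) {
  down <- downscaleScene(scene, cfg$downscaleFactor)
  bgm <- segmentLightTable(down, gamma = cfg$gamma, seed = cfg$seed)
  layout <- detectSceneObjects(bgm, scaleFactor = scaleFactor(down))
  cropRect <- .rescaleRect(layout@leafRegion,
                           layout@scaleFactor / scene@scaleFactor,
                           nrow(scene@pixels), ncol(scene@pixels),
                           snapEven = identical(scene@sourceKind, "bayer_raw"))
  crop <- cropLeaf(scene, layout)
  markerArea <- .measureMarkerArea(scene, layout)
  cal <- calibrate(markerArea, fallbackUm2PerPx = cfg$um2PerPx)
  fg <- crudeForegroundMask(crop, seed = cfg$seed)
  white <- reconstructWhite(crop, fg)
  norm <- whiteBalance(crop, white)
  mask <- computeLeafMask(norm)
  stain <- computeStainMap(norm, mask)
  perScale <- multiscaleDetect(stain, radii = cfg$radii,
                               responseFrac = cfg$responseFrac,
                               shape = cfg$kernelShape)
  labels <- refineAndCombine(perScale, stain, refineFrac = cfg$refineFrac)
  table <- measureLesions(labels, stain, mask, cal, imageId = scene@id)
  list(table = table, norm = norm, mask = mask, stain = stain,
       layout = layout, cal = cal, cropRect = cropRect)
}

.classColours <- c(micro = "#D81B60", meso = "#FB8C00", macro = "#E53935")

# Overlay PNG: white-balanced image with lesion outlines coloured by class.
.writeOverlay <- function(norm, table, path) {
  px <- .clamp(pixels(norm), 0, 1)
  lab <- table@labels@labels
  rec <- table@records
  if (nrow(rec)) {
    per <- lab > 0L & (
      rbind(lab[-1, ], 0L) != lab | rbind(0L, lab[-nrow(lab), ]) != lab |
      cbind(lab[, -1], 0L) != lab | cbind(0L, lab[, -ncol(lab)]) != lab)
    cls <- rec$class[match(lab[per], rec$label)]
    keepcol <- grDevices::col2rgb(.classColours[cls]) / 255
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[per] <- keepcol[ch, ]
      px[, , ch] <- plane
    }
  }
  EBImage::writeImage(EBImage::Image(aperm(px, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

.tableColumns <- function() c("image_id", "label", "area_px", "area_um2",
  "theta_max", "theta_min", "theta_range", "amp_max", "amp_min", "amp_range",
  "eccentricity", "perimeter_px", "circularity", "centroid_row",
  "centroid_col", "dist_edge_px", "dist_centreline_px", "bbox_h", "bbox_w",
  "equiv_diameter_px", "log_sqrt_area", "class", "cluster_id", "kept")

#' Write / read a lesion table as tab-separated text
#'
#' One header line and one row per lesion; real values are written with
#' full precision so a round-trip preserves integers exactly and reals to
#' well below 1e-9. The leaf area and damage are carried in `#`-prefixed
#' header comments.
#'
#' @param table a [LesionTable-class].
#' @param path output TSV path.
#' @return `writeLesionTable` returns `path` invisibly;
#'   `readLesionTable` the reconstructed [LesionTable-class] (with an
#'   empty label map, which is not serialised).
#' @export
writeLesionTable <- function(table, path) {
  rec <- lesionRecords(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# image_id=%s", table@imageId),
               sprintf("# leaf_area_px=%d", table@leafAreaPx),
               sprintf("# damage_percent=%.17g", table@damagePercent)), con)
  cols <- .tableColumns()
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(rec)) {
    fmt <- function(v) {
      if (is.numeric(v) && !is.integer(v)) sprintf("%.17g", v)
      else as.character(v)
    }
    body <- do.call(cbind, lapply(rec[, cols], fmt))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeLesionTable
#' @param path TSV file written by [writeLesionTable()].
#' @export
readLesionTable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(sprintf("^# %s=", key), "",
                            grep(sprintf("^# %s=", key), hdr, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) .stopf("malformed lesion table '%s': no header line", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(.tableColumns(), cols)
  if (length(missing))
    .stopf("malformed lesion table '%s' at line %d: missing column(s) %s",
           path, length(hdr) + 1L, paste(missing, collapse = ", "))
  rec <- if (length(body) > 1L) {
    read.delim(text = body, sep = "\t", stringsAsFactors = FALSE)
  } else {
    df <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
    df
  }
  ints <- c("label", "area_px", "bbox_h", "bbox_w", "cluster_id")
  for (cc in ints) rec[[cc]] <- as.integer(rec[[cc]])
  rec$kept <- as.logical(rec$kept)
  recNoId <- rec[, setdiff(cols, "image_id"), drop = FALSE]
  new("LesionTable",
      imageId = getv("image_id"),
      records = recNoId,
      leafAreaPx = as.integer(getv("leaf_area_px")),
      damagePercent = as.numeric(getv("damage_percent")),
      labels = new("LesionLabelMap", labels = matrix(0L, 1, 1),
                   nLesions = max(0L, recNoId$label)))
}

#' Run the pipeline over a batch of scenes
#'
#' Processes every input, writes one lesion TSV (and optionally an
#' overlay PNG) per image plus a batch summary CSV, then — when `k > 0`
#' and at least one lesion was found — clusters all lesions of the batch,
#' drops the configured clusters, and rewrites tables and summaries with
#' `cluster_id`/`kept` filled in. Failing images are logged to stderr and
#' skipped; the others are still processed.
#'
#' @param cfg a `RunConfig` from [runConfig()].
#' @return Invisibly, a list: `summary` (batch data.frame, one row per
#'   image including failures flagged in `status`), `tables` (named list
#'   of [LesionTable-class]), `assignment` (the batch
#'   [ClusterAssignment-class] or `NULL`), `nFailed`.
#' @export
runPipeline <- function(cfg) {
  inputs <- cfg$inputs
  if (length(inputs) == 0L) .stopf("empty input set")
  outDir <- cfg$outputDir
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  tables <- list(); norms <- list()
  rows <- list()
  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    scene <- tryCatch(
      if (is(inp, "SceneImage")) inp else loadScene(inp),
      error = function(e) e)
    res <- if (inherits(scene, "error")) scene else
      tryCatch(processScene(scene, cfg), error = function(e) e)
    id <- if (inherits(scene, "error")) as.character(inp) else scene@id
    if (inherits(res, "error")) {
      message(sprintf("[lesionquant] %s FAILED: %s", id,
                      conditionMessage(res)))
      rows[[i]] <- data.frame(image_id = id, status = "failed",
                              leaf_area_px = NA_integer_, n_lesions = NA,
                              n_micro = NA, n_meso = NA, n_macro = NA,
                              lesion_area_px = NA, damage_percent = NA,
                              stringsAsFactors = FALSE)
      next
    }
    tables[[id]] <- res$table
    norms[[id]] <- res$norm
    s <- damageSummary(res$table)
    rows[[i]] <- data.frame(image_id = id, status = "ok",
                            s[, c("leaf_area_px", "n_lesions", "n_micro",
                                  "n_meso", "n_macro", "lesion_area_px",
                                  "damage_percent")],
                            stringsAsFactors = FALSE)
  }
  assignment <- NULL
  if (cfg$k > 0L && length(tables)) {
    allRec <- do.call(rbind, lapply(tables, lesionRecords))
    if (!is.null(allRec) && nrow(allRec)) {
      feats <- buildFeatures(allRec)
      assignment <- clusterLesions(feats, k = cfg$k, seed = cfg$seed)
      offset <- 0L
      for (id in names(tables)) {
        n <- nrow(tables[[id]]@records)
        if (n == 0L) next
        sub <- new("ClusterAssignment", k = assignment@k,
                   labels = assignment@labels[offset + seq_len(n)],
                   seed = assignment@seed, inertia = assignment@inertia)
        tables[[id]] <- applyFilter(tables[[id]], sub, cfg$dropClusters)
        offset <- offset + n
      }
      for (i in seq_along(rows)) {
        id <- rows[[i]]$image_id
        if (rows[[i]]$status == "ok" && !is.null(tables[[id]])) {
          s <- damageSummary(tables[[id]])
          rows[[i]][, c("n_lesions", "n_micro", "n_meso", "n_macro",
                        "lesion_area_px", "damage_percent")] <-
            s[, c("n_lesions", "n_micro", "n_meso", "n_macro",
                  "lesion_area_px", "damage_percent")]
        }
      }
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(cfg$filenamePattern)) {
    meta <- .parseFilenameMetadata(summary$image_id, cfg$filenamePattern)
    if (!is.null(meta)) summary <- cbind(summary, meta)
  }
  if (!is.null(outDir)) {
    for (id in names(tables)) {
      base <- tools::file_path_sans_ext(basename(id))
      writeLesionTable(tables[[id]], file.path(outDir,
                                               paste0(base, "_lesions.tsv")))
      if (isTRUE(cfg$writeOverlay))
        .writeOverlay(norms[[id]], tables[[id]],
                      file.path(outDir, paste0(base, "_overlay.png")))
    }
    utils::write.csv(summary, file.path(outDir, "batch_summary.csv"),
               row.names = FALSE)
  }
  nFailed <- sum(summary$status == "failed")
  if (nFailed) message(sprintf("[lesionquant] %d of %d image(s) failed",
                               nFailed, nrow(summary)))
  invisible(list(summary = summary, tables = tables,
                 assignment = assignment, nFailed = nFailed))
}

# Extract metadata columns from file names via a named-group regex.
.parseFilenameMetadata <- function(ids, pattern) {
  m <- regexpr(pattern, basename(ids), perl = TRUE)
  starts <- attr(m, "capture.start")
  if (is.null(starts)) return(NULL)
  nm <- colnames(starts)
  out <- as.data.frame(matrix(NA_character_, length(ids), length(nm)),
                       stringsAsFactors = FALSE)
  names(out) <- nm
  for (j in seq_along(nm)) {
    ok <- starts[, j] > 0
    out[ok, j] <- substring(basename(ids)[ok], starts[ok, j],
                            starts[ok, j] + attr(m, "capture.length")[ok, j] - 1L)
  }
  out
}
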