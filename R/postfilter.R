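# False-positive removal: feature standardisation, mini-batch k-means
# clustering, inspection galleries and cluster-based filtering.

.featureColumns <- c("area_px", "theta_max", "theta_range", "amp_max",
                     "amp_range", "eccentricity", "log_sqrt_area")

.recordsOf <- function(x) {
  if (is(x, "LesionTable")) x@records
  else if (is.data.frame(x)) x
  else .stopf("expected a LesionTable or a records data.frame")
}

#' Build the standardized lesion feature matrix
#'
#' Extracts the seven clustering descriptors (`area_px`, `theta_max`,
#' `theta_range`, `amp_max`, `amp_range`, `eccentricity`,
#' `log_sqrt_area`), in that fixed order, and z-standardizes each column
#' (sd floored at 1e-9 so constant columns stay finite).
#'
#' @param x a [LesionTable-class] or a records data.frame (e.g. several
#'   tables' records row-bound for batch-level filtering).
#' @return A [FeatureMatrix-class]; zero rows signal nothing to filter.
#' @export
buildFeatures <- function(x) {
  rec <- .recordsOf(x)
  if (!nrow(rec)) {
    message("nothing to filter: empty lesion table")
    return(new("FeatureMatrix",
               features = matrix(numeric(0), 0, 7,
                                 dimnames = list(NULL, .featureColumns)),
               center = setNames(numeric(7), .featureColumns),
               scale = setNames(rep(1, 7), .featureColumns)))
  }
  raw <- as.matrix(rec[, .featureColumns])
  ctr <- colMeans(raw)
  scl <- pmax(apply(raw, 2, sd), 1e-9)
  if (nrow(raw) == 1L) scl[] <- 1
  feats <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  new("FeatureMatrix", features = feats, center = ctr, scale = scl)
}

# kmeans++ seeding: spread initial centers proportionally to squared
# distance from those already chosen.
.kmeansppInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1, ] <- x[i, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1L, prob = p)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

.nearestCenter <- function(x, centers) {
  cross <- x %*% t(centers)
  cn <- rowSums(centers^2)
  d <- sweep(-2 * cross, 2, cn, "+")  # + rowSums(x^2), constant per row
  max.col(-d, ties.method = "first")
}

#' Cluster lesions with mini-batch k-means
#'
#' Runs mini-batch k-means (kmeans++ initialisation, per-center learning
#' rate `1/count`) on the standardized features. With fewer lesions than
#' requested clusters, `k` is reduced to `n`. The assignment is
#' deterministic for fixed (features, k, seed).
#'
#' @param feats a [FeatureMatrix-class].
#' @param k requested number of clusters (default 30).
#' @param seed RNG seed.
#' @param batchSize mini-batch size (default 256, capped at n).
#' @param iterations number of mini-batch updates (default 100).
#' @return A [ClusterAssignment-class] with 1-based labels.
#' @export
clusterLesions <- function(feats, k = 30L, seed = 1L, batchSize = 256L,
                           iterations = 100L) {
  x <- feats@features
  n <- nrow(x)
  if (n == 0L)
    return(new("ClusterAssignment", k = 0L, labels = integer(0),
               seed = as.integer(seed), inertia = 0))
  k <- as.integer(min(k, n))
  b <- as.integer(min(batchSize, n))
  .withSeed(seed, {
    centers <- .kmeansppInit(x, k)
    counts <- rep(0, k)
    for (it in seq_len(iterations)) {
      batch <- if (b == n) seq_len(n) else sample.int(n, b)
      asg <- .nearestCenter(x[batch, , drop = FALSE], centers)
      for (j in unique(asg)) {
        pts <- x[batch[asg == j], , drop = FALSE]
        for (r in seq_len(nrow(pts))) {
          counts[j] <- counts[j] + 1
          eta <- 1 / counts[j]
          centers[j, ] <- (1 - eta) * centers[j, ] + eta * pts[r, ]
        }
      }
    }
    lab <- .nearestCenter(x, centers)
    inertia <- sum((x - centers[lab, , drop = FALSE])^2)
    new("ClusterAssignment", k = k, labels = as.integer(lab),
        seed = as.integer(seed), inertia = inertia)
  })
}

#' Suggest clusters that look like false positives
#'
#' False positives from uneven clearing are dark but not blue: their
#' blueness stays near the achromatic angle `acos(1/sqrt(3))` (~0.955
#' rad). Clusters whose mean `theta_max` falls below the blueness floor
#' are suggested for removal.
#'
#' @param x a [LesionTable-class] or records data.frame the assignment
#'   was computed on.
#' @param assign a [ClusterAssignment-class].
#' @param thetaFloor blueness floor in radians (default 1.05, slightly
#'   above the achromatic angle).
#' @return Integer vector of suggested cluster ids.
#' @export
suggestDropClusters <- function(x, assign, thetaFloor = 1.05) {
  rec <- .recordsOf(x)
  if (!nrow(rec)) return(integer(0))
  mt <- tapply(rec$theta_max, factor(assign@labels, levels = seq_len(assign@k)),
               mean)
  unname(which(!is.na(mt) & mt < thetaFloor))
}

#' Mark lesions in dropped clusters as filtered out
#'
#' Lesions in the dropped clusters get `kept = FALSE` (rows are retained
#' for audit) and `cluster_id` is filled in for all lesions; the damage
#' percentage is recomputed over kept lesions.
#'
#' @param table a [LesionTable-class] (or records data.frame, in which
#'   case the updated records are returned and no damage is recomputed).
#' @param assign a [ClusterAssignment-class] covering the table rows.
#' @param dropIds integer set of cluster ids to drop (possibly empty).
#' @return The filtered object of the same type as `table`.
#' @export
applyFilter <- function(table, assign, dropIds = integer(0)) {
  rec <- .recordsOf(table)
  if (length(assign@labels) != nrow(rec))
    .stopf("assignment covers %d lesions but table has %d",
           length(assign@labels), nrow(rec))
  dropIds <- as.integer(dropIds)
  if (length(dropIds) && (any(dropIds < 1L) || any(dropIds > assign@k)))
    .stopf("unknown cluster id in dropIds (k = %d)", assign@k)
  if (nrow(rec)) {
    rec$cluster_id <- assign@labels
    rec$kept <- rec$kept & !(assign@labels %in% dropIds)
  }
  if (!is(table, "LesionTable")) return(rec)
  new("LesionTable", imageId = table@imageId, records = rec,
      leafAreaPx = table@leafAreaPx,
      damagePercent = if (nrow(rec))
        100 * sum(rec$area_px[rec$kept]) / table@leafAreaPx else 0,
      labels = table@labels)
}

#' Render per-cluster inspection galleries
#'
#' For each cluster, samples up to `grid[1] * grid[2]` member lesions
#' without replacement (seeded), crops a padded thumbnail around each from
#' the white-balanced image, and writes one annotated montage PNG per
#' cluster into `dir`.
#'
#' @param table a [LesionTable-class].
#' @param image the [NormImage-class] (or [SceneImage-class]) the lesions
#'   were detected on; `NULL` draws placeholder tiles.
#' @param assign a [ClusterAssignment-class] covering the table.
#' @param dir output directory (created if needed).
#' @param grid montage rows and columns (default `c(10, 15)`).
#' @param seed RNG seed for the sampling.
#' @param tile thumbnail side in pixels.
#' @param pad context padding around the lesion bounding box, in px.
#' @return Invisibly, the written file paths (named by cluster id).
#' @export
renderGallery <- function(table, image, assign, dir, grid = c(10L, 15L),
                          seed = 1L, tile = 32L, pad = 4L) {
  rec <- table@records
  if (length(assign@labels) != nrow(rec))
    .stopf("assignment does not cover the table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- if (is.null(image)) NULL else pixels(image)
  capacity <- grid[1] * grid[2]
  paths <- character(0)
  for (cid in sort(unique(assign@labels))) {
    members <- which(assign@labels == cid)
    take <- if (length(members) > capacity)
      .withSeed(seed + cid, sample(members, capacity)) else members
    tiles <- lapply(take, function(i) {
      if (is.null(px)) {
        warning(sprintf("missing crop for lesion %d; placeholder tile",
                        rec$label[i]))
        return(array(0.5, c(tile, tile, 3)))
      }
      r0 <- max(1L, rec$centroid_row[i] - rec$bbox_h[i] / 2 - pad)
      r1 <- min(nrow(px), rec$centroid_row[i] + rec$bbox_h[i] / 2 + pad)
      c0 <- max(1L, rec$centroid_col[i] - rec$bbox_w[i] / 2 - pad)
      c1 <- min(ncol(px), rec$centroid_col[i] + rec$bbox_w[i] / 2 + pad)
      crop <- px[floor(r0):ceiling(r1), floor(c0):ceiling(c1), , drop = FALSE]
      as.array(EBImage::resize(EBImage::Image(aperm(crop, c(2, 1, 3)),
                                              colormode = "Color"),
                               w = tile, h = tile))
    })
    nr <- ceiling(length(tiles) / grid[2])
    nc <- min(length(tiles), grid[2])
    canvas <- array(1, c(nr * tile, nc * tile, 3))
    for (j in seq_along(tiles)) {
      rr <- (j - 1) %/% nc; cc <- (j - 1) %% nc
      t3 <- aperm(tiles[[j]], c(2, 1, 3))
      canvas[rr * tile + seq_len(tile), cc * tile + seq_len(tile), ] <-
        .clamp(t3, 0, 1)
    }
    f <- file.path(dir, sprintf("cluster_%02d_n%d.png", cid, length(members)))
    grDevices::png(f, width = max(480, nc * tile * 2),
                   height = max(240, nr * tile * 2 + 40))
    graphics::par(mar = c(0.2, 0.2, 2, 0.2))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = NA)
    graphics::rasterImage(canvas, 0, 0, 1, 1, interpolate = FALSE)
    graphics::title(sprintf("cluster %d (n = %d)", cid, length(members)))
    grDevices::dev.off()
    paths[as.character(cid)] <- f
  }
  invisible(paths)
}
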