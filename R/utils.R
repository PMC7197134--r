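# Internal numerical/plumbing helpers shared across the pipeline stages.

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Channel-mean intensity of an H x W x 3 array.
.intensity <- function(px) (px[, , 1] + px[, , 2] + px[, , 3]) / 3

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels whose pixels touch diagonally are merged with union-find.
.label8 <- function(mask) {
  mask <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  newid <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- newid[lab[lab > 0L]]
  out
}

# Density-based spatial clustering (DBSCAN), grid-bucketed on the first two
# dimensions (which bound the full Euclidean distance for eps-neighbours).
# Returns an integer cluster label per row; 0 marks noise.
.dbscan <- function(x, eps, minPts) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n == 0L) return(integer(0))
  cx <- as.integer(floor(x[, 1] / eps))
  cy <- as.integer(floor(x[, 2] / eps))
  cellIdx <- split(seq_len(n), paste(cx, cy, sep = ","))
  off <- expand.grid(dx = -1:1, dy = -1:1)
  neighbours <- function(i) {
    keys <- paste(cx[i] + off$dx, cy[i] + off$dy, sep = ",")
    cand <- unlist(cellIdx[keys], use.names = FALSE)
    dif <- x[cand, , drop = FALSE] - matrix(x[i, ], length(cand), d, byrow = TRUE)
    cand[rowSums(dif * dif) <= eps * eps]
  }
  labels <- integer(n); visited <- logical(n); cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours(i)
    if (length(nb) < minPts) next   # noise unless later claimed as border
    cl <- cl + 1L
    labels[i] <- cl
    labels[nb[labels[nb] == 0L]] <- cl
    queue <- nb; qi <- 1L
    while (qi <= length(queue)) {
      j <- queue[qi]; qi <- qi + 1L
      if (visited[j]) next
      visited[j] <- TRUE
      nb2 <- neighbours(j)
      if (length(nb2) >= minPts) {
        fresh <- nb2[!visited[nb2] & labels[nb2] == 0L]
        labels[fresh] <- cl
        queue <- c(queue, fresh)
      }
    }
  }
  labels
}

# 2-D convolution with symmetric (reflective, edge-repeated) boundary,
# via FFT on a padded copy. k must have odd dimensions.
.convolve2 <- function(x, k) {
  pr <- (nrow(k) - 1L) %/% 2L
  pc <- (ncol(k) - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  ri <- c(if (pr > 0) seq(pr, 1L), seq_len(H), if (pr > 0) seq(H, H - pr + 1L))
  ci <- c(if (pc > 0) seq(pc, 1L), seq_len(W), if (pc > 0) seq(W, W - pc + 1L))
  xp <- x[ri, ci, drop = FALSE]
  fp <- EBImage::filter2(xp, k, boundary = "circular")
  matrix(fp, nrow(xp), ncol(xp))[pr + seq_len(H), pc + seq_len(W), drop = FALSE]
}

# Binary morphology wrappers returning logical matrices.
.dilate3 <- function(mask) {
  out <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                         EBImage::makeBrush(3, "box"))
  matrix(out > 0.5, nrow(mask), ncol(mask))
}

.close3 <- function(mask) {
  out <- EBImage::closing(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                          EBImage::makeBrush(3, "box"))
  matrix(out > 0.5, nrow(mask), ncol(mask))
}

.fillHoles <- function(mask) {
  out <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(out > 0.5, nrow(mask), ncol(mask))
}

# Row/col index vectors for the linear indices of an H x W matrix.
.rowOf <- function(idx, H) ((idx - 1L) %% H) + 1L
.colOf <- function(idx, H) ((idx - 1L) %/% H) + 1L

# Bounding boxes (min/max row/col) per label of a label matrix.
.labelBBoxes <- function(lab) {
  idx <- which(lab > 0L)
  lb <- lab[idx]
  H <- nrow(lab)
  r <- .rowOf(idx, H); c <- .colOf(idx, H)
  n <- max(lab)
  data.frame(
    label = seq_len(n),
    r0 = as.vector(tapply(r, factor(lb, levels = seq_len(n)), min)),
    r1 = as.vector(tapply(r, factor(lb, levels = seq_len(n)), max)),
    c0 = as.vector(tapply(c, factor(lb, levels = seq_len(n)), min)),
    c1 = as.vector(tapply(c, factor(lb, levels = seq_len(n)), max)),
    area = tabulate(lb, n))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
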