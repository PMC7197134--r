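# Shared fixtures, built in code at test time.

# Bright field with a dark axis-aligned rectangle (rows/cols are 1-based
# inclusive bounds).
brightFieldWithRect <- function(H = 80, W = 100, bright = 0.9, dark = 0.3,
                                rows = 30:55, cols = 40:70) {
  px <- array(bright, c(H, W, 3))
  for (ch in 1:3) px[rows, cols, ch] <- dark
  SceneImage(px, id = "rect_fixture")
}

# Bright field with a centered dark ellipse; returns the scene and the
# ellipse mask.
brightFieldWithEllipse <- function(H = 80, W = 100, bright = 0.9, dark = 0.3,
                                   ra = 18, rb = 28) {
  r <- matrix(seq_len(H), H, W); c <- matrix(seq_len(W), H, W, byrow = TRUE)
  ell <- ((r - H / 2) / ra)^2 + ((c - W / 2) / rb)^2 <= 1
  px <- array(bright, c(H, W, 3))
  for (ch in 1:3) { p <- px[, , ch]; p[ell] <- dark; px[, , ch] <- p }
  list(scene = SceneImage(px, id = "ellipse_fixture"), ellipse = ell)
}

# StainMap built directly from a stain matrix (theta/amplitude chosen so
# stain = theta * amplitude holds; leaf covers everything by default).
stainMapFrom <- function(stain, leaf = NULL) {
  if (is.null(leaf)) leaf <- matrix(TRUE, nrow(stain), ncol(stain))
  amp <- matrix(1, nrow(stain), ncol(stain))
  theta <- stain
  theta[!leaf] <- 0
  st <- theta * amp
  st[!leaf] <- 0
  new("StainMap", theta = pmin(theta, pi / 2), amplitude = amp * pmax(1, stain),
      stain = st, leaf = leaf)
}

# The above caps theta; for tests needing exact stain values use amplitude
# to carry the magnitude instead.
stainMapExact <- function(stain, leaf = NULL) {
  if (is.null(leaf)) leaf <- matrix(TRUE, nrow(stain), ncol(stain))
  st <- stain
  st[!leaf] <- 0
  theta <- matrix(1, nrow(st), ncol(st))
  theta[st == 0] <- 0
  new("StainMap", theta = theta, amplitude = abs(st), stain = st, leaf = leaf)
}

# Independent brute-force convolution oracle with symmetric (reflective,
# edge-repeated) padding — never calls the package's convolution.
bruteConvolve <- function(x, k) {
  pr <- (nrow(k) - 1L) %/% 2L; pc <- (ncol(k) - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  ri <- c(if (pr > 0) seq(pr, 1L), seq_len(H), if (pr > 0) seq(H, H - pr + 1L))
  ci <- c(if (pc > 0) seq(pc, 1L), seq_len(W), if (pc > 0) seq(W, W - pc + 1L))
  xp <- x[ri, ci, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    out[i, j] <- sum(xp[(i):(i + 2 * pr), (j):(j + 2 * pc)] * k)
  }
  out
}

# A small synthetic scene that keeps per-test pipeline runs fast.
smallSceneSpec <- function(...) {
  args <- list(width = 220, height = 170, leafRadii = c(55, 65),
               nLesions = 5L, lesionRadiusRange = c(3, 8), markerSide = 22L)
  do.call(syntheticSpec, utils::modifyList(args, list(...)))
}

# Label map wrapper for hand-built detection masks.
labelMapFrom <- function(labels) {
  new("LesionLabelMap", labels = labels, nLesions = max(labels))
}

# LeafMask wrapper for hand-built masks.
leafMaskFrom <- function(leaf, holes = NULL) {
  if (is.null(holes)) holes <- matrix(FALSE, nrow(leaf), ncol(leaf))
  new("LeafMask", leaf = leaf, holes = holes,
      leafAreaPx = as.integer(sum(leaf)), holeAreaPx = as.integer(sum(holes)))
}
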