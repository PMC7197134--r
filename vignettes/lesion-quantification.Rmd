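---
title: "Quantifying stained leaf lesions with LesionQuant"
author: "LesionQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stained leaf lesions with LesionQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LesionQuant)
```

## The measurement problem

Dead plant tissue takes up trypan blue; viable cells exclude it. After
clearing (chlorophyll removal) and staining, a leaf photographed on a
backlit light table shows damage as blue-absorbing patches on a cream,
translucent background — from single-cell "microlesions" of one pixel up
to cuts spanning hundreds of pixels. LesionQuant turns such a
transmitted-light RGB image into (i) a leaf mask with true holes, (ii) a
table of per-lesion morphometrics, and (iii) a leaf-scale damage
percentage,

$$\mathrm{Damage} = \frac{\text{lesion area}}{\text{leaf area}} \times 100 ,$$

with a clustering-based post-filter that removes false positives caused by
unevenly cleared (dark but not blue) tissue.

## The pipeline, stage by stage

**Scene ingestion.** The scene is downscaled by a total pixel factor of 16
(4 × 4 block means) for speed. A gamma correction (exponent 0.5) is
applied to the channel-mean intensity, and bright light-table candidates
are selected relative to the bright reference level (the 95th percentile
of the corrected intensity, cut at fraction 0.9). The cut is deliberately
*relative*: it is invariant to a global exposure change, and it must sit
above the leaf/table transmission contrast after gamma (about 0.82 for a
cream cleared leaf) plus the unevenness of the illumination (several
percent on a consumer light table). Candidate coordinates (a seeded
subsample of at most 50,000) are grouped by density-based spatial
clustering; the largest cluster is the light table, and the mask is
completed from the connected components of the candidate mask. Holes in
the background are then ranked by area: the largest is the leaf; a
near-square, compact hole (aspect ratio within [0.8, 1.25],
bounding-box fill ≥ 0.9) is the 1-cm² size marker; an elongated hole
(aspect ratio ≥ 2) is the barcode label. These classification rules are
plumbing chosen here — only the classes themselves are inherent to the
scene. The leaf is cropped from the full-resolution image with its
surrounding background (8 px margin at the downscaled resolution).

**Illumination reconstruction and white balance.** Light tables are not
uniform, so a global threshold on raw intensity is unreliable. A crude
foreground mask is obtained by density clustering on joint
(row, col, R, G, B) features — largest cluster background, second largest
leaf — and the "white image" (the scene as it would look without the
leaf) is reconstructed by copying background pixels and infilling the
foreground per channel with 1-D linear interpolation along rows and
columns, averaged. This infill is bounded by the surrounding background
values and continues a linear illumination gradient exactly; any smooth,
bounded interpolant would be acceptable, and the row/column scheme was
chosen for transparency and speed. Dividing the scene by the white image
gives a normalised image whose background is ≈ 1; ratios above 1
(specular noise) are clipped to 1 and values are floored at 1e-4 so the
log transform below stays finite. The leaf mask is Otsu's threshold on
the grayscale (unweighted channel mean) of the normalised image: the
largest dark 8-connected component is the leaf, enclosed bright regions
are recorded as real holes, and the leaf area excludes them. If the
dark/bright class separation falls below 0.1 the mask is refused — this
reproduces the known failure mode of very thin, bright leaves being
mistaken for background rather than silently returning nonsense.

**Stain map.** The normalised transmission is converted to absorbance
$a = -\log(\mathrm{norm})$ per channel and expressed in spherical form:
the *amplitude* $\rho = \lVert a \rVert_2$ is overall darkness; the
blueness angle is measured from the blue absorbance axis,
$\theta = \arccos(a_B / \rho)$. A pixel that absorbs red and green but
transmits blue — i.e. looks blue — has small $a_B$ and large $\theta$; an
achromatic pixel scores $\arccos(1/\sqrt3) \approx 0.955$ rad regardless
of its gray level; a white pixel scores 0. The stain score is
$\theta\rho$, zeroed outside the leaf. The axis convention is a design
choice (the alternative orderings are selectable in code by permuting
channels); this one makes "blue and dark" large, which is what the dye
signal is.

**Multiscale detection.** The stain image is convolved with zero-sum
center-surround kernels: an inner disc of radius $r \in \{1,\dots,13\}$
with weight $+1/N_{in}$ and an annulus out to $2r$ with weight
$-1/N_{out}$. The kernels sum to zero, so constant regions give zero
response and the detector adapts to each image's own contrast. Each of
the 13 response images is thresholded at 0.1 of *its own* maximum
(comparisons are ≥), dilated once with a 3 × 3 square, hole-filled, and
labelled (8-connectivity). Within each labelled segment, pixels at or
above 60% of the within-segment stain range are kept; the refined
binaries of all scales are OR-ed, restricted to the leaf, and relabelled.
The surround radius ($2r$), the ≥ convention, the dilation element and
the reflective boundary handling are numerical choices fixed here and
kept configurable; dilate-then-fill and fill-then-dilate give nearly
identical results on disc-like lesions, and the former is used. The
radius-1 kernel (an inner cross of 5 pixels) is what gives the method its
single-pixel sensitivity: an isolated 1-px lesion with stain well above
the local residual responds at $1/5$ of its stain value.

**Morphometrics and classes.** Per lesion the table records pixel and
physical area, min/max/range of $\theta$ and $\rho$, centroid,
moments-based eccentricity (a 1-px lesion is defined to score 0),
boundary perimeter counted as exposed pixel edges, circularity
$4\pi A/P^2$ capped at 1, bounding box, equivalent diameter
$\sqrt{4A/\pi}$, distance from the centroid to the nearest non-leaf pixel
(Euclidean distance transform) and to the leaf centreline, and
$\log_{10}(\sqrt{A}+0.1)$. The centreline is the principal (major) axis
through the leaf-mask centroid — a medial-axis variant would track curved
leaves better but is unstable for lobed margins, so the axis was chosen
as the default. Physical calibration comes from the 1-cm² marker
($10^8/\text{marker px}$ µm²/px) or, absent a marker, a configured value
(default 1800 µm²/px, the scale of a fixed-height setup where one pixel
is about half an epidermal cell). Classes partition area disjointly:
micro = 1 px, meso = 2–200 px, macro > 200 px; at the default calibration
the meso/macro boundary is 360,000 µm².

**Post-filtering.** Each lesion is described by exactly seven features —
area, $\theta_{max}$, $\theta$ range, $\rho_{max}$, $\rho$ range,
eccentricity, $\log_{10}(\sqrt{A}+0.1)$ — z-standardized per column
(raw-scale area would otherwise dominate the Euclidean metric) and
clustered with mini-batch k-means into 30 clusters (kmeans++
initialisation, per-center learning rate $1/n$, seeded and deterministic;
`k` is reduced to the lesion count when smaller). Inspection galleries
(10 × 15 thumbnails per cluster by default, seeded sampling without
replacement) support the manual decision of which clusters are false
positives; an automated suggestion flags clusters whose mean
$\theta_{max}$ stays below a blueness floor (default 1.05 rad, just above
the achromatic angle), since false positives from uneven clearing are
dark rather than blue. Dropped lesions are retained with `kept = FALSE`
for audit, and damage is recomputed over kept lesions only.

## What the synthetic scenes emulate — and what they do not

`syntheticSpec()` renders, deterministically for a given seed: a bright,
slightly colour-tinted background with a smooth low-order illumination
field (±6% by default); a wobbled-ellipse leaf with transmission
(0.75, 0.70, 0.55) and a darker midrib band (×0.8); disc lesions whose
red/green transmission drops to 0.16 at the rim and 0.10 in a darker core
(blue ≈ ×0.95), so they are blue *and* dark and the core/rim structure
exercises the over-segmentation behaviour; optional capsule-shaped cuts
(> 200 px macrolesions); achromatic confounder patches (×0.45 all
channels) emulating uneven clearing; real holes; a dark 1-cm² marker
square and a striped barcode region; and Gaussian pixel noise
(sd 0.01). Damage presets 0–5 range from an undamaged negative control
through low (1–2) and high (3–5) severity, level 5 adding cuts.

Two default choices deserve their arithmetic spelled out. First, lesion
$\theta$ must exceed the achromatic angle by a solid margin: at the rim,
$a \approx (2.1, 2.2, 0.65)$ gives $\theta \approx 1.36 \gg 0.955$.
Second, the 60% refinement level must fall between the leaf-halo stain
and the rim stain *including noise on the order statistics*: a segment
that includes halo pixels has min ≈ 0.5 and max ≈ core stain plus the
maximum of a few hundred noise deviates (≈ 5.3 + 0.45), putting the level
near 3.6, safely below the rim stain (≈ 4.2 − 3σ ≈ 3.97). With the core
at 0.07 instead, the level lands exactly on the rim value and lesion rims
erode — which is why the defaults are 0.10/0.16.

The scenes deliberately do not model venation (beyond the midrib),
partial-coverage edge pixels, camera optics, chromatic noise, or the
full biological variability of clearing quality. Passing the recovery
checks therefore demonstrates that the *algorithmic chain* is faithful —
segmentation, transform, detection, measurement and filtering compose
correctly and recover known truth — not that any particular accuracy
will be attained on field-collected images, whose clearing artefacts are
richer than the single confounder class rendered here.

## Validation problem sizes

The packaged checks run 20 default scenes of 420 × 320 px with 12
lesions each (radii 3–20 px), severity presets 0–5 over several seeds,
and two confounder scenes with 6 achromatic patches; these sizes keep a
full validation run in the low minutes on one core while still covering
every lesion class and failure mode. On these scenes the pipeline
recovers leaf area exactly, lesion counts and total damage to within a
few percent, detected damage is strictly rank-ordered across the
severity presets, and truth-defined confounder clusters are removed
without losing true lesions (the `scripts/acceptance.R` report recomputes
all of these).

## Degenerate inputs and tie-breaks

Flat scenes are all light table by construction of the relative cut; an
all-dark scene raises "no light table found" (absolute floor 0.15).
Equal-size density clusters are broken by higher mean intensity. An
all-zero stain map yields 13 empty label images, not an error. A
zero-range segment keeps all its pixels in refinement. Tables with no
lesions short-circuit the post-filter with a message. Cluster count is
capped at the lesion count. Perimeter of a 1-px lesion is 4 edges;
circularity is capped at 1 for pixelated shapes whose edge-count
perimeter underestimates smoothness.

## Known limitations

- The raw-sensor path accepts RGGB mosaics in standard raster
  containers and demosaics bilinearly; proprietary camera-raw container
  decoding is out of scope.
- One leaf per scene is assumed (the largest background hole); multi-leaf
  scenes require splitting upstream.
- Lesions larger than the top kernel radius (13 px) are detected through
  their edge response plus hole-filling; extremely large uniform lesions
  with no internal structure could in principle under-fill.
- The centreline distance uses the principal axis, which bends away from
  the anatomical midrib for strongly curved leaves.
- Mini-batch k-means is deterministic per seed but, like any k-means,
  only locally optimal; the gallery/inspection step exists precisely
  because cluster identity is not semantic.
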