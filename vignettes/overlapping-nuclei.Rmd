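---
title: "Detecting overlapping nuclei in cervical cytology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting overlapping nuclei in cervical cytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoverlap)
```

## The problem

In a Pap smear preparation, cell nuclei project onto the image plane and
frequently intersect. Two overlapped nuclei render as a single merged
dark region that is larger, flatter and more irregular than a single
nucleus, and — crucially — carries more than one intensity valley,
because each nucleus contributes its own density maximum. `cytoverlap`
detects such regions without any training data: it extracts candidate
nucleus boundaries morphologically, summarizes each candidate with five
shape and texture features, and clusters the feature vectors into two
groups, overlapped and single.

This vignette records the model assumptions, the tunable parameters and
their defaults, the numerical choices made where the design was
genuinely open, and what the synthetic validation does and does not
demonstrate.

## Stage 1: boundary extraction

**Hue gate.** Cytoplasmic material in a stained cervical sample falls in
a mid-hue band; the bright slide background, blood and many artifacts do
not. `hue_gate()` converts RGB to HSV (range 0–1) and keeps pixels with
hue in the closed interval \[`hue_lo` = 0.2, `hue_hi` = 0.7\]. The
interval is closed at both ends: hue is a continuous quantity and the
boundary choice is arbitrary, so we pick the inclusive convention for
determinism. Only the hue channel is used; saturation and value are
deliberately ignored (keeping the gate insensitive to staining
intensity), which users should know when samples are nearly achromatic.
The raw gate is cleaned by a morphological closing (disk radius 5 px,
configurable) and hole filling so the cluster support forms solid
blobs.

**Gradient and edges.** The grayscale image (luma weights
0.299/0.587/0.114, rounded half-up, for bit-exact reproducibility) is
differentiated with the 3×3 Sobel kernels and the two responses
combined as a Euclidean norm. The edge filter then operates on this
magnitude raster: Gaussian smoothing (σ = 1), normalization to \[0, 1\]
by the maximum, hysteresis thresholding with a strong threshold of 0.4
and a low threshold at 40 % of it, and finally thinning of the
surviving ridge band to one-pixel curves.

Two numerical choices deserve a note:

* *Thinning instead of directional non-maximum suppression.* Downstream
  stages require **closed** contours (an open arc cannot be filled).
  Directional suppression tends to leave one-pixel diagonal gaps where
  the gradient direction quantizes; morphological (Zhang–Suen) thinning
  of the hysteresis band preserves connectivity by construction. The
  cost is a small inward bias of the resulting centerline, addressed
  below.
* *Single published threshold.* The classical edge filter needs two
  thresholds, but the method is specified by a single value (0.4). We
  adopt the common convention `low = 0.4 × high`, exposed as
  `canny_low_ratio`.

**Morphological filtering.** Edge components are filtered by pixel
count (default window \[20, 5000\] at the 1280×960 reference scale,
rescaled by image area — the window acts on *edge component length*,
not enclosed area, since the boundary of a nucleus is what the edge
stage produces). Components that do not enclose any interior pixel
(open arcs) are removed. Remaining components are reduced to simple
closed curves: iterative spur pruning deletes pixels with a single
8-neighbor to a fixpoint, then redundant junction pixels are deleted
one at a time, a deletion being accepted only if every remaining pixel
keeps at least two neighbors, the component stays 8-connected, **and no
enclosed interior pixel leaks out**. The last guard is essential: at
the waist of a merged pair the outline develops a chord, and without
the enclosure check the cleanup can open the outer ring while all local
degree conditions still hold.

**Regions.** Each closed curve is filled by flood filling its
complement from the bounding-box exterior. The filled mask is then
dilated by one pixel (`region_dilate = 1`): the thinned curve is the
centerline of a gradient band roughly three pixels wide, so the raw
fill systematically excludes the outer half of the dark-to-bright
transition; one dilation restores the full dark support (measured on
synthetic scenes this recovers ~0.10–0.15 of mask Tanimoto). Candidate
regions whose centroid lies outside the cell-cluster mask are removed —
centroid membership is cheap and unambiguous compared with
any-overlap rules. Overlapping candidates are resolved in favor of the
larger one (a junction pocket loop would otherwise displace the
enclosing outline), regions below `min_nucleus_area` (50 px² at
reference scale) are dropped, and labels are assigned in raster-scan
order of centroids so runs are deterministic.

## Stage 2: the five-feature descriptor

The descriptor couples three shape features with two texture features.

| feature | definition | default-relevant choices |
|---|---|---|
| eccentricity | `sqrt(1 − b²/a²)` from the mask's second central moments (+1/12 pixel-variance correction) | 0 = circle; degenerate masks clamp to 1 − ε with a warning |
| axis ratio | `a/b` ≥ 1 | — |
| diameter ratio | `sqrt(4·Area/π) / (P_n/π)` | `P_n` = count of region pixels with a 4-neighbor outside |
| n_minima | number of 8-connected local-minimum plateaus | optional pre-smoothing, σ = 1 in the pipeline default |
| max_minima_dist | largest pairwise distance between minima | 0 when fewer than two minima |

Notes:

* *Perimeter convention.* `P_n` counts boundary **pixels** literally.
  On a digital circle this undercounts the geometric circumference by
  roughly 11 %, so the diameter ratio of an ideal disk sits near 1.12
  rather than 1.0. The feature is used comparatively (wavy outlines
  push it *down*), so the offset is harmless, but absolute values
  should not be read as calibrated geometry. The ratio stays in
  (0, 1.2\] for convex rasterized shapes.
* *Local minima.* A pixel qualifies when no 8-neighbor is strictly
  darker; a connected constant-intensity plateau counts as **one**
  minimum at its centroid (a strict reading would silently drop
  flat-bottomed valleys, which 8-bit quantization makes common). Only
  pixels whose full 8-neighborhood lies inside the region are eligible,
  so region-boundary artifacts cannot register. The pipeline smooths
  with σ = 1 before minima detection: sensor noise and quantization
  create spurious one-pixel minima, and a one-pixel Gaussian removes
  them while leaving genuine valleys (tens of gray levels deep, ~10 px
  apart) intact. Set `minima_sigma = 0` to analyse raw intensities.
* *Standardization.* The five features are z-scored before clustering
  (`standardize = TRUE`). The two minima features are measured in
  counts and pixels (tens), the shape features are dimensionless near
  1; unstandardized Euclidean distance would be dominated by features
  4–5. `--no-standardize` reproduces the literal unscaled metric.

## Stage 3: clustering

Both back-ends are implemented in the package and share kmeans++-style
seeding from a single seed.

* **k-means** (Lloyd): assign to the nearest centroid, recompute
  centroids as means; the within-cluster sum of squares is
  non-increasing and the per-iteration trace is kept for audit. Ten
  restarts by default; an emptied cluster is reseeded at the worst-fit
  point.
* **Fuzzy c-means**: memberships `u_ij` are inverse-distance ratios
  raised to `2/(m−1)`; centroids are `u^m`-weighted means; iteration
  stops when the largest membership change drops below `tol = 1e-5`
  (the published description states only "a threshold"). The fuzzifier
  defaults to the canonical `m = 2`; as `m → 1` the calls coincide with
  k-means. A point coinciding with a centroid takes membership one by
  the standard singularity rule.

The cluster whose centroid has the larger (standardized) `n_minima`
coordinate is labeled *overlapped* — overlap adds intensity valleys,
never removes them — with ties broken by `max_minima_dist`, then
`axis_ratio`; identical centroids in all three raise an error rather
than guess. Each region's confidence is its maximum membership (always
1 for k-means).

## The synthetic scene generator

No suitable public image set ships with ground-truth *overlap* labels
at the instance level, so the package renders its own scenes
(`generate_scene()`): a bright background (gray level 225), one large
elliptical cytoplasmic cluster (200), and dark elliptical nuclei
(center 60, ramping quadratically to the nucleus/cytoplasm midpoint at
the rim) placed inside the cluster without unintended contact. An
overlapped pair is rendered as the pixelwise minimum of two such
profiles at center distance 0.6 × the summed mean radii, which keeps
both valley bottoms and darkens the junction. Hue is synthesized by
fixed channel offsets that put cytoplasm and nuclei at hue 0.45 and
background at 0.95 — safely inside/outside the 0.2–0.7 gate — chosen so
that the 8-bit luma of the rendered color equals the designed intensity
plus a constant; grayscale conversion therefore preserves the designed
minima structure exactly. Optional Gaussian pixel noise is added to the
intensity channel before color synthesis.

Default scene conditions (used by the test sweep and the acceptance
script): 1280×960 px, 14 single nuclei plus 3 overlapped pairs
(20 nuclei, ~18 % of objects overlapped), nucleus semi-axes 12–20 px,
noise σ alternating between 0 and 1.5 gray levels. These mirror a
moderately populated field of view at the working resolution of a
down-sized 2560×1920 acquisition.

What the generator does **not** emulate: stain variability and
illumination gradients, mucus/blood-cell distractors, nuclei touching
the cytoplasm border, chromatin texture inside nuclei, and overlaps of
more than two nuclei. Passing the synthetic sweep therefore
demonstrates the internal consistency of the pipeline — that the
implemented stages recover exactly the structures they model — not
clinical-grade performance; on real samples the segmentation stage is
the known weak point and can be bypassed entirely by supplying
human-drawn masks (`detect_overlaps(image, mask = ...)`, the
semi-automated mode).

## Evaluation

Mask agreement uses the Tanimoto (Jaccard) coefficient
`Nc / (Na + Nb + Nc)`; detections are matched to ground-truth objects
greedily by decreasing Tanimoto, one-to-one, and an object counts as
*located* at Tanimoto ≥ 0.5 (`min_iou`, configurable — the matching
rule is this package's choice). An overlapped pair merges into a single
connected dark object, which is what the boundary stage can recover, so
matching operates on merged ground-truth objects; classification is
scored on matched regions with *overlapped* as the positive class.
Per-feature discriminability uses the independent two-sample
signal-to-noise score `|m₁ − m₂| / sqrt(v₁/n₁ + v₂/n₂)`.

Validation sizes: the packaged test sweep and `scripts/acceptance.R`
both use ten seeded scenes at the conditions above (170 objects per
sweep). On these the pipeline locates every object, with mean mask
Tanimoto ≈ 0.89 and F1 = 1.0 for both clustering back-ends; fuzzy and
hard calls agree on every region. These figures are recomputed, not
asserted, on every run.

## Known limitations

* Separating the constituent nuclei inside a detected overlapped
  region (interior border delineation) is out of scope by design.
* The edge stage assumes nucleus/cytoplasm contrast dominates all other
  gradients; faint nuclei below the 0.4 normalized threshold are lost.
  The threshold, the hysteresis ratio and the smoothing σ are exposed
  for adaptation.
* The thinned contour sits up to ~3 px inside the true boundary before
  the one-pixel region dilation compensates; masks of very small nuclei
  (area near `min_nucleus_area`) remain biased.
* Label masks are written as 16-bit TIFF (the installed PNG writer is
  8-bit only); readers accept both TIFF and 16-bit PNG.
* Clusters are exactly two; scenes containing *only* overlapped or
  *only* single regions will still be split into two groups, and calls
  should then be read with the centroid audit (`model$centroids_raw`).
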