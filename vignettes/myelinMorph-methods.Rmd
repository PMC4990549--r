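---
title: "Segmenting axon and myelin in nerve cross-sections: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting axon and myelin in nerve cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelinMorph)
```

## The problem and its assumptions

A myelinated nerve fiber seen in cross-section is an approximately
annular structure: a lipid-rich myelin sheath wrapped around an axonal
lumen. In the contrast convention this package works in, the lumen is
*darker* than the sheath, and the inter-fiber background sits between
the two (optical and electron microscopy of stained tissue, and CARS
microscopy, can all be brought into this convention, by intensity
inversion if necessary). The quantities of biological interest are
per-fiber: the axon equivalent diameter, the fiber (axon + sheath)
equivalent diameter, their ratio (the **g-ratio**, physiologically
around 0.6–0.8), the sheath thickness, and densities and distributions
of these quantities per anatomical region.

The pipeline rests on three structural assumptions:

1. lumens are *basins* of the intensity field, separated from the
   background by the bright sheath wall;
2. each sheath is a closed, roughly convex annulus around its lumen,
   with approximately homogeneous thickness;
3. fibers do not interpenetrate — apparent myelin overlap indicates a
   segmentation conflict, not biology.

## Axon detection: extended minima

Candidates are the extended minima of the image: the regional minima
of the H-minima transform, computed as grayscale reconstruction by
erosion of $f + h$ over $f$ with 8-connectivity. A basin survives
exactly when its depth relative to the lowest escape barrier exceeds
$h$. Two thresholds are used and their binary masks OR-ed: a small
$h_1$ keeps small axons whose lumen-to-sheath contrast is weak, while
a larger $h_2$ gives fuller markers for large axons at the price of
flooding shallow basins. Defaults are $h_1 = 0.15$, $h_2 = 0.30$ on
the [0, 1] intensity scale; on equalized real images the useful range
is roughly 0.1–0.4, and both are exposed as the primary tuning knobs.

Intensities are quantized to 256 levels before reconstruction. This
makes the fixed point of the iterative reconstruction exact and
platform-independent, and matches the 8-bit provenance of most
microscopy exports. Two consequences are documented in the tests: a
constant image is a single plateau (raised by $h$, whole-plateau
minimum), and a ramp shallower than $h$ yields one *connected*
minimum region rather than a single pixel.

The cleanup chain after thresholding — remove isolated pixels, fill
isolated holes, 3×3 closing, H-break, 3×3 opening, border clearing —
uses the smallest non-trivial structuring element (3×3 square) so that
fibers on the 1-px scale are not erased. "H-break" deletes the
bridging center of an H-shaped 3×3 configuration (both orientations),
the standard reading of removing H-connected pixels. Cleanup is
applied *after* the OR of the two threshold masks; applying it before
would only remove structure the OR could not restore.

## Features and discrimination

Shape features are computed per labeled object: circularity
$4\pi A/P^2$ with $P$ the length of the traced outer-contour polygon
(a pixel-edge count would bias circularity low for disks — a 10×10
square then has $P = 36$ and circularity 0.970, and digital disks land
near 1.0); solidity with the convex area counted as pixels whose
centers fall in the convex hull of the object's pixel centers, which
keeps solidity ≤ 1 and equal to 1 for convex objects within ±0.02;
ellipticity as the minor/major axis ratio of the second-central-moment
ellipse (each pixel contributing a unit-square moment, so single
pixels are well-defined); and the equivalent diameter
$\text{px}\cdot\sqrt{4A/\pi}$. Intensity features use a neighborhood
defined as the dilation of the object by a disk of radius 2 px (center
distance ≤ 2) minus the object — the ring only, so `contrast =
neighborhood mean − object mean` is a pure boundary-contrast measure.

Prior screening keeps objects with area ≥ `minSize` (µm²), solidity
and ellipticity at or above their thresholds (inclusive, matching how
slider values are reported as kept boundaries). Defaults (0.2 µm²,
0.6, 0.3) are deliberately permissive: their job is to remove debris
below the smallest plausible myelinated axon (~0.8–1 µm lumen) and
grossly ragged inter-fiber shapes, leaving the discriminant to do the
finer work.

The discriminant is a two-class Gaussian classifier — linear (pooled
covariance) or quadratic (per-class) — scoring by log-likelihood
ratio. Eight features enter by default: the four shape features plus
object mean, object SD, neighborhood SD and contrast. The neighborhood
*mean* is excluded since it is exactly contrast + object mean;
including all three would make the covariance singular on clean data.
A ridge term of $10^{-6}\,\mathrm{tr}(\Sigma)/d$ on the diagonal
guarantees invertibility on small training crops. Priors default to
equal: the class balance of a hand-corrected training crop carries no
information about the full image. The ROC is swept over every distinct
score; the default operating point minimizes the Euclidean distance to
(sensitivity, specificity) = (1, 1), with maximal-sensitivity and
maximal-specificity rules available.

## Myelin segmentation: coupled circular paths in polar coordinates

The sheath around each accepted candidate is found in polar
coordinates centered on the candidate centroid. The image is sampled
bilinearly on a grid of `nAngles` angles (default 72, i.e. 5°
resolution) and radii up to `rmaxFactor` (default 3) times the
candidate equivalent radius. The radial sampling pitch defaults to one
pixel (`nRadii = ceil(rMax/pixelSize)`): boundary localization cannot
be better than the radial pitch, so sampling coarser than the pixel
grid (e.g. tying `nRadii` to the candidate diameter alone, which at
`rmaxFactor = 3` gives a 1.5 px pitch) needlessly quantizes the
boundary; one-per-pixel adds negligible cost.

A radial Sobel derivative (angular axis wrapping circularly, radial
axis replicating) is positive where intensity increases outward. With
dark lumen, bright sheath and intermediate background, the inner
border is the strongest *outward-increasing* transition and the outer
border the strongest *outward-decreasing* one. The outer border is
found first as the circularly closed path minimizing the summed signed
gradient — one radius per angle, consecutive radii (including the
wrap-around pair) differing by at most `maxStep` (default 1) — solved
exactly by dynamic programming, once per admissible starting radius,
keeping the best closed path. The inner border is the subsequent
maximal path constrained strictly inside the outer one. Cost ties
resolve toward smaller radii, so degenerate flat grids give the
constant path at the smallest admissible radius — a deterministic,
testable convention. An outer path pinned at the smallest radius is
treated as a failure (`outer_at_min`) rather than silently producing a
degenerate ring.

The published description of this stage invokes a double active
contour with constraints; the energy itself is unspecified. Here the
same constraints are realized by a deterministic construction:
circular moving-average smoothing of both radius sequences (window 5
angles ≈ 25°, enough to suppress single-angle gradient noise without
rounding genuine ellipticity), a thickness-homogeneity repair (angles
whose thickness deviates from the median by more than `thicknessTol` =
50% have the *inner* radius reset to outer − median thickness; the
outer border, a high-contrast myelin/background edge, is the more
reliable of the two), and a g-ratio clamp: the implied g (area-based)
is clamped into [0.4, 1] by scaling the inner border uniformly,
iterating against the rasterized masks so the bound holds for the
reported, mask-derived g-ratio, not merely the continuous radii. A
ring that is non-annular after repair is dropped with a reason code.

Conflict cleaning then rejects any fiber whose myelin mask shares
strictly more than 50% of its area with another fiber's myelin.
Overlap is evaluated against the original (pre-rejection) mask set in
ascending id order, which makes the outcome independent of processing
order.

## Morphometrics

The record list stores, per fiber, the axon and myelin pixel masks,
areas in px and µm², the centroid, and diameters from equivalent
circles of the axon mask and the (axon ∪ myelin) mask. The g-ratio is
the ratio of these equivalent diameters — an area-based definition
that remains stable for non-circular fibers — and myelin thickness is
half the diameter difference. The thickness definition is therefore
the equivalent-diameter difference, not a mean radial thickness; for
markedly elliptical fibers the two differ, and the choice is flagged
here deliberately: it keeps `thickness` consistent with the stored
diameter fields.

## Full-image processing

Blocks of `blockSize` px (default 512) advance with stride
`round(blockSize·(1 − overlap))` (default overlap 0.2); the last
window clamps to the image edge. Overlap zones are split at their
midpoints into disjoint *cores* that tile the image; a fiber belongs
to the block whose core holds its centroid. This de-duplicates
stitching exactly whenever half the overlap exceeds the largest fiber
radius — with the default `rmaxFactor`, fibers up to
`blockSize·overlap/3` px in axon diameter are stitched identically to
a single-pass run, which the tests verify to the pixel. Histogram
equalization, when enabled, is computed per block; for strict
blocked-vs-single-pass equality it should be disabled (phantom
parameter sets disable all pre-processing since phantoms are already
in convention). Conflict cleaning operates within blocks; a conflict
spanning a core boundary between two fibers in different cores is not
re-examined across blocks — a documented limitation, immaterial when
fibers do not overlap (the phantom regime) and minor in practice
because conflicts are local.

Fibers whose *mask* (not centroid) enters the band within `edgeMargin`
= 2 µm of the full-image border are discarded: the rule exists to
prevent measuring incomplete fibers, and a fiber is incomplete as soon
as any part of it could extend beyond the frame. The pixel distance of
the band is measured from pixel centers, with the first row/column at
distance zero.

## The phantom: what it emulates, and what it does not

The generator renders fibers as two concentric (optionally mildly
elliptical, area-preserving) disks — outer at myelin intensity, inner
at lumen intensity — on an intermediate background, plus solid bright
distractor disks, Gaussian blur, and clipped i.i.d. Gaussian noise.
Default study conditions: 1024² px fields, 100 fibers, axon diameters
from a gamma distribution (shape 3, scale 0.7; mean 2.1 µm —
representative of small-mammal spinal cord) truncated to [1, 4] µm so
fibers remain well inside the field of view and block cores, g-ratios
uniform on [0.6, 0.8], outline clearance ≥ 1 µm, border clearance
3 µm (placing complete fibers clear of the edge-discard band).
Modality presets vary what makes each contrast hard: OM (0.1 µm/px,
blur σ = 1.5 px — boundary smear), SEM (0.08 µm/px, noise σ = 0.10 —
grain), CARS (0.2 µm/px, lumen within 0.03 of background — weak
lumen/background separation). All randomness flows from one seed in a
fixed consumption order, so generation is bit-reproducible.

What the phantom does *not* emulate: intracellular texture
(mitochondria, neurotubules), stain artifacts and intensity
inhomogeneity, partial or split sheaths, and touching or deformed
fibers. Passing the phantom suites therefore demonstrates the
correctness of the geometry, constraints, stitching and statistics
under the stated contrast model — not segmentation quality on real
tissue, which depends on contrast and resolution and requires
per-dataset parameter tuning on a cropped region.

Problem sizes in the test and acceptance suites were chosen so the
whole suite runs comfortably on a single CPU: oracle comparisons use
200 random 8×8 images (extended minima) and 200 random ≤ 5×4 polar
grids (exhaustive path enumeration); end-to-end phantom recovery and
blocked-vs-single-pass stitching run at the full 1024²/100-fiber study
conditions; constraint measurements use 20 annuli (g-ratio bound),
10 000-px ring pairs with exactly counted overlaps (conflict
threshold), and 7 fibers at graded border clearances with integer-pixel
outer radii, so that clearance is measured exactly on the pixel grid
(edge margin).

## Numerical conventions and degenerate inputs

* Images are matrices with row = y, col = x; points are (x, y) px;
  masks are linear indices. File I/O transposes accordingly.
* 256-level quantization before reconstruction (see above); `h` on
  the [0, 1] scale is rounded to the nearest level.
* RGB loads average the channels unweighted — stain-agnostic, with no
  claim about perceptual luminance.
* Objects of < 3 pixels get degenerate-flagged features with a
  pixel-edge perimeter fallback; single pixels have SD 0 and
  ellipticity 1.
* An object filling the whole image has an empty neighborhood: flagged,
  contrast 0.
* Percentiles (Dice summaries, etc.) use linear interpolation between
  order statistics (R's default type 7), stated so summaries are
  reproducible elsewhere.
* Centroid-based validation matches a test object to the reference
  object containing its rounded centroid; each reference object keeps
  the closest such test centroid (ties: lower id). The reverse
  direction (reference centroid inside test object) is deliberately
  not used; the convention is fixed and documented.

## Known limitations

* The polar boundary model assumes star-convex sheaths about the
  candidate centroid; strongly non-convex or C-shaped sheaths are
  repaired toward an annulus or dropped.
* The thickness-homogeneity constraint intentionally suppresses real
  focal thickness variation (e.g. local decompaction) beyond ±50% of
  the median.
* Conflict cleaning across block boundaries is not performed (see
  above).
* Deconvolution is accepted in the parameter schema for compatibility
  but is a no-op; no deconvolution method is implemented.
* Global (not adaptive) histogram equalization is implemented; images
  with strong illumination gradients may need external flattening
  first.
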