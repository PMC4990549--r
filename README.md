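# myelinMorph

Automatic axon and myelin segmentation, and per-fiber morphometry, for
2D cross-sectional microscopy of nervous tissue (optical, scanning
electron, or CARS contrast). The package is aimed at researchers who
need per-fiber measurements — axon diameter distributions, myelin
g-ratios, sheath thickness, fiber densities per anatomical region —
from large histology sections containing thousands to millions of
myelinated fibers, where manual delineation is impractical and
irreproducible.

## Method

The pipeline assumes the working contrast convention **axon (lumen) <
background < myelin**; an inversion step in pre-processing handles
images acquired with the opposite polarity.

1. **Pre-processing** — intensity inversion, 3×3 mean filtering, and
   global 256-bin histogram equalization, with the pixel size (µm/px)
   attached to the image (optionally calibrated from a scale bar).
2. **Axon detection** — candidate lumens are the *extended minima* of
   the intensity field: the regional minima of the H-minima transform,
   which suppresses all minima of depth < *h* via morphological
   reconstruction by erosion of *f + h* over *f*. Two depth thresholds
   (h₁, h₂) are OR-ed — the small one catches small, low-contrast
   axons, the large one the big ones. A morphological cleanup chain
   (speck removal, hole filling, closing, H-break, opening, border
   clearing) yields an 8-connected label map.
3. **Discrimination** — per-object shape features (circularity
   4πA/P², solidity A/convex-area, ellipticity, equivalent diameter
   √(4A/π)·px) and intensity features (object and neighborhood
   mean/SD, contrast) feed inclusive prior thresholds and, optionally,
   a linear or quadratic Gaussian discriminant. The operating point is
   picked on the ROC curve, by default the point of minimal Euclidean
   distance to the ideal corner (sensitivity = specificity = 1).
4. **Myelin segmentation** — each accepted axon's neighborhood is
   unwrapped to polar coordinates; radial Sobel gradients are computed;
   the outer sheath border is the circularly closed minimal-cost path
   (strongest outward-decreasing gradient) and the inner border the
   subsequent maximal path constrained inside it, both found exactly
   by dynamic programming over angle with a per-step radial bound.
   Constraints enforce homogeneous sheath thickness around the
   circumference and a g-ratio in [0.4, 1]. Fibers whose myelin
   overlaps another fiber's myelin by more than 50% of their own sheath
   area are rejected.
5. **Morphometrics** — the *axon list*: per fiber, the pixel masks,
   areas (px and µm²), centroid, equivalent diameters of axon and
   fiber, g-ratio d_axon/d_fiber, and thickness (d_fiber − d_axon)/2,
   exportable as CSV and as metric-colored label images.
6. **Full images** — processed in overlapping blocks (default 20%
   overlap) and stitched by disjoint-core ownership; fibers within
   2 µm of the image border are discarded as potentially incomplete.
7. **ROI statistics & validation** — affine landmark registration of
   ROI/atlas masks, per-ROI counts, moments, densities and diameter
   histograms; detection quality against a reference segmentation via
   centroid matching (sensitivity TP/(TP+FN), precision TP/(TP+FP))
   and per-object Dice 2a/(2a+b+c) with 10th/50th/90th percentiles.

A synthetic phantom generator renders nerve-section images (bright
annuli around dark lumens, with blur, noise, distractors and presets
mimicking the OM/SEM/CARS contrast regimes) together with exact
ground-truth geometry, so every stage is testable against known truth.

## Worked example

```r
library(myelinMorph)

spec    <- phantomPreset("OM", imageSize = 512L, nFibers = 25L,
                         noiseSigma = 0.03, seed = 42)
phantom <- generatePhantom(spec)
params  <- phantomSegParameters(spec)
fibers  <- segmentFullImage(phantom@image, params)
fibers
#> AxonList: 25 myelinated fiber(s), 512 x 512 px image, 0.1 um/px
#>   axon diameter: 0.90-3.59 um (median 1.93)
#>   g-ratio: 0.518-0.772 (median 0.653)

head(as.data.frame(fibers)[, c("axonId", "axonEquivDiameter",
                               "fiberEquivDiameter", "gRatio")], 3)
#>   axonId axonEquivDiameter fiberEquivDiameter gRatio
#> 1      1             2.081              2.962  0.702
#> 2      2             3.040              5.013  0.606
#> 3      3             2.605              4.155  0.627

report <- validateSegmentation(renderLabelMap(fibers, "id", "axon"),
                               phantom@axonLabels)
sprintf("sensitivity %.3f, precision %.3f, median Dice %.3f",
        report$sensitivity, report$precision, median(report$dice))
#> "sensitivity 1.000, precision 1.000, median Dice 0.965"
```

The three `axonEquivDiameter` values are the equivalent-circle
diameters of the recovered lumens in µm; `gRatio` is the ratio of axon
to fiber diameter (physiologically ~0.6–0.8); the validation line says
every planted fiber was found (no misses, no false detections) and
that the median per-fiber mask agreement with the generated ground
truth is Dice 0.965.

For real images: load with `loadImage(path, pixelSize)`, tune
parameters on a cropped region (`segmentImage`), persist them with
`writeSegParameters()`, and apply them to the full image with
`segmentFullImage()`. A sample parameter file for an optical-microscopy
sample at 0.25 µm/px ships in
`inst/extdata/segparams_om_sample.json`, and a thin command-line
wrapper in `inst/scripts/myelinmorph-cli.R` exposes `segment`,
`validate`, `phantom` and `params-init` subcommands.

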