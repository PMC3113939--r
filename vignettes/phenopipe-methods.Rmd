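---
title: "Methods: colour segmentation and phenotype measurement in phenopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colour segmentation and phenotype measurement in phenopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopipe)
```

## The problem

Automated greenhouse platforms photograph hundreds of potted plants (here
modelled on barley screening) at regular intervals, in two orthogonal
views: a top view and a side view.  Besides the plant, every image contains
structured scenery — soil, the pot carrier, support cages and sticks, and a
conveyor belt — some of it close in colour to plant tissue.  The analysis
task is to isolate the plant pixels in each image and reduce them to a
small set of phenotypic parameters: height and width (side view), x-extent,
y-extent and maximum diameter (top view), and the projected shoot area in
both views, a 2-D proxy for shoot biomass that tracks growth and treatment
response over the screening period.

## The classifier

phenopipe uses multidimensional histogram thresholding (MHT): a purely
per-pixel classifier with no neighbourhood context.  An object class is a
colour volume — one closed `[lo, hi]` interval on *each* of the six channels
of the combined RGB and HSV colour spaces, tested conjunctively.  A class
may carry several such volumes (a disjunction), which lets one class cover
disjoint colour modes such as light and dark green foliage.

Two colour spaces are used together deliberately.  RGB channels are highly
correlated: a change in illumination moves all three at once.  HSV
separates chromatic identity (hue) from purity (saturation) and brightness
(value), but hue is numerically unstable at low saturation, so HSV alone is
not reliable either; the conjunction over both spaces is the practical
compromise.  Package-wide conventions: hue in degrees `[0, 360)` (not the
8-bit scale of some imaging tools — configuration files may declare
`h_unit: byte`, rescaled by 360/256 on input); achromatic pixels are
assigned `h = 0` so threshold tests on them are deterministic.  Hue
intervals may wrap around 0/360.

Colour alone cannot separate objects whose colours genuinely overlap.  Each
non-plant class is therefore bound to a calibrated image *region*
(rectangle or circle, in 0-based pixel coordinates) and can only claim
pixels inside it.  Regions scale automatically about their centroid with a
single configurable factor, compensating camera-zoom changes; scaled
regions may leave the image and are clipped at rasterization, where a pixel
belongs to a region iff its integer centre coordinate satisfies the closed
region inequality.  The `"plant"` class is never region-bound — leaves can
reach anywhere in the frame.

Ambiguity between classes is resolved by declaration order: the first class
whose region contains the pixel and whose colour volume contains its colour
wins; unmatched pixels get the reserved `"background"` label.  The original
method leaves conflict resolution unspecified; declaration order was chosen
because it is explicit, reproducible, and lets the user express priorities
(the unrestricted `"plant"` class is conventionally declared last among the
colour classes).  For configurations whose volumes are pairwise disjoint the
order is provably irrelevant, and `validateConfig()` flags classes that
share a region with intersecting volumes.

## Calibration

Thresholds are estimated from labelled pixel samples by `deriveProfile()`:
per channel, the `trim` and `1 - trim` sample quantiles, with `trim = 0`
(the default) giving exact extrema so that every calibration pixel
satisfies its own profile.  Positive `trim` buys robustness against
mislabelled pixels at the cost of coverage.  Hue is handled circularly: the
reference cut is placed in the largest circular gap of the sample hues,
which minimises the circular span of the derived interval and produces a
narrow wrapping interval for hue samples straddling 0/360 rather than the
whole circle.  How the original interactive calibration turned user gestures
into thresholds is not documented; per-channel trimmed extrema are the
simplest estimator consistent with a min/max threshold per channel.

A complete per-view calibration (`ViewConfig`) holds the ordered classes,
the named regions (five in the default top view: soil, carrier, cages,
sticks, conveyor belt; three in the side view: carrier, cages, sticks), the
region scaling factor, the millimetre-per-pixel factor, and the opening
radius.  It is persisted as a versioned YAML document
(`schema: 1`); packaged defaults live in `inst/extdata/`.

## Morphological cleanup

Colour similarity and sensor noise leave isolated misclassified pixels in
the extracted plant mask.  The mask is refined by morphological opening —
erosion then dilation with the same square `(2r + 1)`-pixel structuring
element, default `r = 1`.  Opening removes foreground features smaller than
the element and preserves larger shapes exactly; it is anti-extensive
(never adds pixels) and idempotent.  The square element and the border
convention (outside-image counts as background during erosion) are fixed
choices; the method description names opening but neither the element shape
nor the border rule, and both must be pinned for bit-exact verification
against the neighbourhood-scan oracle used in the tests.

The plant colour calibration deliberately covers green foliage tones only.
Yellow and brown plant parts (senescent leaf tips) resemble soil and cage
colours; admitting them to the plant volume would misclassify scenery as
plant.  This is an emergent property of the packaged default profile, not a
hard-coded rule — a user whose scene permits it can calibrate a wider plant
class — and it biases measurements slightly low on senescing plants, the
documented trade-off.

## Measurements

All measurements are taken on the opened mask:

* extents use the inclusive pixel-count convention
  (`max − min + 1`; a single pixel is one pixel wide);
* "diameter" is interpreted as the maximum Feret diameter — the largest
  Euclidean distance between any two plant-pixel centres — computed via the
  convex hull plus pairwise distances over hull vertices, and verified in
  tests against the full O(n²) pairwise oracle.  The original parameter is
  not defined formally; max Feret is the standard reading for an irregular
  rosette;
* projected shoot area is the plant pixel count times the squared
  millimetre-per-pixel factor;
* empty masks yield zeroed records with an explicit `empty_flag`.

Group growth curves (`summarizeGroups()`) report the arithmetic mean and
the standard error of the projected shoot area per group and timepoint,
using the sample (n−1) standard deviation — the standard convention for
"± SE of n replicates"; single-replicate cells report SE 0 with a warning
rather than `NA`, and empty cells are omitted with a warning.

## Batch runs and reproducibility

`runBatch()` processes jobs in input order, never aborts on a single bad
image (failures are collected and reported alongside the table), and writes
CSV with fixed column order and fixed formatting — lengths to 2 decimal
places, areas to 1 — so an identical batch re-run reproduces the file byte
for byte.  No timestamps enter the table body; provenance is the source
path, the configuration identifier and the package version.

## What the synthetic scenes do and do not show

No reference image corpus is available, so validation rests on a
first-class synthetic generator.  A scene is a backdrop, the region-bound
objects painted into their regions, optional distractor blobs, and the
plant (solid canopy rectangle or stylised stem in side view, disk or
ellipse in top view), with optional uniform integer noise per channel,
clipped to the 8-bit range.  Ground truth — label map, bounding box, pixel
count, maximum diameter — is computed at generation time by independent
brute-force scans that share no code with the measurement module.

The companion configuration derives each class's profile by exhaustively
enumerating the RGB cube of half-width `noise + 2` around the class's
palette colour and taking exact extrema.  Every perturbation of a palette
colour by at most the declared noise amplitude is a member of that
enumeration, hence inside the derived volume *by construction*: "safe"
noise provably cannot change a label, which is what makes exact
equality-to-ground-truth a legitimate test.  The default palette keeps
class colours at least 40 intensity units apart in some RGB channel, so the
derived volumes stay disjoint at the default noise amplitude (8).

Adversarial scenes place blobs of plant-like colour (inside the plant
colour volume) into a non-plant region and widen the owning region-bound
class with a second profile covering that colour; because the owning class
precedes `"plant"`, the region restriction — not colour — decides those
pixels.  This isolates exactly the mechanism that region binding exists
for.

What the generator does *not* emulate: gradients and shadows (noise is
i.i.d. uniform, not spatially structured), reflexions, specular highlights,
perspective distortion, overlapping leaves with translucency, and the
yellow/brown senescent tissue discussed above.  Passing the synthetic suite
therefore demonstrates the correctness of the pipeline's mechanics —
classification, region logic, morphology, measurement, bookkeeping — not
segmentation quality on real greenhouse imagery, which depends on
calibration quality in the way the validation literature for this class of
pipelines describes (systematic slight underestimation of extents, outliers
from reflexions on pots and screws).

## Study conditions used by the validation suite

The acceptance checks run at desk scale, sized as the package's own study
conditions: segmentation oracle equivalence on ten 64×64 random images
under randomized valid configurations; morphology and measurement oracles
on one hundred 32×32 and 40×40 random masks (radii 1–2, up to 200 plant
pixels); parameter recovery on fifty 120×150 side-view scenes (noise-free:
exact; noise 8 with opening radius 1: within 2 px-equivalents in length and
2 % in area); a 96-image batch (8 plants × 6 days × 2 views at 160×200)
checked for row bookkeeping and byte-identical CSV re-runs; and
mean-recovery of a 4-group × 3-day growth design (8 replicates, CV 0.15,
90×120 scenes) within 3·SE in ≥ 95 % of the 1200 group/day cells across
100 seeds — the coverage expected from sampling theory for n = 8
replicates.  Log-normal areas model multiplicative growth variability
between plants; means (700–2000 px²) keep canopies comfortably inside the
frame.

## Numerical and degenerate-input choices

* Profile containment and classification use closed intervals everywhere, so
  calibration pixels at the extrema are always covered.
* For `trim = 0` the hue bounds are exact sample hues; no modular
  arithmetic touches them (a shift-and-unshift formulation can perturb a
  bound by a few ulps and exclude a boundary sample).
* Empty masks: extents and diameter 0, empty annotation draws only the
  scale bar; single-pixel masks have diameter 0.
* Ties in the Feret pair and in the largest hue gap resolve to the first
  occurrence — deterministic given identical input.
* Scaled regions may extend beyond the image and are clipped at
  rasterization; a region fully outside yields an empty mask, not an error.
* The scale bar is `round(scaleBarMm / mmPerPx)` pixels (default 100 mm),
  anchored 10 px from the bottom-right corner, clipped with a warning if it
  exceeds the image width.

## Known limitations

* Per-pixel classification cannot use texture or shape; scenes whose
  classes genuinely overlap in colour *and* share regions are ambiguous and
  resolved only by declaration order (flagged by `validateConfig()`).
* Opening removes genuine plant structures thinner than the structuring
  element (thin leaf tips at radius ≥ 1), part of the known downward bias.
* The calibration estimator assumes labelled samples from a roughly
  axis-aligned colour volume; strongly curved colour distributions are
  covered loosely by a single box and are better served by several
  profiles per class.
* Only visible-spectrum RGB input is supported; near-infrared and
  ultra-violet channels of multi-spectral platforms are out of scope, as is
  any database, conveyor or RFID integration.
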