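---
title: "Sexing melon fly pupae by machine vision: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sexing melon fly pupae by machine vision: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupavision)
```

## The problem

The sterile insect technique against the melon fly *Zeugodacus cucurbitae*
releases sterilized males only, so males must be sorted out before release —
ideally at the pupal stage, where handling does no harm. Male pupae carry a
diagnostic external feature: a comb of *pectinate setae* on the backplane of
the tail segments. The long setae of that comb (0.05–0.18 mm) occur in males
only and become visible roughly two days before eclosion; a second group of
short setae (0.02–0.05 mm) occurs in both sexes and is useless for sexing.
`pupavision` implements a complete image pipeline that finds this feature in
daily stereomicroscope images of single pupae and calls each pupa male
(setae detected) or not, then scores the calls against eclosion outcomes.

## Pipeline model

Each raw image is a three-channel TIFF with pixel values on a
$[0, 65520]$ scale, holding exactly one pupa. The stages are:

1. **Range normalization.** Pixels are mapped monotonically to $[0, 255]$ by
   $p \mapsto \lfloor p \cdot 255/65520 + 0.5\rfloor$ (round half up; the
   rounding rule is fixed so results are reproducible).
2. **Saturation channel.** The image is converted to HSV;
   $S = 255\,(\max - \min)/\max$ per pixel. The pupal cuticle is strongly
   colored while the background is nearly gray, so $S$ gives the best
   foreground/background contrast and is the channel segmented.
3. **Segmentation.** Otsu's threshold (256-bin histogram, between-class
   variance, ties broken toward the smaller threshold) binarizes $S$;
   foreground is the bright (saturated) side. Interior holes are filled
   (background components not connected to the border), the mask is opened
   with a Euclidean disk of radius 5 px to remove speckle and protrusions,
   and the largest 8-connected component is kept as the body.
4. **Pose normalization.** The minimum-area enclosing ellipse of the mask is
   fitted on its boundary points; the rectangle circumscribing that ellipse
   (same center and angle, sides $2a \times 2b$) defines the body pose. The
   image is rotated about the rectangle center by minus its angle (bilinear
   interpolation, zero padding), cropped to the now axis-aligned rectangle
   (half-open integer bounds) and resized to exactly $2800 \times 1300$.
   The resize is deliberately anisotropic; the per-axis calibration
   $\mu_x = \mu \cdot w_\text{crop}/2800$, $\mu_y = \mu \cdot
   h_\text{crop}/1300$ (micrometres per standardized pixel) compensates, so
   physical lengths are preserved.
5. **Grid screening.** The standard frame is tiled into a $5\times 5$ grid
   of $560 \times 260$ cells, numbered row-major from the top left. Four
   features are computed per cell: mean gray, standard deviation, the dark
   fraction (pixels below $\max(0, \text{mean} - 2\,\text{sd})$), and
   co-occurrence contrast (horizontal offset 1 px, 32 gray levels). For each
   cell the cohort-mean absolute change of each feature between day $d$ and
   day 1 is z-scored per feature, and cells are ranked by the maximum z over
   days and features. In a cohort containing males, the tail cell — cell 17
   under our orientation convention — ranks first.
6. **Setae detection and calling.** In the tail cell, dark objects are
   pixels below $\text{mean} - 2\,\text{sd}$. Each 8-connected component is
   measured along its principal axis (projection extent plus one pixel); a
   component is a *stripe* if it is large ($\ge$ 10 px), elongated
   (length/width $\ge$ 3), roughly perpendicular to the body axis
   ($\pm 30^\circ$ of vertical), and dark ($\ge$ 25 gray levels below the
   cell mean). Stripe length in mm projects the per-axis calibration onto
   the stripe's axis. A day is called `male_setae_detected` if at least one
   stripe is *strictly* longer than 0.05 mm; a pupa is positive if any day
   is positive (latch rule — no day gating, since detection runs
   retrospectively over the whole series).
7. **Evaluation.** Calls are cross-tabulated against eclosion outcomes
   (female / male / unfledged). Accuracies: males among emerged
   setae-positive pupae; females among emerged setae-negative pupae; correct
   calls among all emerged pupae. Unfledged pupae are excluded from every
   denominator — they carry no sex label — and percentages are rounded half
   up to one decimal.

## Conventions and open design choices

Several details are not forced by the problem and were fixed once:

* **Coordinates.** Pixel arrays are `c(width, height[, 3])` (first index =
  x), 0-based coordinates at pixel centers, y pointing down, angles in
  $(-90^\circ, 90^\circ]$ from the x axis, rectangles half-open.
* **Head/tail orientation.** Straightening cannot distinguish head from
  tail. The package's convention is *tail left, setae band below the
  midline*, which is exactly what places the setae in grid cell 17 (row 4,
  column 2); the generator renders pupae in that canonical orientation, and
  because the daily rotations stay inside $(-90^\circ, 90^\circ)$,
  straightening restores it deterministically. For real data where the
  orientation is unknown, the mirrored candidate cell
  (`mirror_cell_index()`, cell 19) should be screened as well; the ranking
  produced by `temporal_screen()` covers all cells, so both candidates are
  always visible in its output.
* **Boundary at 0.05 mm.** The long- and short-setae length ranges share
  the endpoint 0.05 mm; the call uses *strictly greater*, assigning the
  boundary to "short". This is conservative for the female-error direction.
* **`min_long_count = 1`.** Although a male comb carries 16–20 long setae,
  recognition rests on presence, not count; the count is kept as a
  diagnostic (`long_stripe_count`).
* **Otsu side.** Foreground is always the high-saturation side, locked by
  the physics of the scene (colored cuticle on gray background).
* **"Opening" is opening.** The morphological step is erosion followed by
  dilation with the same Euclidean disk, implemented exactly via two
  distance transforms (the image exterior counts as background for the
  erosion). Opening is idempotent and anti-extensive; both properties are
  unit-tested against a brute-force sliding-window oracle.
* **Minimum enclosing ellipse.** Computed on the mask's boundary points
  (which contain the convex hull) with the Titterington minimum-volume
  algorithm, then rescaled minimally so every boundary point is inside —
  the approximate solver alone can leave points marginally outside.
* **Stripe robustness filters.** Bilinear upsampling to the fixed frame
  correlates sensor noise into short vertical smears; two filters beyond
  the geometric ones keep them out: a minimum component area (10 px) and a
  minimum mean darkness (25 gray levels below the cell mean). Real setae
  are roughly 100 gray levels darker than the cuticle, an order of
  magnitude beyond both chance dips and the filter value, so the filters
  cost no sensitivity.
* **Hue.** Hue is computed but unused; byte-scale hue (0–255) is the
  default representation, with an unquantized degree scale available
  (`hue_scale = "degrees"`) under which HSV→RGB back-conversion is exact to
  one gray level.

## The synthetic cohort: what it emulates, and what it does not

No pupal photographs are distributed, so the package carries a seeded
generator that emulates the statistical structure of the acquisition: one
pupa per image, one image per day for 11 days, eclosion on day 12, a bright
saturated elliptical body (semi-axes ~320 × 125 px, ±5 % per-pupa jitter) at
a fresh uniform rotation in $\pm 45^\circ$ each day on a low-saturation
background, additive Gaussian read noise (sd 800 on the 16-bit scale, about
3 gray levels after normalization), and anti-aliased capsule stripes for the
setae. Males receive 16–20 long setae (lengths uniform on 0.05–0.18 mm) plus
6–12 short setae (0.02–0.05 mm); females receive the short group only;
setae appear exactly on the two days before eclosion; pupae marked
unfledged die early and never develop setae. A raw-image calibration of
8 µm/px puts the rendered body at a realistic ~5 × 2 mm. Sex and unfledged
status are allocated by rounding half up on the configured fractions
(defaults 0.5 male, 0.096 unfledged), the latter independent of sex. Every
image is a pure function of `(configuration, seed)`, so cohorts are
bit-reproducible.

The generator is deliberately *not* photorealistic: no cuticle
microtexture, no illumination gradients, no segmentation-hostile clutter,
no optical effect of the day-8 water-immersion treatment (carried only as
the `water_treated_day8` metadata flag), and setae rendered as clean
capsules rather than tapering bristles. Consequently, passing the
end-to-end tests demonstrates that the pipeline's geometry, calibration and
decision logic are correct under the stated image model — not that the
stated accuracy would be achieved on arbitrary microscope data.

## Numerical choices and degenerate inputs

* Round half up everywhere a value is quantized (normalization, reported
  percentages, cohort allocation).
* Otsu on a constant image, an empty mask after opening, fewer than five
  boundary points, collinear boundaries, and zero-area rectangles raise
  typed errors (`pv_degenerate_histogram`, `pv_segmentation_failure`,
  `pv_degenerate_geometry`); the batch runner quarantines the affected
  image with its reason and continues.
* Ties in the temporal-screen ranking break toward the lower cell index;
  with no temporal change at all, every score is exactly 0.
* The empty cohort is a valid input (empty outputs, no error); an
  all-unfledged cohort reports `NA` accuracies with a warning.

## Problem sizes used by the test-suite and acceptance script

Unit tests run on a reduced generator configuration (560 × 360 px canvas,
200 × 80 px body, 12 µm/px) that preserves the physical stripe scale while
keeping the suite fast. The acceptance checks run the full default geometry:
a 100-pupa cohort (50 male, 10 % unfledged, default noise) through the
complete pipeline, which is the package's reference experiment for the
zero-female-false-positive and ≥95 % male-sensitivity claims, plus a
100-image Otsu oracle comparison and the pose-normalization residual check
(≤1° after straightening). `scripts/acceptance.R` recomputes the same
quantities from scratch with a caller-supplied seed.

## Known limitations

* Real acquisitions with the tail pointing right would need the mirrored
  tail cell; the package exposes but does not auto-select it.
* The dark threshold `mean − 2·sd` assumes the tail cell is dominated by
  cuticle; a cell that is mostly background (badly failed segmentation)
  would distort it. Segmentation failures are caught earlier in practice.
* Physical lengths assume the raw calibration (µm/px) supplied by the
  user or manifest is correct; the pipeline propagates but cannot verify it.
* Accuracy estimates carry no uncertainty quantification; the evaluation
  mirrors a single-cohort contingency table.
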