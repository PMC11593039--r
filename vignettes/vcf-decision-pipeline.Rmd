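---
title: "Vertebral morphometry and decision-level fusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebral morphometry and decision-level fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfusion)
```

## The measurement model

A vertebral body on a mid-sagittal slice is summarised by three column
heights: anterior `Ha`, middle `Hm`, and posterior `Hp`. The posterior
column sits next to the pedicle, is rarely involved in compression, and
serves as the within-vertebra reference. The height loss ratio

$$\mathrm{HLR} = \max\left(0,\; 1 - \frac{\min(H_a, H_m)}{H_p}\right)$$

is graded semiquantitatively: normal (< 20%), mild (20–25%), moderate
(25–40%), severe (≥ 40%), with every interval closed on its lower edge.
Two properties of the ratio matter for what follows. It is scale-invariant
— multiplying all three heights by a constant leaves it unchanged — so the
same *relative* deformity scores identically on small and large bodies,
while the same *absolute* loss does not (5 mm off 15 mm is 33%; off 25 mm,
20%). And it is blind to uniform collapse: a crush deformity reduces `Hp`
together with `Ha` and `Hm`, so the ratio stays near zero however severe
the fracture. Both behaviours are exercised explicitly by the phantom
tests.

### Height measurement

`measure_heights()` places three vertical bands at fractions 0.15 / 0.50 /
0.85 of the anterior–posterior (AP) extent, each with half-width 5% of the
extent, and reports the vertical foreground extent inside each band
((max − min) of pixel-centre coordinates plus one row spacing). Extent
rather than centroid-line thickness was chosen because it is robust to
endplate concavity and matches how calipers are placed clinically. The
band positions are configurable; nothing in the grading convention pins
down where the "three points" sit, and 0.15/0.50/0.85 keeps the anterior
and posterior bands clear of the rounded corners of a typical body.

Masks are axis-aligned before measurement, in millimetre coordinates so
anisotropic spacing is respected. Alignment is two-stage by default
(`align = "endplate"`):

1. a principal-component rotation of the foreground pixel cloud resolves
   the gross orientation (long axis taken as AP);
2. a line fit to the inferior boundary (lowest foreground point per AP
   bin, over the central 80% of the extent to avoid the rounded corners)
   levels the inferior endplate.

The second stage exists because plain PCA is *deformity-sensitive*: a
strong wedge tilts the principal axes along the sloped superior endplate,
which rotates the reference posterior column away from vertical and can
understate the height loss by a large margin (in phantom experiments, up
to 0.20 of HLR at a target of 0.49). The inferior endplate is intact by
definition of the deformity model, so levelling it restores the intended
measurement frame; with it, the worst-case recovery error over 200 random
wedge/biconcave phantoms is below 0.02 of HLR at 1 mm spacing. `"pca"`
and `"none"` remain available for comparison and for pre-aligned rasters.

The anterior side cannot be inferred from a binary mask alone, so
`anterior = "left"` is a convention (configurable); only the labelling of
the three bands depends on it. 3D label volumes are reduced to each
vertebra's mid-sagittal slice, chosen as the slice maximising foreground
area.

### Positivity threshold

`hlr_positive` defaults to HLR ≥ 0.25, the diagnostic threshold for a
clinically reportable VCF; 0.20 — the onset of the mild grade — ships as
the alternative preset, since screening applications may prefer to count
mild deformities. Both are one keyword apart throughout the package.

## The contour band

The detector-facing representation of a vertebra is its contour band:
`dilate(mask) AND NOT mask`. The structuring element is the elementary
3×3 square (or 4-connected diamond) iterated `radius_px` times; dilation
clips at the image border. The defaults (square, radius 1) are a
convention, documented rather than asserted, since nothing downstream
depends on the band width. Two set identities are guaranteed and
property-tested: the band is disjoint from the mask, and
`|band| = |dilate(mask)| − |mask|`.

## Detector output and matching

Detections arrive as YOLO-style text rows `class cx cy w h conf` with
centre and size normalized to the image. Each detection is attributed to
the vertebra whose reference box it overlaps most, if the IoU reaches
`iou_min = 0.25`; the per-vertebra confidence is the maximum over
attributed boxes and 0 when none match. The low default reflects that the
question is *presence per vertebra*, not localization quality: a box that
covers most of a vertebral body but is loosely sized should still count.
Across slices of a 3D case the per-vertebra confidence is the maximum — a
fracture visible on any sagittal slice counts.

## The four fusion strategies

With HLR threshold $\tau$ (default 0.25), detector operating threshold
$\theta_{pos}$ (default 0.5) and negation threshold $\theta_{neg}$:

| Method | Call rule | Fused score (for ROC) |
|---|---|---|
| 1, HLR only | HLR ≥ τ | HLR |
| 2, detector only | conf ≥ θ_pos | conf |
| 3, positive override | HLR ≥ τ **or** conf ≥ θ_pos | 1 if HLR ≥ τ, else conf |
| 4, negative override | HLR ≥ τ **and** conf ≥ θ_neg | conf if HLR ≥ τ, else 0 |

All comparisons use `≥`, consistent with the closed lower bounds of the
grading intervals. Method 3's positives are a superset of Method 1's, so
its sensitivity can only rise and its specificity only fall; Method 4's
positives are a subset, so its specificity can only rise. Both orderings
are asserted on every simulated cohort in the test suite.

The two detector thresholds are deliberately distinct. Published
per-method confusion matrices for this family of pipelines show the
negative override retaining more true positives than the detector-only
method finds (e.g. 89 vs 82 of 99), which is only possible if the
negation criterion is weaker than the detector's operating point. The
default $\theta_{neg} = 10^{-6}$ encodes "any detection box at all":
a vertebra with no matched box carries confidence exactly 0 and is
negated, while any emitted box survives. Setting $\theta_{neg} = 0$
disables the override (everything passes a `≥ 0` test), and
$\theta_{pos} = 1$ disables Method 3's override when confidences stay
below 1; both limits collapse onto Method 1 and are tested as such. For
ROC analysis the fused scores sweep the detector threshold with τ held
fixed.

## Evaluation metrics

Pixel-overlap metrics follow the standard Dice decomposition:
DSC = 2TP/(2TP+FP+FN), FND = 2FN/(2TP+FP+FN), FPD = 2FP/(2TP+FP+FN),
IoU = TP/(TP+FP+FN). The identities DSC = F1,
DSC = 1 − (FND+FPD)/2 and IoU = DSC/(2−DSC) hold exactly and are
property-tested on random mask pairs. Two empty masks are an error, not a
silent 1.0.

Classification metrics come with 95% binomial intervals, Clopper–Pearson
exact by default; the accuracy interval treats correct calls as binomial
over the whole cohort. The Wilson score interval is available as
`ci_method = "wilson"` because published reports mix conventions across
metrics within one table — exact intervals for sensitivity/specificity,
Wilson for accuracy/precision is a combination that several statistics
packages produce by default. Zero-denominator metrics are reported as
`NA` with `NA` bounds rather than failing the whole report.

AUROC is the normalized Mann–Whitney statistic — the probability that a
random positive outscores a random negative, ties at half credit — which
equals trapezoidal integration of the ROC curve; both routes are computed
and cross-checked in the tests, along with an exhaustive pair-counting
oracle and an external reference implementation. Percentages print at two
decimals with round-half-even.

## The phantom: what it emulates, and what it does not

`generate_spine()` renders a stack of vertebral bodies as a mid-sagittal
label mask. Each body is a rounded rectangle whose superior endplate
profile is remapped by the deformity plan (the inferior endplate stays
fixed, keeping `Hp` the reference): wedge scales the anterior column to
(1−t)·Hp with the middle at (1−t/2)·Hp, biconcave scales the middle,
crush scales all three. The profile is flat under each of the three
measurement bands with smooth cosine ramps between, so the rendered
column heights equal the plan exactly up to pixel quantisation — and the
truth table records the *rendered* (quantised) heights, so measurement
error can be judged against exactly what is in the raster. Corner
rounding (default 8% of body width) stays clear of the bands.
Defaults — 22 mm posterior height, 35 mm body width, 4 mm disc gap, 1 mm
isotropic spacing — are typical adult lumbar dimensions on
sagittal-reformatted CT.

`cohort_spec()` samples a cohort: heights uniform on 18–28 mm, fracture
positions shuffled, deformity classes wedge/biconcave/crush at
0.6/0.25/0.15 (wedge-dominant, as in osteoporotic series), target HLR
uniform on 0.26–0.55 so planned fractures sit above the diagnostic
threshold. The default size, 99 fractured against 882 normal vertebrae,
matches the composition of the clinical test cohort this pipeline family
is evaluated on.

The mock detector draws each vertebra's confidence from a logit-normal
distribution whose location is set by closed-form quantile matching:
$\mu = \sigma\,\Phi^{-1}(\text{target})$ puts the requested mass above
the 0.5 operating point (sensitivity target for fractured, 1 − specificity
for normal vertebrae). Boxes are the truth boxes with 1% jitter, emitted
only when the confidence reaches `emit_floor = 0.02` — so weak calls still
produce a box (Method 4's "any detection" criterion sees them) while the
clearest negatives produce none. Targets of 1.0 clamp the quantile at ±8
standard deviations, giving complete separation in any finite cohort.

What the phantom does **not** emulate: intensity texture beyond a flat
two-level rendering (the low-density augmentation operates on that
substrate), segmentation errors (masks are exact, so normal vertebrae
never show spurious height loss — phantom specificity for the HLR method
is optimistic), spine curvature, rib/vessel clutter, and real detector
failure modes (confidences are exchangeable given the label, with no
difficulty structure). Passing tests therefore demonstrate that the
*decision machinery* is correct and that the documented HLR blind spots
exist, not that any particular clinical operating point is attainable.

## Numerical choices and problem sizes

* Heights are measured on pixel centres; the `+1 row spacing` term makes
  an n-pixel column measure n·spacing, so axis-aligned rectangles are
  exact.
* The endplate fit uses unweighted least squares on per-bin minima; with
  ≤ 2 usable bins the stage is skipped.
* Ties at every threshold resolve by `≥`.
* Grading uses half-open intervals `[lower, upper)` over [0, 1); HLR
  exactly 1 is rejected as non-physical input.
* Test problem sizes: contour and overlap properties on ~15×15 random
  masks; AUROC oracle on up to 200 scores across 100 seeds; mock-detector
  calibration on a 1000-vertebra cohort (binomial SE ≈ 0.01); fusion
  orderings on fifty 1000-vertebra cohorts; morphometry recovery on 200
  deformed vertebrae; the acceptance script runs one 981-vertebra cohort.

## Known limitations

* Anterior/posterior orientation is a convention, not inferred; masks
  rotated by more than ~45° can swap the long axis.
* The endplate-levelling fit assumes an intact inferior endplate; severe
  biconcave inferior involvement would bias it.
* Per-vertebra masks are assumed connected after largest-component
  selection; fragmented segmentations are measured on the largest piece.
* The fused score for Method 3 saturates at 1 for all HLR-positives, so
  its ROC resolution above the HLR operating point comes from the
  detector only.
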