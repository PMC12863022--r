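---
title: "SinusDx: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SinusDx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SinusDx)
```

## The problem and the model

Endoscopic diagnosis of sinusitis rests on seeing purulent mucus in the
middle meatus (MM), the drainage channel lateral to the middle turbinate
(MT). Two sources of inter-operator variability dominate: identifying
the turbinate landmarks, and deciding whether mucus actually occupies
the MM — which is frequently not directly visible because of anatomical
positioning and occlusion. `SinusDx` assumes the landmark-detection
problem is solved upstream (any multi-class instance detector producing
MT / inferior-turbinate (IT) / mucus masks with confidences) and makes
the remaining clinical inference explicit, deterministic and auditable:
a geometric MM construction followed by an intersection-over-union (IoU)
decision rule.

The model is intentionally two-dimensional and box-based. The MM region
is represented as an axis-aligned bounding box derived from the
turbinate masks, and the decision statistic is box IoU between that
region (or the MT box, for the fallback pathway) and each detected mucus
box. Polygon masks enter only through their extremes (medial edge,
vertical extent, tight bounding box). This mirrors how the decision
thresholds were calibrated and keeps every step reproducible from
annotation files alone; it deliberately does not model depth,
three-dimensional anatomy, or mucus appearance.

## Coordinates and geometric conventions

Coordinates are continuous, 0-based, origin at the top-left, y downward
— the convention of both COCO and YOLO annotation formats. Boxes are
closed intervals with area $(x_2-x_1)(y_2-y_1)$; degenerate boxes are
constructor errors, so IoU never sees a zero-area operand. Mask edges
are read from polygon vertices, not rasterized contours: this is
deterministic and resolution-independent, and rasterization is kept as a
test oracle only (pixel-counting IoU agrees with the analytic box IoU to
1e-6 over 1,000 random pairs in the test suite). Multi-part masks use
min/max over all parts — a conservative tight cover. The one place
rasterization is used in production code is mask-to-mask IoU for
segmentation evaluation ([iouMasks()]), where pixel-center sampling is
the field's standard convention.

## The middle-meatus construction

With both turbinates detected (primary construction), the region spans
vertically from $\max(y_{MTtop}-\Delta y, 0)$ down to $y_{ITtop}$, and
horizontally $\Delta x$ from the MT's medial edge. When the IT is
undetected, the fallback keeps the same top, bounds the bottom at
$y_{MTbottom} + 0.5\,h_{MT}$, and narrows the span to $\Delta x_{safe}$.

Parameters (all in `algorithmConfig()`):

| parameter | default | unit | role |
|---|---|---|---|
| `deltaX` | 50 | px | horizontal extent, primary construction |
| `deltaY` | 20 | px | superior margin above the MT top |
| `deltaXSafe` | 30 | px | horizontal extent, fallback (conservative) |
| `iouThreshold` | 0.3 | – | diagnostic cut, strict `>` |
| `confidenceThreshold` | 0.3 | – | detection filter, inclusive `>=` |

The offsets are empirical constants calibrated on manually annotated MM
regions at the native 1024 × 768 px resolution; for other frame sizes
they are scaled by `width/1024` (horizontal) and `height/768`
(vertical), since a fixed pixel offset has no meaning across
resolutions.

Design points that were genuinely open, and the choices made:

- **Horizontal direction.** The construction pins one vertical edge of
  the MM box to the MT's medial mask edge and extends the span from
  there; only the fallback's horizontal rule is written out explicitly
  (`x_start = x_MTedge − Δx_safe`, `x_end = x_MTedge`, i.e. toward
  decreasing x in a right cavity). The primary construction follows the
  same direction, and a left cavity mirrors it by laterality symmetry.
  Anatomically the MM lies lateral to the MT, so one could argue for the
  opposite direction; the implemented default follows the one
  construction that is stated exactly, and the whole rule is
  mirror-equivariant either way (a property the test suite enforces).
- **Fallback vertical rule.** Two statements of the fallback's lower
  bound coexist: the strict MT extent, and the extended
  $y_{MTbottom} + 0.5\,h_{MT}$ clause attached to the primary equation
  for the IT-undetected case. The extended clause is the more specific
  formula and is the default (`fallbackYRule = "extended"`); the strict
  variant stays available (`"strict_mt"`).
- **Instance selection.** With several MT (or IT) instances in a frame,
  the highest-confidence one is used (ties: larger mask area, then first
  occurrence) — the detector's own ranking is the only ordering
  available.
- **Failure is a state, not an error.** No MT, a zero span, a clamped
  box that degenerates, or an IT top above the region top (inconsistent
  anatomy) all produce `method = "failed"`; downstream logic treats this
  as "no MM evidence", never as an exception.

## The diagnostic rule

Both pathway IoUs are always computed and reported: the MM–mucus IoU
(when localization succeeded) and the MT–mucus IoU (when an MT was
detected). A pathway fires when its IoU strictly exceeds
`iouThreshold`. Two gating semantics are implemented because the
validation accounting implies both were in play: the reported
trigger-usage tally counts frames satisfying both criteria, which
requires evaluating both pathways per frame, while the fallback pathway
is described as activating when MM localization fails. The default
`callMode = "permissive"` calls a frame positive when either pathway
fires (and records all that fired); `"strict"` makes the MT–mucus
pathway eligible only on MM failure. With multiple mucus instances the
maximum single-instance IoU is used (the formula is written for one
mucus box); `mucusAggregation = "union"` instead scores the union of
all mucus boxes, which rewards fragmented deposits.

Frames with no retained detections — or no MT, or no mucus — are
negative calls: absence of landmarks or mucus is the no-evidence state,
and such frames stay in the denominator of evaluation metrics.

## Evaluation stack

- **Classification metrics** are plain confusion-matrix arithmetic in
  percent; any ratio with a zero denominator is reported as `NA`, never
  silently 0. F1 is always the harmonic mean of the returned precision
  and sensitivity (an invariant the tests scan for).
- **Segmentation metrics** match predictions to same-class ground truth
  per frame, greedily in descending confidence, one ground-truth
  instance per match, at mask IoU ≥ 0.5 — the COCO-style convention,
  adopted because the matching rule behind the reported per-class table
  is not spelled out.
- **ROC analysis** varies the IoU threshold; the per-frame score is the
  larger of the two pathway IoUs (the quantity the rule thresholds),
  with the same strict `>` comparison. The AUC is the trapezoid over the
  empirical curve at all distinct scores, which equals the
  concordance-pair (Mann–Whitney) estimator with ties counted ½ — the
  suite checks agreement to 1e-9, and against `pROC` where available.
  The 95% CI is a seeded nonparametric percentile bootstrap over frames
  (2,000 resamples; degenerate single-class resamples are dropped).
- **Pathway statistics** derive per-pathway precision, false-positive
  share and usage share from the (laterality × ground truth) firing
  tally.
- **Agreement** reports mean pairwise F1 against a reference rater and
  Fleiss κ from the standard per-item formulation. Both are small,
  self-contained computations implemented here because no installed
  dependency provides them.
- Percentages print at one decimal with half-up rounding
  (`roundHalfUp()`), matching the convention of clinical tables —
  base R's `round()` is banker's rounding and would disagree on .x5
  values.

## What the synthetic scenes do and do not show

`generateScene()` builds annotation-level scenes, not images: one convex
8–12-vertex MT polygon (vertically elongated, medial side per
laterality), an IT polygon below it (absent with probability
`pItAbsent` = 0.25, standing in for obstruction / image-quality /
out-of-frame cases), and 0–2 mucus polygons. Placement defines ground
truth *by construction against the same MM rule the pipeline applies*:
`in_mm` inscribes mucus in the derived MM box (box IoU ≥ 0.5 before
jitter), `on_mt` deposits it on the MT (fallback-pathway positive), and
`remote` keeps it at least 2·Δx away from both MM region and MT box
(negative). Defaults (`pMucus` = 0.9, placement weights
0.35/0.47/0.18) give an expected 74% positive rate, matching the
positive prevalence of the clinical validation cohort; vertex jitter of
3 px emulates annotation noise; per-class confidence means
(0.88/0.85/0.78) echo the relative segmentation difficulty of the three
classes. Scenes are deterministic in `(seed, index)` and a `mirror`
switch produces exact left/right reflections for equivariance tests.

Because ground truth is constructed against the rule itself, noiseless
scenes (`jitterSd = 0`, zero confidence spread) are recovered at 100%
sensitivity and specificity, and ROC analysis on default-noise scenes
yields AUC ≈ 1. That is the point — it validates the implementation's
internal consistency, threshold behavior and mirror symmetry — but it
says nothing about clinical accuracy: real detector errors (missed
turbinates, hallucinated mucus, laterality misclassification),
anatomical variation, and borderline IoU values near 0.3 are exactly
what the synthetic generator does not model. Clinical performance
figures can only come from expert-labeled endoscopic images.

## Problem sizes and numerical choices

The test suite runs at deliberately modest sizes — 1,000 random box
pairs for the IoU oracle, 200 noiseless scenes for the recovery check,
101-point threshold grids, 50-frame ROC instances, 2,000 bootstrap
resamples — chosen so the full suite completes in well under a minute
per file while leaving every property with enough instances to fail
loudly. Geometry comparisons use 1e-6 (pixel coordinates), AUC-estimator
equivalence 1e-9, and rasterized mask IoU a ~2% tolerance reflecting
pixel-center sampling. The strict-inequality behavior at exactly
IoU = 0.3 is pinned by a dedicated test.

## Known limitations

- The rule cannot distinguish purulent from non-purulent mucus; that
  discrimination must come from the upstream detector or future work.
- Box-based IoU under-weights thin or curved mucus deposits relative to
  mask-based overlap; the stage-3 formulas are box formulas, so boxes
  are implemented, with mask IoU available for evaluation.
- The geometric construction presumes roughly upright endoscope
  orientation; strong rotation breaks the "medial edge" heuristic.
- Laterality is required metadata and is never inferred; mislabelled
  laterality flips the construction and silently degrades calls.
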