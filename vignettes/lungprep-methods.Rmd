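---
title: "lungprep: methods, parameters and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lungprep: methods, parameters and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungprep)
```

## The problem

Lung fields on an axial CT slice are air-filled and therefore dark, set
inside a bright soft-tissue body, which itself sits in a dark air
background, often with a bright, elongated patient table near the bottom
edge. Classical intensity-based segmentation of this scene is a solved
problem *on clean slices*, and that is exactly the role this package plays:
a deterministic, auditable preparation stage that produces candidate lung
masks and vets them (and any externally provided ground-truth masks) before
they are used to train a learning-based segmenter. It deliberately rejects
what it cannot segment confidently rather than guessing; on heterogeneous
clinical data a substantial rejection rate is the expected behavior, not a
failure mode.

## The segmentation model and its assumptions

`segment_slice()` assumes: (i) one patient body, the largest dense object
in the slice; (ii) lungs darker than the surrounding tissue, so a global
two-class threshold separates air from tissue; (iii) a roughly bimodal
intensity histogram after normalization. The chain is:

1. **Min–max normalization** to [0, 1]. Per-image, not per-dataset: input
   bit depths and window settings vary and are unknown, so each slice is
   normalized on its own range. A constant slice maps to all zeros with a
   logged warning instead of an error, to keep batch runs alive.
2. **Percentile contrast stretch** (defaults: 1st and 99th percentile to 0
   and 1, clipped). The reference procedure names a contrast-enhancement
   step but not its method; a percentile linear stretch was chosen over
   adaptive histogram equalization because it is deterministic, testable in
   closed form, and cannot create new local structure. Whether enhancement
   runs before or after thresholding was also open; it runs before, so the
   threshold sees the corrected histogram.
3. **Otsu binarization** on a 256-bin histogram of [0, 1] (the 8-bit
   convention). Every bin edge is evaluated; ties break toward the smaller
   threshold so the result is reproducible. The returned threshold is a bin
   edge `k/bins`, which makes `value < threshold` reproduce the class split
   exactly. Lung candidates are pixels *below* the threshold — binarization
   polarity follows the physics (air is dark).
4. **Body identification**: largest 8-connected component of the *dense*
   (above-threshold) mask, interior holes filled. This includes the lungs
   inside the body and discards the table, which is dense but smaller and
   disconnected. Candidates are then AND-ed with the body.
5. **Morphological refinement**: closing with a 5×5 square element iterated
   3 times, then hole filling, then removal of components under 0.1% of the
   image area. "Iterated three times" could mean three closings or three
   independent dilate/erode passes; three closings were chosen because
   closing is idempotent, making the iteration count harmless where the
   simpler reading would make it meaningless. The order closing → fill →
   remove-small is fixed; the ingredients were specified but not their
   order, and this order lets closing merge fragments *before* the area
   cutoff is applied.

Connectivity is 8 for foreground and 4 for background (the standard duality
pair), and out-of-image pixels are background for both dilation and erosion
(so border foreground erodes). With that clipped-domain convention the
erosion/dilation pair is not a formal adjunction near the border; closing
idempotence is still observed empirically on thousands of random masks (and
asserted in the test suite), but erosion/complement duality genuinely fails
at the border and is therefore tested on padded masks.

## Acceptance filters

Three rules vet each candidate mask, all evaluated (no short-circuit) so a
rejection records every violated rule:

| Rule | Default | Rationale |
|---|---|---|
| border contact | margin 1 px | foreground on the edge row/column means cropped lungs |
| object count | 1–2 | two lungs; a fused pair is one object and is accepted |
| per-object area | ≥ 5% of image | smaller blobs are artifacts, not lung fields |
| aspect ratio | bbox width/height in [0.2, 3] | a table bar is ~10; upright lung fields are ~0.5 |

Decisions taken where the reference was silent: the 5% rule is inclusive at
exactly 5% ("at least"); it applies *per object*, since the filter
"examines each object"; empty masks are rejected through the object-count
rule (an empty mask cannot be a lung field); the aspect bounds [0.2, 3] are
an engineering choice — no anatomical norm was quantified — and are
exposed in `filter_config()`. The border margin of 1 px means strict edge
contact; pixels within `k` pixels of the edge are flagged when the margin
is raised to `k`.

A structural consequence worth stating: a mask produced by
`segment_slice()` can *never* touch the image border. Final-mask foreground
is always inside the filled body, border pixels of the body are dense
tissue, and hole filling only fills background regions *not* connected to
the border — so a lung cut open by the image edge is excluded from the body
rather than kept as border-touching foreground. The border filter therefore
matters for externally produced masks (its real use case: vetting provided
annotations), and the filter tests run on ground-truth masks directly.

## Quality control battery

Agreement metrics are the standard overlap family (IoU, Dice, IoU loss,
precision, recall, specificity). Degenerate cases are fixed by convention
and logged: both masks empty gives IoU = Dice = 1; any 0/0 ratio is 1.

Two statistics need no reference mask:

* **PLC** (percentage of lung coverage), in percent to match its
  "< 5% or > 50%" exclusion phrasing.
* **Asymmetry** `|A_L − A_R| / max(A_L, A_R)` with the split at the image
  vertical midline (first `floor(W/2)` columns). The reference names a
  symmetry analysis and its 50% flag threshold but no formula; this
  relative difference makes "exceeding 50%" a natural cutoff, and the fixed
  midline (rather than the mask centroid) keeps the statistic deterministic
  and sensitive to one-sided masks. It assumes a roughly centered patient.

The **weighted quality score** is `w₁·IoU + w₂·(1 − asymmetry) + w₃·[PLC in
range]` with equal default weights. Only "integrating IoU, symmetry and
PLC" was specified; a linear form with a binary in-range PLC term was
chosen because PLC has no meaningful gradient inside its plausibility band.
Weights are configurable and validated to sum to 1. Without a reference
mask the IoU term uses a placeholder of 1 (logged), so the score then
reflects plausibility only.

Flags fire at IoU < 0.85, asymmetry > 0.5, PLC outside [5, 50] — the
thresholds are inclusive on the acceptable side (IoU = 0.85 is acceptable,
asymmetry = 0.5 is acceptable, PLC = 5 and 50 are acceptable).

## The phantom generator: what it emulates, and what it does not

`generate_phantom()` renders the stated world of the pipeline's
assumptions: background 0.05, body tissue 0.65, lung 0.15, table 0.75 (on
[0, 1] before quantization), a body ellipse of semi-axes (0.34·H, 0.39·W),
two lung ellipses of semi-axes (0.21·H, 0.115·W) offset ±0.185·W from the
midline, Gaussian noise (σ = 0.01 by default, on the [0, 1] scale), and
8-bit quantization. The intensity levels are configuration, not physics:
they were chosen once to give a clean bimodal histogram with the air/tissue
separation (~0.5 after contrast stretch) far larger than the default noise,
and they are not tuned per test. Two lungs of these axes cover ~15% of the
slice, inside the 5–50% PLC band, with a per-lung area (~7.6%) above the 5%
per-object cutoff and a bbox aspect (~0.55) inside the filter band.
Ground-truth masks are the exact pre-noise rasterizations
(center-of-pixel inclusion), so expected areas follow from ellipse
arithmetic.

Defects are geometric edits made *before* rendering, so each one perturbs
the image and the ground truth coherently: `BORDER_TOUCH` shifts the
anatomy up until the lungs cross the top edge; `EXTRA_OBJECT` adds a
lung-density disc of radius 0.03·W in the mediastinal corridor (area
~0.3% of the image — above the 0.1% small-object cutoff, below the 5%
filter; the radius keeps the corridor gap wider than the 4 px a 5×5
closing can bridge at any image size); `TINY_LUNGS` scales the lung
semi-axes to 45% (per-lung area ~1.5%); `MERGED_LUNGS` widens and
approaches the lungs until they fuse; `TABLE_ARTIFACT` draws a bar of
aspect ratio > 5 below the body, disjoint from it. Cohorts jitter the
geometry by a few percent within bounds that provably keep clean lungs
inside the body and inside every filter band, and each defect is injected
independently at its stated rate.

What the phantom does **not** emulate: lung texture (vessels, airways,
parenchymal gradients), pathology (consolidation, ground-glass opacity,
emphysematous destruction), patient rotation, partial fields of view,
windowing variation, or non-Gaussian reconstruction noise. A green phantom
test therefore establishes algorithmic correctness — each stage does what
its contract says on a scene satisfying the assumptions — not clinical
performance. On real data the pipeline is expected to reject heavily; that
is its design.

## Numerical and I/O conventions

* Pixels are row-major, origin top-left, 1-based in R; rows are the
  vertical (cranio-caudal in-slice) axis.
* Masks are 0/1 in memory, 0/255 uint8 on disk; decode threshold is
  value > 127. Round trips are bit-exact.
* PNG I/O uses the `png` package (8- and 16-bit reads; stored integer
  values are reconstructed from the bit depth). TIFF I/O is a built-in
  baseline codec (uncompressed grayscale 8/16-bit, both byte orders on
  read; little-endian single-strip on write) because no TIFF package is
  available in the target environment; it is cross-checked against an
  independent Python reader/writer in the test suite. Multi-channel input
  is averaged to grayscale with a logged warning rather than rejected.
* Filenames pair by extension-stripped stem; duplicate stems in one
  directory are an error (ambiguous key), unmatched reference masks are
  logged, and listings are sorted with radix ordering so results are
  locale-independent.
* All randomness (noise, cohort geometry, defect assignment) flows from
  explicit integer seeds; generation restores the caller's RNG state.

## Known limitations

* Strictly 2-D and per-slice; no volumetric connectivity or Hounsfield
  calibration (source conversion metadata is assumed unavailable).
* The global Otsu threshold assumes bimodality; slices dominated by one
  class (e.g. abdominal slices with no lung) produce junk candidates that
  the filters must catch.
* A lung touching the image border cannot be recovered by the pipeline (see
  the structural note above); such slices are rejected by the downstream
  object-count/area rules rather than segmented.
* The aspect-ratio band, symmetry statistic and quality-score form are
  principled stand-ins where the reference procedure named a concept but no
  formula; all are configurable.
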