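---
title: "Methods: automatic lung-nodule detection in chest CT slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic lung-nodule detection in chest CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungcad)
```

## The problem and the pipeline

A chest CT exam is a series of a few hundred axial slices; pulmonary nodules
appear on them as small, bright, roughly circular cross-sections inside the
dark lung parenchyma. The main confounders are blood vessels and bronchi:
cylindrical structures whose cross-sections look just like nodules on a
single slice. `lungcad` implements a fully automatic two-phase CAD pipeline
on 8-bit grayscale slices (PNG exports of DICOM series):

1. **Lung segmentation** (per slice): an intensity histogram with bin step
   $\kappa$ is scanned for its *second local minimum*; the intensity at the
   top of that bin, $\lambda$, marks the valley where the low-intensity peaks
   (black background, dark body rim, dark lung fields) end. Thresholding
   $I > \lambda$ removes those regions; the result is complemented
   ($\bar I = 255 - \hat I$), an Otsu threshold $\tau$ separates the bright
   chest wall from everything else, and the binary map $B = (\bar I > \tau)$
   is refined by connected components: the largest component (the bright
   outer region enclosing the lungs) is deleted, as are border-touching
   components and specks below `min_area`; interior holes are filled, the
   survivors dilated with a small disc, and the masked grayscale lungs are
   median-filtered with a $3\times3$ window.
2. **Nodule detection** (per exam): inside the lung mask, a second Otsu
   threshold separates the bright inner structures from the parenchyma. Each
   8-connected structure component that is large enough and round enough
   (isoperimetric circularity $4\pi A/P^2 \ge$ `circ_min`) seeds a
   region-growing step; the grown region is summarized by the feature vector
   $F_i = (\mu_i, me_i, mo_i, \sigma_i^2, \sigma_i, t_i)$ — mean, median,
   mode, population variance, standard deviation, and a binary *consistency*
   bit $t_i$ that is 1 iff a candidate center re-occurs within a matching
   radius in one of the $2k$ neighbouring slices. A linear SVM trained on
   labelled candidates separates nodules from vessels/bronchi.

Evaluation uses the standard detection battery: sensitivity, specificity,
precision, accuracy, $F_\beta$, the Matthews correlation coefficient, and the
burden rates FPI (false positives per image) and FPE (per exam).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `kappa` | 5 | intensity | histogram bin step for the $\lambda$ scan |
| `smooth_width` | 1 (off) | bins | optional moving average before the minima scan |
| `min_area` | 50 | px | smallest surviving lung-mask component |
| `dilation_radius` | 2 | px | disc radius of the mask dilation |
| `fill_holes` | TRUE | — | fill interior mask holes before dilating |
| `circ_min` | 0.6 | — | circularity gate for candidate seeds |
| `min_candidate_area` | 9 | px | smallest candidate component |
| `max_intensity_distance` | 0.18 | of [0,1] | region-growing similarity bound |
| `k` | 1 | slices | consistency half-window (window of size 3) |
| `match_radius` | max(3, d/2) | px | consistency matching tolerance |
| `consistency_mode` | "feature" | — | how $t_i$ enters classification |
| `beta` | 0.5 | — | F-score recall weight |
| `svm_cost` | 1 | — | linear-SVM regularization |

The operating point ($\kappa = 5$, growing distance 0.18, $k = 1$,
$3\times3$ median, $F_{0.5}$) is the pipeline's reported configuration; the
remaining defaults are this package's own choices, discussed below.

## Design choices in detail

**Second local minimum.** "Second local minimum" is ambiguous for plateaus
and noisy counts. The scan is deterministic: an interior bin is a minimum iff
its count is strictly below both neighbours; a flat run bounded by strictly
larger values is one minimum located at its centre bin; minima are ordered
from intensity 0 upward and $\lambda$ is the highest intensity contained in
the second one. Counts are scanned raw by default — the bin step $\kappa$
already aggregates away single-intensity noise, and raw counts keep the scan
exactly reproducible by a brute-force oracle; a centred moving average is
available via `smooth_width` for histograms with very ragged counts. When
fewer than two minima exist (degenerate or synthetic slices), $\lambda$ falls
back to the Otsu threshold of the raw slice and the choice is flagged in the
per-slice threshold log.

**Thresholding conventions.** Background removal keeps a pixel only when
$I > \lambda$ (strict), so a pixel exactly at $\lambda$ is removed. Otsu
maximizes the between-class variance of the split $\le t$ versus $> t$ over
all 256 candidates, breaking ties toward the smallest $t$; it optionally
restricts to a domain mask (used for the inner-structure threshold, which is
computed over lung pixels only).

**Mask refinement order and hole filling.** Components are labelled with
8-connectivity throughout (the common choice for binary foreground).
Deletion order: largest component first (on exact ties all tied components
go — at realistic sizes only wall/background components tie), then
border-touching components, then components under `min_area`. Bright inner
structures are *removed* by the complement thresholding and would leave holes
in the lung mask; since phase 2 must see those pixels, interior holes
(background regions not reachable from the image border) are filled before
the dilation. The dilation (disc, radius 2) then recovers a thin boundary
band, matching its stated purpose of re-including false negatives inside the
lungs; dilation alone cannot re-include a nodule interior, which is why hole
filling is on by default. The $3\times3$ median filter is applied to the
masked grayscale image, not to the binary mask.

**Circularity.** Candidate roundness is $4\pi A / P^2$ with $P$ the
chain-code length of the outer boundary (Moore tracing; axis steps count 1,
diagonal steps $\sqrt 2$), capped at 1. Digital discs of radius 5–50 score
above 0.85 under this perimeter; elongated bars score below the 0.6 gate once
the aspect ratio reaches about 5 (a $3\times40$ bar scores about 0.22). The
pixel-centre path slightly under-measures very thin shapes (a 2-pixel-wide
bar can score above 0.6), so in-plane vessels thinner than 3 px may pass the
gate — they are then rejected by the consistency feature, which is the
intended division of labour. The gate has no upper size bound, keeping the
detector size-invariant.

**Region growing.** Intensities are normalized to $[0,1]$ and a frontier
pixel is absorbed when it is within `max_intensity_distance` of the *running
region mean*. The frontier is a FIFO queue with neighbours visited in
row-major order, so the grown set is a deterministic function of the inputs.
Under a running mean, growing with a larger distance is not provably nested
in the smaller-distance result; nestedness is checked empirically on layered
fixtures rather than asserted as a theorem. Two seeds that grow to identical
pixel sets are reported once.

**Consistency feature.** The window of size $2k+1$ around slice $j$ contains
$j$ itself, so the search covers the $2k$ *neighbouring* slices; at stack
boundaries only existing slices are searched, and a single-slice exam yields
$t = 0$ everywhere. The matching tolerance defaults to half the candidate's
equivalent diameter, floored at 3 px, since no fixed tolerance is stated;
the boundary is inclusive. `consistency_mode` controls whether $t_i$ is a
sixth feature scored by the SVM (`"feature"`, the default, matching the
printed feature vector), a hard pre-filter that drops $t=0$ candidates
without scoring (`"filter"`, the narrative behaviour), or both.

**Classifier.** Features are standardized with training-set centre/scale
(zero-variance features get scale 1, since the raw features mix scales of
$[0,255]$ and $\{0,1\}$), then a linear-kernel SVM (libsvm via `e1071`,
cost 1) is fit. The decision function is stored as explicit weights and bias
— sign-anchored against the fitted model's own predictions, because libsvm
orients decision values by class appearance order — so persistence is plain
JSON and classification is exactly reproducible and order-invariant.

**Metric conventions.** Any metric with a zero denominator is reported as 0
and flagged rather than dropped; MCC returns 0 when any marginal sum is zero.
True negatives are ill-defined for a detection task at the image level, so TN
is counted over *classified candidates*: a candidate classified non-nodule
with no ground-truth centre within the matching radius. Detection-to-truth
matching is per slice, greedy nearest-first, one-to-one. $F_\beta$ is the
weighted harmonic mean of precision and recall and cannot exceed 1 for
valid precision/recall; no printed value above 1 is reproducible from the
formula.

## The phantom generator

Real chest CT cannot ship with the package, so every stage is exercised on a
seeded synthetic phantom that emulates the four-region structure of a
PNG-exported slice: black background (level 0), a dark-gray circular body rim
(60), a bright chest wall (235) carrying a few darker patches (170), and two
dark lung fields (50) shaped as mirrored ellipses with sinusoidal boundary
perturbation. Nodules are bright spheres (210): their cross-sections share
one in-plane centre across adjacent slices, with radius
$\sqrt{R^2 - (\Delta j \cdot dz)^2}$, drawn wherever it rounds to at least
2 px (sub-pixel spherical caps are neither drawn nor recorded as truth).
Vessels are bright oblique cylinders (200) whose cross-section centres drift
6 px per slice along a random direction — more than the default matching
radius, so they fail the consistency test by construction. Gaussian noise
(sd 3) is added and clipped.

The default study conditions are 320×320 slices, 9 slices per exam, 2
nodules (sphere radius 4–6 px) and 3 vessels (radius 2–4 px) per exam; the
recovery experiments train on 10 exams and test on 20, and segmentation
overlap is scored on 20 single-slice phantoms. These sizes keep the lungs at
a realistic ~40% of the thorax cross-section while every experiment remains
a desk-scale computation.

What the phantom does *not* emulate — and hence what passing tests do not
show about clinical data: Hounsfield calibration and scanner windowing,
juxta-pleural (wall-attached) nodules, ground-glass opacities, breathing or
motion artefacts, streak/Poisson noise, anatomy such as the trachea and
mediastinum, and the annotation variability of human readers. Published
performance numbers on clinical collections are not comparable to phantom
recovery rates.

## Numerical and degenerate-input conventions

* Degenerate DICOM intensity ranges (max = min) map to an all-zero slice;
  multi-frame and colour payloads are rejected rather than coerced.
* A constant slice, or one whose complemented image is constant, produces an
  empty mask with a warning — an exam may legitimately contain slices with
  no lung.
* Otsu on a constant domain is an error at the operation level; pipeline
  callers guard it and degrade to the empty-mask path.
* Mode ties take the smallest value; medians of even-sized regions average
  the two central order statistics; variance divides by the region size
  (population form).
* The region-growing similarity test uses a tolerance of $10^{-12}$ on the
  normalized scale so that exact-boundary pixels are absorbed platform-
  independently.

## Known limitations

* Strictly 2D phase-1 segmentation: no lung-lobe separation, left/right
  labelling, trachea removal, or 3D components.
* Juxta-vascular nodules fused with a vessel into one component are scored
  as a single shape; no splitting procedure is attempted.
* The DICOM reader covers single-frame grayscale Little Endian files only —
  enough for CT slice exports; compressed transfer syntaxes and sequences
  with undefined length are rejected.
* No FROC analysis or confidence intervals; the report type leaves room for
  both.
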