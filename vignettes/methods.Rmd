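---
title: "Methods: 3D feature-pyramid nodule detection with location-history false-positive reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D feature-pyramid nodule detection with location-history false-positive reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Computer-aided detection of pulmonary nodules in chest CT must satisfy two
competing demands: high sensitivity (missing a nodule is costly) and a low
false-positive rate (a reader cannot review dozens of spurious marks per
scan). `pulmo3d` implements a three-part pipeline that addresses both:

1. **Self-supervised backbone pre-training.** A rotation-prediction pretext
   task: each volume is rotated in the axial plane by 0, 90, 180 or 270
   degrees and a classifier must recover the angle. Solving this requires
   recognising the consistent orientation of thoracic anatomy, so the
   shared feature extractor learns spatial structure without any
   annotation.
2. **A 3D feature-pyramid detector.** Cubic sliding windows (96 voxels a
   side at full scale) pass through a five-stage 3D residual backbone
   (stage grids 96/48/24/12/6 cubed). Every pyramid output level fuses all
   four backbone stages C2–C5 — lateral 1×1×1 projections, transposed-
   convolution upsampling from coarser stages and max-pooling from finer
   ones — so each scale sees both high-resolution detail and semantic
   context. A 3×3×3 head plus two 1×1×1 sibling convolutions predict
   per-anchor confidence and cube offsets.
3. **Location-history false-positive reduction (HS2).** Nodules and
   vessels look alike in a single slice, but behave differently across
   slices: a sphere's cross-section grows and shrinks concentrically,
   a vessel's translates. The Location History Image (LHI) captures this:
   per pixel, when the absolute difference between consecutive slices
   exceeds a threshold the history resets to a ceiling `tau`, otherwise it
   decays by one. A small CNN over LHI patches relabels candidates as
   nodule or tissue.

Evaluation follows free-response ROC (FROC) methodology: sensitivity at
1/8, 1/4, 1/2, 1, 2, 4 and 8 false positives per scan, and their mean, the
Competition Performance Metric (CPM).

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| HU window | [-1200, 600] HU | linear map to [0, 255] gray; round-half-up, then clipped |
| target spacing | 1 mm | isotropic resampling (trilinear) |
| anchors | {3,5,10,15,20,25,30} voxels | cube sides; placed on P2–P5 by scale (<8 → P2, <16 → P3, <28 → P4, rest → P5) |
| IoU thresholds | 0.02 / 0.4 | below: negative; above: positive; between: ignored |
| score threshold | 0.1 | candidate selection, applied before NMS |
| NMS IoU | 0.1 | suppression threshold (unstated upstream; configurable) |
| window overlap | 32 voxels | at least the largest nodule, so no nodule is split by every window boundary |
| LHI `tau` | 10 | slice pairs in an 11-slice stack |
| LHI difference thresholds | 30 and 40 gray | two patch variants per candidate, used as augmentation |
| HS2 decision threshold | 0.5 | probability `>= 0.5` keeps the candidate (the boundary counts as nodule) |

## Design choices where the design was open

* **Rotation convention.** One 90-degree step maps pixel `(y, x)` to
  `(x, H-1-y)`. Handedness is not observable by the pretext task (the
  label set is closed under either convention); it is fixed for
  reproducibility and tested as an exact voxel permutation with period 4.
* **LHI initialisation and accumulation.** The history starts at zero
  before the first slice pair, "larger than a threshold" is strict `>`,
  and one LHI is accumulated over the whole 11-slice window; per-pair
  history images are a visualisation, not the classifier input. The
  48×48 resize happens *after* LHI computation because the difference
  thresholds are defined on raw gray levels.
* **Anchor-to-level mapping** follows receptive-field scale (see table).
  Ground-truth nodules are represented as cubes of side `d` for IoU
  purposes, matching the cubic anchor convention.
* **Positive supervision (force matching).** Cubic IoU is unforgiving
  between anchor scales: a 7-voxel nodule against the 5/10 anchor ladder
  peaks at IoU `(5/7)^3 = 0.36`, below the 0.4 positive threshold, even
  perfectly centred — such nodules would receive no positive anchor at
  all. On the training path each truth therefore also claims its
  best-overlapping anchor as positive (provided the overlap clears the
  negative threshold), the standard region-proposal fallback. The
  exported `assign_anchors()` applies the plain threshold rule unless
  `force_match = TRUE`.
* **Negative sampling.** Negatives are sampled at 3:1 against positives
  with a floor (default 32 positives' worth) so background is trained in
  sparse windows; half of the sample is taken from the currently
  highest-scoring background anchors (online hard-negative mining), half
  at random. Purely random sampling at this ratio leaves the vast
  majority of the ~70k background anchors per window unseen during a
  desk-scale run, which manifests as a wall of high-scoring false
  positives; the hard half concentrates training on exactly those. The
  classification loss is class-balanced (positives and negatives carry
  equal total weight, with the per-class denominator floored at 8 so a
  lone positive cannot dominate an update).
* **Normalisation and optimiser.** Every backbone and head convolution is
  followed by a per-sample instance normalisation (channel-wise over
  space) — the residual reference backbone is a normalised network, and
  batch statistics are unavailable when training one window at a time.
  The detector trains with Adam (learning rate 1e-3) by default; plain
  SGD with momentum is available by configuration. Training windows are
  additionally augmented by random axial 90-degree rotations, with truth
  cubes rotated in lockstep.
* **Box coding** is `(Δcentre)/side` plus `log(side ratio)`; decode ∘
  encode is the identity (tested to 1e-9).
* **Matching and FROC.** The hit criterion is centre distance strictly
  below the truth radius; extra hits on an already-hit truth are ignored.
  Sensitivity at an FP level is the best operating point with
  `FP/scan <= level` (step-function reading by default; a linear
  interpolation between adjacent operating points is available via
  `froc_sensitivities(..., interpolate = TRUE)`). Seven FP levels
  (1/8 … 8) are canonical. CPM is reported at 3 decimals.
* **Size strata** partition diameters as small `[3,5)`, medium `[5,10]`,
  large `(10,∞)` mm; the boundary diameters 5 and 10 are medium. Stratum
  sensitivities use stratum truths only, against the global FP rate.
* **HS2 head** is a 2-way softmax with cross-entropy; kernel sizes
  (5×5 convs, 2×2 pools) are fixed here since only channel widths are
  specified upstream. At inference the two threshold-variant patches are
  averaged; at training they are separate samples. Filtering *relabels*
  candidates (tissue candidates leave the positive set); raw scores and
  coordinates are never altered.
* **Lung masking** is the classical pipeline (Gaussian smoothing,
  low-density thresholding, 3D connected components keeping interior
  components, morphological closing); masking is optional and detection
  runs without it. Masking zeroes non-lung voxels; cropping is a flag.

## The phantom generator

Every stage is exercised on seeded synthetic phantoms: an elliptic
soft-tissue body in air, two dark lung ellipsoids, a bright posterior
spine rod, spherical nodules (diameters constrained to the 3–30 mm range
of screening practice) rendered with a one-voxel soft edge, tubular
vessels whose cross-section drifts laterally slice to slice, and i.i.d.
Gaussian noise clipped to [0, 255] (sd 8 gray levels by default — small
against the default contrasts of 70–80, as in contrast-conspicuous
screening nodules). The nodule cross-section follows the circular-cap
profile `r(s) = sqrt(max(0, R^2 - (s - s0)^2))`, exactly how a sphere
intersects consecutive slices, so the two LHI patterns the classifier
relies on are faithfully present. The spine rod gives every phantom a
consistent anatomical orientation, which is what makes rotation
prediction solvable in the pretext task.

What the phantoms deliberately do **not** model: textured parenchyma,
scanner artefacts, juxtapleural and ground-glass nodules, vessel
branching, respiratory motion. Passing the phantom experiments therefore
demonstrates that the mechanisms are implemented correctly and can be
trained, not that clinical performance transfers.

## Desk-scale study conditions

The reference configurations carry the full-scale settings (96-cube
windows, 64-channel pyramid, seven anchors; pretext at learning rate 0.1
halved after epochs 70/85, weight decay 5e-4, 100 epochs, batch 16; HS2
at 30/50 conv channels, 2048/1024/512 FC widths, 2000 epochs). The
experiments shipped with the package run the same mechanisms at desk
scale, chosen once as follows:

* **Pretext:** 40 phantoms of 32 cubed voxels, 30 train / 10 held out,
  backbone channels (4, 8, 16, 16, 16), 6 epochs, learning rate 0.02.
* **HS2:** 200 training and 100 held-out 48×48 LHI patches, conv
  channels (6, 12), FC widths (48, 24, 16), 15 epochs.
* **Detector:** 64-cube windows (one window per 64-cube phantom), anchors
  {3, 5, 10}, pyramid 16 channels, 30 training and 10 evaluation
  phantoms with two nodules (6–12 mm, within the anchors' working range)
  and three vessels each, 10 epochs of Adam at learning rate 1e-3.

All randomness flows through one explicit seed per experiment;
determinism holds under single-threaded execution (the BLAS behind the
GEMM-based convolutions must not multi-thread for bit reproducibility).

## Numerical notes and degenerate inputs

* The pyramid requires window sides divisible by 16 (five stages of
  halving); volumes smaller than the window are zero-padded into a single
  window, and edge windows are clamped to the volume.
* `hu_to_gray` rejects already-windowed input rather than double-mapping.
* Resampling uses voxel-centre alignment with border replication past the
  last centre; output lengths are `round(n·spacing/target)` so physical
  extent is preserved within one output voxel.
* A candidate at a volume corner yields a zero-padded LHI stack rather
  than an error; a candidate without patches is left `unfiltered` with a
  warning.
* An all-ignored anchor assignment yields a zero detection loss with a
  warning; cross-entropy probabilities are clamped at 1e-12.
* With no qualifying operating point, FROC sensitivity at a level is 0;
  an empty size stratum reports `NA`.

## Known limitations

* The detector is trained and evaluated on phantoms; no claim is made
  about LUNA16-scale clinical performance, which requires GPU-scale
  training on real cohorts. Published CPM rows are reproduced as metric
  arithmetic only.
* Axis-aligned geometry only; direction cosines are rejected at load.
* The GAN-based lung masking of the original pipeline is replaced by the
  classical threshold/component method, and masking is optional.
* Batch-normalisation statistics in HS2 are computed over small desk
  batches; very small batches (< 4) can destabilise training.
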