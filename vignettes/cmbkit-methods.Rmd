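---
title: "Recognising cerebral microbleeds with cmbkit: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising cerebral microbleeds with cmbkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cmbkit)
```

## The problem

Cerebral microbleeds (CMBs) are small hemosiderin deposits that appear as
dark (hypointense) focal spots on susceptibility-sensitive MRI (GRE and
SWI sequences). They matter clinically — burden bands of 1–4, 5–9 and 10+
lesions inform treatment decisions — but they are rare, small (a few
voxels), and easily confused with calcifications, vessel flow voids and
imaging artefacts. Automated recognition therefore faces two coupled
difficulties: extreme class imbalance (a whole brain yields thousands of
lesion-free patches per true lesion) and a false-positive problem driven
by CMB mimics.

cmbkit implements a patch-based recognition framework around a 3D
convolutional classifier: volumes are standardised, 11×11×11-voxel
patches are extracted and labelled against ground-truth lesion
coordinates, and the classifier is trained under one of four
training-set assembly strategies that differ in how the non-CMB class is
built:

* **A** — all CMB patches + an undersampled random subset of non-CMB
  patches;
* **B** — all CMB patches + all non-CMB patches;
* **C** — all CMB patches + all non-CMB patches + detector false
  positives (hard negatives);
* **D** — all CMB patches + detector false positives only.

Hard negatives come from a candidate proposer run over whole volumes:
its false positives, by construction, *look like* microbleeds, and
feeding them back as negatives is what sharpens the decision boundary
against mimics.

## The classifier

The network is a small 3D CNN: three stages of two Conv+BN+ReLU layers
(32, 64, 128 filters of 3×3×3), each stage closed by 2×2×2 max pooling
and dropout (rates 0.3, 0.3, 0.4), then a 256-unit linear layer, dropout
0.4, and a 2-unit output. Convolutions use same-padding (padding 1), so
only pooling reduces the grid: 11 → 5 → 2 → 1 by floor division, leaving
a flattened width of 128. Without same-padding an 11³ input would
collapse before the third stage, so the padding policy is forced by
consistency of the layer table; it is recorded here as an assumption
because the original description does not state it. Under this policy the
network has exactly 892,834 trainable parameters (batch-norm running
statistics are buffers, not parameters), which
`count_parameters(cmb_model())` reproduces and the test suite re-derives
from a closed-form per-layer summation.

Training uses Adam (learning rate 0.01, weight decay 1e-4 added to the
gradient), softmax cross-entropy over the two classes, and batches of
128 — all exposed in `cmb_control()`. Batch normalisation keeps running
statistics with momentum 0.1 (unbiased variance) for evaluation-mode
forward passes. The linear head applies a ReLU after the 256-unit layer;
the layer table lists no activation there, but without one the two
linear layers would collapse into one. When a validation set is given,
the returned weights are those of the epoch with the best validation
balanced accuracy, ties resolved toward the earlier epoch; the original
work does not state its selection rule, so this choice is ours.
`cmb_train(..., init = <cmb_net>)` continues from saved weights without
freezing any layer, which realises the pretrain/fine-tune workflow.

Because no deep-learning framework is part of this package's dependency
set, the forward and backward passes are implemented in the package
itself (im2col convolution kernels in C++ via Rcpp/RcppArmadillo, batch
norm and the optimiser in R). The backward pass was verified against
central finite differences on a small model; the unit tests keep a
determinism contract (same seed, same history and weights) instead,
since the gradient check is a development-time tool.

Augmentation follows the recipe of concatenating originals with
stochastically transformed copies: per copy, each enabled flip
(left–right, anterior–posterior) is applied with probability 1/2,
`rescale` multiplies intensities by a factor drawn from [0.9, 1.1] and
`intensity_shift` adds an offset in [−0.1, 0.1] on the standardised
scale. The transform names are given in the source work; the magnitudes
are not, and the values here were chosen as small perturbations that
keep standardised patch statistics finite and labels unambiguous.

## Coordinates, normalisation, patches

Volumes are NIfTI-1 with the usual RAS+ world frame; voxel indices are
0-based and conversion applies the (inverse) 4×4 affine with
round-to-nearest (ties to even). Converted points falling outside the
grid are flagged, never clipped: silently moving a lesion annotation is
worse than refusing it. Annotation CSVs record their coordinate space
(`ras` or `voxel`) explicitly rather than guessing a convention.

"Zero mean and unit variance" normalisation is applied per whole volume
(population SD) before any patch extraction; a constant volume is an
error rather than a silent zero-division.

Sliding-window extraction tiles the volume with stride = edge
(non-overlapping) starting at the origin and *drops* partial windows at
the far faces — padding would inject synthetic intensities into the
training distribution. A tile is labelled `cmb` iff a lesion *centre*
lies inside it; when the tile pool serves as the non-CMB complement to
lesion-centred positives, tiles whose extent merely grazes a lesion
sphere are excluded so near-miss tiles do not enter the negative class
with misleading labels. Lesion-centred extraction shifts the window
inward at boundaries (again, no padding), so the lesion is always
contained even if not centred. Undersampling keeps every positive and a
seeded uniform subset of negatives, `round(ratio × n_cmb)` of them, with
ratio 1 (balanced) as the default — the original ratio is not published,
so it is configuration, not a claim.

## The phantom

Real GRE/SWI cohorts with expert CMB annotations are access-restricted,
so the package ships a phantom generator that makes every downstream
stage testable: a smooth tissue background (Gaussian-blurred white
noise, mean 100, SD 10 in arbitrary scanner units), multiplicative
hypointense spheroids for microbleeds, two mimic families, and additive
voxelwise Gaussian noise (SD 5 by default, i.e. SNR 20 against the
background mean — a mid-range value for these sequences).

A lesion of radius $r$ and contrast $c$ multiplies the volume by
$1 - c\,e^{-\lVert x - \mu\rVert^2 / (2 (r/2)^2)}$: the centre attains
exactly the configured fractional intensity drop and the profile blends
smoothly into background. Mimics are (i) vessel-like tubes — a line
segment of length 8–16 voxels, radius 1, rasterised as overlapping
spherical stamps combined by elementwise minimum so overlap does not
compound darkening — and (ii) artefact-like clusters of 3–7 single-voxel
speckles with sharp (unsmoothed) drops. Defaults are 1–4 microbleeds of
radius 1–3 voxels at contrast 0.6, 2 vessel and 3 artefact mimics per
scan; the source data's lesion sizes in voxels are not published for its
scanners, so these are configuration choices representing "small, dark,
a few voxels", fixed once. Inserted structures keep a minimum Chebyshev
centre separation of 2·max(radius)+1 voxels so patch labels stay
unambiguous. All randomness flows from one seeded stream per call
(the caller's RNG state is saved and restored), making every output
bitwise reproducible from `(config, seed)`.

What the phantom does *not* emulate: anatomy (no skull, ventricles or
vessels-as-anatomy), T2*/phase physics, partial-volume or susceptibility
dipole effects, scanner-specific noise spectra. Passing tests on
phantoms therefore demonstrate the *mechanics* of the framework — patch
labelling, imbalance handling, hard-negative mining, metric arithmetic —
not clinical-grade performance on real scans.

## Candidate proposal and hard-negative mining

The shipped proposer is a multi-scale Laplacian-of-Gaussian blob
detector on the inverted (hypointensity) image: for each probed radius
$r$ the volume is smoothed at $\sigma = r/\sqrt3$ (the scale at which a
solid 3D blob of radius $r$ maximises the scale-normalised response),
the response $-\sigma^2 \Delta (G_\sigma * I_{inv})$ is computed with
separable kernels and a 6-neighbour Laplacian, and 26-neighbourhood
local maxima above a threshold survive greedy non-maximum suppression
(Chebyshev radius max(scales)) up to a per-scan cap. A border band of
2·max(scales) voxels is excluded because replicate-edge padding biases
the response at the faces. The defaults — scales 1–3 voxels, threshold
1.0 (in units of standardised intensity), cap 100 — were calibrated once
on the phantom's score distributions: every phantom microbleed produces
a candidate (scores ≥ ~1.8) while noise maxima sit mostly below 0.8,
leaving roughly nine false positives per scan, dominated by the planted
mimics. That is deliberately FP-rich: the proposer's job in this
framework is to supply realistic hard negatives, not to be a good
detector. Any detector can be substituted through the candidate contract
(centre, score, scale).

Candidates are matched to ground truth greedily in descending score
order, one-to-one, within a Chebyshev radius of 5 voxels — half the
patch edge, so a "true positive" is precisely a candidate whose centred
patch contains the lesion centre. Unmatched candidates are false
positives; on a zero-CMB (normal) scan that is every candidate. False
positives are harvested as `mined_fp` patches and feed strategies C/D.

## Evaluation kit

Balanced accuracy, precision, sensitivity and F1 are computed from
confusion counts kept as nonnegative *reals*, because repeated
cross-validation reports fold-averaged counts and those averages must
pass through the same formulas. F1 is the standard harmonic mean
2PS/(P+S). Degenerate denominators (e.g. sensitivity on a normal scan
with no positives) return 0 with an explicit `degenerate` attribute
instead of raising — evaluation over normal cohorts must not abort. AUC
is the Mann–Whitney rank-sum probability with midrank tie handling.
Metrics print at 3 decimals and tests compare at ±0.001 to absorb mixed
truncation/rounding in published tables.

Burden stratification uses categories 1–4, 5–9 and ≥10 CMBs (the only
partition consistent with "five to nine" and "ten or more"; zero-CMB
scans are reported separately as "normal", not folded into category 1),
and pools counts within category before computing metrics
(micro-pooling).

Cross-validation is five-times five-fold by default: positives are dealt
round-robin after a seeded shuffle so per-fold positive counts differ by
at most one ("TP-balanced" folds); negatives are split uniformly; an
optional scan-grouping mode keeps all patches of a scan in one fold
(patient-level splitting). Repeat $r$ reseeds fold construction with
seed + $r$. Aggregation first averages each repeat over its folds, then
reports the mean and the *sample* (n−1) standard deviation across
repeats — the convention pinned by reproducing a published aggregation
row exactly.

## Study sizes used in the tests and acceptance script

The package's own reduced-scale studies run on 64³-voxel phantoms:

* *Separable training*: 13 scans (10 train / 3 held out), 4 high-contrast
  (0.8) noise-free microbleeds per scan, no mimics; strategy A at ratio 2;
  full architecture, up to 50 epochs with early stop at training
  accuracy 1.
* *Strategy-B recovery and strategy comparisons*: cohorts of 8–12 scans
  under the default phantom settings; positives augmented with 8
  stochastic copies each (the concatenation recipe above); a reduced
  schedule (8/16/32 filters × 1, 64-unit head — the `ModelConfig`
  schedule is overridable by design) trained 20–25 epochs over 3 seeds.

These sizes are the package's chosen experimental design for phantom
studies; the directional conclusions (hard negatives reduce normal-scan
false positives; undersampled training inflates false positives under
exhaustive testing) are asserted as directions, never as the absolute
counts published for real cohorts, which are not reproducible without
the restricted data.

## Known limitations

* The phantom's mimic geometry is the simplest distinguishable proxy for
  the named mimic families; real flow voids and artefacts are richer.
* The CNN runs on CPU in double precision; it is sized for patches, not
  whole-volume dense inference.
* The proposer is intentionally simple; swapping in a learned detector
  changes the hard-negative distribution and likely the strategy C/D
  margins.
* Whole-volume normalisation assumes roughly comparable tissue coverage
  across scans; skull-stripping and bias-field correction are out of
  scope.
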