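---
title: "Automated fissure integrity assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated fissure integrity assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The human lungs are divided into five lobes by the pulmonary fissures: the
left oblique fissure (LOBL) between the left upper and lower lobes, the
right oblique fissure (ROBL) between the right middle/upper lobes and the
right lower lobe, and the right horizontal fissure (RHOR) between the right
upper and middle lobes. In many individuals a fissure is *incomplete*: part
of the lobar boundary has no pleural invagination, so parenchyma is fused
across the boundary and air can flow between lobes (collateral
ventilation). Quantifying fissure completeness — the *fissure integrity
percentage* (FI%), the fraction of the lobar boundary surface where the
fissure is radiographically present — matters clinically because
endobronchial-valve treatment for emphysema fails when the target lobe is
ventilated collaterally, and because fissure integrity affects lobar
sliding and lung biomechanics.

`lungfissure` assesses fissure integrity automatically from CT. Its inputs
follow the output contract of an upstream segmentation stack: the CT volume
itself, a binary left/right lung mask, a five-lobe segmentation, and a
fissure probability map in `[0, 1]` that is high where a fissure is
radiographically visible. Such maps are produced by cascaded fissure
detection CNNs; this package does not re-implement them, it consumes their
output — and ships a synthetic phantom generator that emulates the whole
contract so every stage is trainable and testable without clinical data.

## The pipeline

For each lung the pipeline: (1) clips CT intensities to (−1024, 200) HU and
rescales them linearly to (−1, 1); (2) crops CT and probability map to the
lung's bounding box and concatenates them as two channels; (3) applies a 3D
attention U-Net that classifies every voxel as background, intact fissure,
or incomplete fissure; (4) cleans the labeling with three morphological
steps confined to the *complete fissure* — the full lobar boundary surface
extracted from the lobe segmentation; (5) reports FI% and the derived
metrics. Three independent networks are trained, one per fissure; the right
lung's input is used twice, once for ROBL and once for RHOR.

### Boundary extraction

The complete fissure is the set of voxels of a designated *reference lobe*
that are face-adjacent (6-connectivity) to a voxel of the partner lobe:
LOBL uses LUL voxels adjacent to LLL, RHOR uses RUL voxels adjacent to RML,
and ROBL unites RML- and RUL-voxels adjacent to RLL (the right oblique
fissure separates different lobe pairs anteriorly and posteriorly). Two
design choices here were genuinely open:

* **Sidedness.** "Boundary voxels adjacent to another lobe" can be read as
  one- or two-sided. We take the one-sided reading: FI% is a ratio over the
  surface, so the choice approximately cancels, and a one-voxel-thick sheet
  matches the thin-target design of the network. A `two_sided` flag
  provides the other reading.
* **Connectivity.** 6-adjacency yields the thinnest well-formed digital
  surface; 26-adjacency would thicken corners.

Voxels at the right-lung triple junction that qualify for both ROBL and
RHOR are retained in both masks, because each fissure is assessed
independently by its own network.

### Network

The architecture is a standard 3D U-Net with additive attention gates on
the skip connections. The published description of the original network
fixes only the topology (four encoding steps, attention-gated skips,
two-channel input, three-class softmax output); filter counts,
normalization and upsampling operators are this package's own choices,
declared defaults rather than claims about any prior model:

* two 3×3×3 convolutions per level, channel count doubling from
  `base_filters` (default 16) per encoding step, 2×2×2 max pooling;
* **instance normalization** (per-volume, per-channel) after each
  convolution. Batch-style statistics are degenerate at the batch sizes a
  whole-lung 3D model permits (1–2), so per-instance statistics are the
  stable choice;
* **nearest-neighbour ×2 upsampling followed by a 1×1×1 channel-halving
  projection** in the decoder. This sits in the same capacity class as
  trilinear or transposed-convolution upsampling with a cheaper and exactly
  adjoint backward pass;
* additive attention gates: the upsampled coarser decoder feature acts as
  gating signal `g`; with skip features `x`, the gate computes
  `a = sigmoid(psi(relu(Wg g + Wx x)))` through 1×1×1 projections and
  multiplies the skip features by `a`.

The forward and backward passes are implemented directly (R orchestration
over BLAS-backed C++ kernels for convolution, pooling and upsampling);
their correctness is anchored by finite-difference gradient checks over
every parameter tensor in the test suite, rather than by a framework.

### Loss

Class imbalance is extreme: the fissure surface is a one-voxel-thick sheet
in a lung volume, so background outnumbers each fissure class by orders of
magnitude. The Tversky loss generalizes soft Dice with asymmetric weights
on false positives (α) and false negatives (β = 1 − α):

TI_c = (Σ p_c g_c + s) / (Σ p_c g_c + α Σ p_c (1 − g_c) + β Σ (1 − p_c) g_c + s),
loss = Σ_c (1 − TI_c).

We use α = 0.05, hence β = 0.95: missing a fissure voxel costs ~19× more
than hallucinating one. This deliberately biases the network toward
over-segmentation, which the post-processing step then confines to the true
boundary surface. The per-class sum includes the background class
uniformly, and a stabilizer s = 1 in numerator and denominator avoids 0/0
on empty classes. At α = β = 0.5 each term reduces exactly to soft Dice —
one of the identities the tests assert.

### Training

Adam with a static learning rate of 0.0002. Training samples are random
crops of fixed size (default 128×128×64) from the per-lung inputs; when the
lung crop is smaller than the target, the CT channel is padded with −1, the
probability channel with 0 and the target with background. Because the
fissure sheet is thin, purely uniform crops frequently contain no
foreground; with probability `fg_crop_prob` (default 0.5) a crop is
therefore constrained to contain at least one complete-fissure voxel. This
biased sampling is switchable.

Splits are always at the subject level, never the crop level: proportions
0.75/0.15/0.10 for train/test/validation, apportioned by largest remainder.
The best epoch is the one minimizing validation Tversky loss (ties to the
earlier epoch); "best" is not further specified in the original description,
so the criterion is configurable. For k-fold cross-validation (k = 8 in the
reference design) the published account gives both the fixed proportions
and the k-fold scheme without reconciling them; we implement k-fold with a
0.10 validation carve-out from each fold's training portion and treat the
fixed split as the single-fold special case.

### Post-processing

Three steps, in order, all confined to the complete fissure surface:

1. **False-positive removal** — every voxel outside the surface becomes
   background.
2. **False-negative fill** — every surface voxel labeled background takes
   the majority class among its 26-neighbours labeled intact or incomplete.
   Passes are synchronous (computed from the previous pass's state, so the
   result is independent of update order) and repeat until the surface is
   fully labeled; stragglers in components with no label at all take the
   class of the nearest labeled surface voxel (Euclidean). Ties go to
   *incomplete*: for collateral-ventilation screening it is the
   conservative call, flagging possible leakage rather than masking it.
3. **Smoothing** — one simultaneous majority-vote pass over the
   26-neighbourhood, neighbours-only by default (a `smooth_include_center`
   flag adds the centre's own label to the vote); ties keep the original
   label.

26-connectivity is stated for the smoothing step in the reference design;
we use it for the fill too, because a thin oblique digital surface is
26-connected but often 6-disconnected, and a 6-connected fill would stall
on staircase patterns. Whether smoothing iterates was likewise unstated; a
single pass is the default because iterated majority smoothing on a
two-class surface can oscillate on checkerboards.

### Metrics

* `FI% = 100 · #intact / #(intact + incomplete)` over the surface.
* `FIS error = (FI%_pred − FI%_truth) / FI%_truth`, undefined at truth 0;
  such cases are excluded from aggregation and counted. Cohort tables
  report the mean of absolute FIS errors (the signed mean is also emitted):
  published per-fissure values of this statistic are non-negative with
  standard deviations too small for signed averaging around zero, so the
  absolute reading is the consistent one.
* `ACC_FIS% = 100 · #correctly labeled surface voxels / #surface voxels`,
  defined only when prediction and truth share a surface — which
  post-processing guarantees.
* Category: complete (FI% ≥ 90), partial (10 ≤ FI% < 90), missing
  (FI% < 10). ROC AUC for complete-vs-rest uses the predicted FI% as the
  continuous score (rank-based, ties at 1/2).
* Reproducibility across timepoints is the absolute difference in FI
  percentage points (a relative variant sits behind a flag).
* All summary tables use the sample (n − 1) standard deviation.

## The phantom generator

The generator defines the study conditions for everything the package can
demonstrate without clinical data. Each case is built as:

* **Lungs**: two ellipsoids in a 0 HU "chest wall", parenchyma −850 HU.
* **Fissures**: smooth height fields `z = f(x, y)` — oblique fissures are
  tilted planes (slope ≈ 0.4 in z per y-voxel) plus two sinusoidal
  perturbations of amplitude `fissure_undulation` (default 2 voxels);
  the horizontal fissure is a near-axial undulating plane. The left lung
  splits into 2 lobes, the right into 3; where the horizontal surface dips
  below the right oblique one, the middle lobe is locally absent and the
  upper lobe directly abuts the lower lobe, reproducing the anatomic
  posterior configuration of the right oblique fissure.
* **Incompleteness**: per fissure, a contiguous patch is grown on the
  extracted boundary surface by breadth-first search from a random seed
  voxel until it covers `gap_fraction` of the surface — real
  incompleteness is spatially contiguous, and contiguity is what makes the
  learning task realistic. The ground-truth mask labels the remainder
  intact; by construction the achieved true FI% is `100·(1 − gap_fraction)`
  up to rounding, and decreases monotonically in the requested fraction.
* **CT appearance**: a one-voxel-thick sheet at −650 HU on intact surface
  voxels only (≈200 HU contrast against parenchyma, matching the order of
  literature attenuation values; only the contrast matters to the
  contract), plus Gaussian noise (`noise_sd`, default 30 HU).
* **Probability map**: the visible-fissure indicator blurred with a
  Gaussian (`prob_blur`, default 1 voxel), gain-normalized so a flat sheet
  interior reaches ≈1, clipped to `[0, 1]`. It stands in for a detection
  CNN's confidence; it is deliberately not a learned model.
* **Seeds**: the geometry (gap placement, undulation phases) and the CT
  noise draw from separate streams, so a case can be regenerated with
  identical anatomy under fresh noise — the synthetic analog of re-scanning
  a subject at a later timepoint.

What the phantom does *not* emulate: airways and vessels, accessory
fissures, emphysematous texture, scanner/protocol variation, motion
artifacts, and fissure-like pathologies. Tests passing on phantoms
demonstrate that the pipeline's machinery — boundary extraction, learning,
post-processing, metrics — recovers a known generating parameter; they do
not certify performance on clinical CT, where the radiographic appearance
of fissures is far more variable.

## Numerical choices and degenerate inputs

* Resampling to isotropic spacing (1 mm by default): trilinear for scalar
  volumes, nearest-neighbour for label volumes (which provably never
  invents labels). The interpolation for the probability map is not
  dictated by the contract; linear is used, matching its continuous nature.
* All volumes of a case must share one grid; spacing/origin agreement is
  checked to 1e-3 mm, a tolerance tight enough to catch real mismatches and
  loose enough for header round-off.
* The network requires spatial sizes divisible by `2^levels` and fails fast
  otherwise; `predict_integrity()` pads (CT −1, probability 0) and strips
  the padding afterwards.
* An empty fissure surface makes FI% undefined — an error, not a silent 0.
  A raw prediction that is entirely background on a non-empty surface is an
  error from the fill step (there is nothing to propagate).
* `fis_error` with ground-truth FI% = 0 is undefined; such fissures are
  excluded from FIS-error aggregation and counted separately.

## The scaled validation study

`run_validation_study()` is the package's own end-to-end demonstration,
sized for a single CPU: 40 phantoms on a 64×64×32 grid with gap fractions
uniform in [0, 0.8]; 30 training cases (3 carved out for validation), 10
held out; one 3-level, 8-filter attention U-Net per fissure trained for 20
epochs of two 24×24×16 foreground-biased crops per case with single-crop
Adam steps. It reports the pooled R² of predicted versus true FI% on the
held-out cases, the mean absolute FI% error, ACC_FIS%, mean |FIS error| and
the complete-vs-rest AUC; `run_reproducibility_study()` then regenerates
the test phantoms with identical geometry and fresh noise and reports the
mean absolute FI% difference between the two runs. These are the quantities
`scripts/acceptance.R` recomputes.

Problem sizes here are the package's declared scaled-down study conditions:
large enough that the networks must genuinely interpolate missing boundary
from context, small enough that the whole study runs in minutes. The
acceptance thresholds asserted in the test suite (R² ≥ 0.8, mean |FI%
error| ≤ 10 points, reproducibility ≤ 5 points) were fixed with the study
design, before any tuning against outcomes.

## Known limitations

* The phantom's geometry is idealized (ellipsoids, graph surfaces); lobar
  boundaries in vivo curve back on themselves near the hilum, which graph
  surfaces cannot represent.
* Voxel-based surfaces only; no mesh extraction, no topology-preserving
  smoothing.
* No DICOM ingestion and no registration: misaligned inputs are rejected,
  not fixed.
* Lungs with other than the standard five-lobe anatomy (accessory or azygos
  fissures) are out of scope, mirroring the exclusion of anatomic variants
  in the reference cohort design.
* Training determinism holds for a fixed platform/BLAS; bitwise identity
  across different BLAS builds is not guaranteed.
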