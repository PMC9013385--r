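---
title: "Liver segmentation and volumetry with hepavol: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liver segmentation and volumetry with hepavol: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In living-donor liver transplantation the graft and the remnant must both be
large enough, so pre-operative CT volumetry of the whole liver and of its
resectable units — the left lobe, the right lobe, and the small caudate lobe
beside the inferior vena cava — is safety-critical. Manual slice-by-slice
contouring is the reference standard but takes an expert tens of minutes per
scan. `hepavol` implements the full automated alternative: segment the liver
(or one lobe) in 3D from abdominal CT with a convolutional network, convert
the mask to a volume by slice-area summation, and quantify how well the
automated volumes agree with manual ones.

The package is organised so that every stage is a testable function over
ordinary R objects: a `ct_volume` (3D HU array plus anisotropic voxel
spacing), a `label_volume` (binary masks per structure), tibbles for every
tabular result, and a seeded phantom generator standing in for clinical data.

## Preprocessing

CT intensities are Hounsfield units. `apply_window()` clips them to a
soft-tissue window — level 50 HU, width 180 HU by default, i.e. the interval
[−40, 140] HU — and rescales linearly to [0, 1], matching the sigmoid output
range of the network. Windowing is deliberately *not* idempotent on its own
output, so a second application is refused rather than silently corrupting
the scale.

`resize_inplane()` resamples each axial slice (bilinear for images, nearest
neighbour for masks, so labels stay binary) and rescales the in-plane spacing
by the size ratio: 512 px at 0.7 mm becomes 256 px at 1.4 mm, preserving the
physical field of view and, importantly, volumes. `to_model_blocks()` then
cuts the slice axis into fixed-depth blocks (default 64) with a trailing
channel axis; the last block is zero-padded and its valid-slice count
recorded so predictions can be un-padded exactly. Cohort splitting
(`split_dataset()`) is at patient level with a 70:15:15 default and a floor
rule — `floor(0.70 n)` train, `floor(0.15 n)` validation, remainder test — so
the partition is always exhaustive and blocks from one scan never leak across
sets.

I/O covers NIfTI (via RNifti) for images and label-coded masks, and a
minimal reader for uncompressed explicit-VR little-endian DICOM series:
slices are sorted by their along-axis position (never by filename), the
section thickness is inferred from the inter-slice gap, and an inconsistent
gap is an error naming the offending pair of positions. Rescale slope and
intercept are applied on read, so volumes are standard HU from the start.

## The segmentation network

The model family is a 3D U-Net — an encoder–decoder with skip connections —
with three independent toggles that reproduce a four-row ablation ladder:

| configuration | attention gates | deep supervision | ConvLSTM |
|---|---|---|---|
| 3D U-Net | – | – | – |
| AU-Net | yes | – | – |
| AU-Net w/ DS | yes | yes | – |
| DALU-Net (full) | yes | yes | yes |

Per level the encoder applies two 3×3×3 convolutions, each followed by batch
normalisation and ReLU, then 2×2×2 max pooling; filters start at
`base_filters` and double per level. The decoder mirrors this with 2×2×2
transposed-convolution upsampling and concatenated skip features. The final
head is a 1×1×1 convolution with a sigmoid, so outputs are voxel-wise
foreground probabilities.

**Attention gates.** Each skip connection is gated by coefficients
$\alpha = \sigma\!\big(\psi\,\mathrm{ReLU}(W_s s + W_g g + b)\big)$, where
$s$ is the skip feature, $g$ the upsampled decoder feature at the same
resolution, and $W_s, W_g, \psi$ are 1×1×1 projections (intermediate width =
the level's filter count). The gated skip is $s \cdot \alpha$ — a learned
multiplicative mask in (0, 1) that suppresses background regions. With all
gate parameters zero, $\alpha = \sigma(0) = 0.5$ exactly, a property the
tests pin down.

**Convolutional LSTM.** CT context along the slice axis is thin when sections
are 5 mm apart — small structures like the caudate lobe span only a few
slices, which plain 3D convolution handles poorly. The decoder therefore can
run a convolutional LSTM over the gated skip features, treating the slice
axis as the recurrence axis: 3×3 convolutional input and recurrent
transforms, sigmoid input/forget/output gates, tanh candidate, hidden width
equal to the feature width. The recurrence is unidirectional in ascending
slice order (output at slice *k* depends only on slices ≤ *k*); nothing in
the design requires bidirectionality and the single direction keeps cost and
state handling simple.

**Deep supervision.** When enabled, auxiliary 1×1×1-conv + sigmoid heads are
attached to the bottleneck output and to each decoder level's post-gate
features — `levels` heads in total — and each is scored against the ground
truth nearest-neighbour-downsampled to that head's resolution. The training
objective is the *unweighted sum* of the final-head dice loss and all
auxiliary dice losses; the history logs the components so the sum identity
is checkable to 1e-6.

**Implementation.** The network, including every backward pass, is native R:
convolutions are im2col gathers followed by BLAS matrix products; the
transposed convolution and pooling use precomputed index maps; batch
normalisation (over the spatial extent of the single 3D block per step, i.e.
instance statistics) carries running moments for deterministic inference.
Every layer's analytic gradient is verified against central finite
differences in the test suite (relative error ~1e-7). Weight initialisation
is He for convolutions, with the ConvLSTM forget-gate bias set to 1, and is a
pure function of the initialisation seed, so builds and training runs are
bit-reproducible.

## Training

Training minimises the dice loss
$1 - (2\sum p\,t + \varepsilon) / (\sum p + \sum t + \varepsilon)$,
$\varepsilon = 10^{-6}$, with Adam. The schedule is reduce-on-plateau:
initial learning rate 0.01; when the monitored loss (validation dice loss of
the final head, inference mode) has not strictly improved — beyond 1e-8 —
for 10 consecutive epochs, the rate is multiplied by 0.1 and the patience
counter resets. Successive reductions compound (0.01 → 0.001 → 1e-4 …): the
alternative reading, always rescaling the *initial* rate, would freeze the
rate after the first reduction and contradict plateau-scheduler convention.
Early stopping fires after 30 consecutive non-improving epochs; the weights
returned are those of the best-validation epoch. Batch size defaults to 1
because a 3D block is already a large sample; gradients are averaged when a
larger batch is configured. An optional `stop_loss` floor ends a run once the
training loss falls below it — a convenience for bounded overfitting runs,
off by default.

## Volumetry

`mask_volume()` implements the classic CT volumetry estimator: per-slice
segmented area (foreground count × pixel area) times the section thickness,
summed over slices, divided by 1000 to give mL. It is exactly linear in
thickness and invariant to slice order. `lobe_volumetry()` reports all four
structures plus the additivity gap (whole minus the lobe sum) — identically
zero on a true partition, and deliberately reported rather than hidden
otherwise. Volumes are computed on the prediction grid with its rescaled
spacing, not re-upsampled: because resampling preserves the physical extent,
the two differ by under 2% on phantoms, a property under test.

## Evaluation metrics

`seg_metrics()` reports recall, precision, dice similarity coefficient
(DSC), intersection over union (IoU), and the Hausdorff distance in mm.
DSC and IoU obey $\mathrm{DSC} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$
identically, which doubles as a cross-check in the tests. The Hausdorff
distance is the exact (100th percentile) symmetric max–min Euclidean
distance between boundary-voxel centres (6-connectivity erosion complement),
with voxel indices scaled by the anisotropic spacing; for solid masks the
boundary restriction changes nothing but the cost. Empty-mask conventions
are explicit: both masks empty is vacuous agreement (fractions 1, distance
0); exactly one empty gives 0 overlap scores and an `NA` Hausdorff distance,
surfaced rather than defaulted, because the distance is genuinely undefined.

## Agreement analysis

`linear_agreement()` regresses automated on manual volumes by OLS (slope,
intercept, R²) — the axis convention of method-comparison scatter plots.
`bland_altman()` uses differences d = automated − manual: bias = mean(d),
95% limits of agreement bias ± 1.96·SD(d) with the sample (n−1) SD and the
exact normal quantile 1.96, the standard Bland–Altman convention. The sign
convention means a positive bias is automated overestimation; the paired
significance test on d is a paired t-test. `agreement_report()` produces one
row per structure plus regression and Bland–Altman figures (ggplot2), and
`tidy()`/`glance()`/`autoplot()` methods make results pipeline-friendly.

## The phantom generator

Clinical liver CT with lobe-level ground truth is rarely shareable, so the
package carries a seeded geometric phantom: a liver-sized ellipsoid split by
a plane into left and right lobes plus a small separate caudate ellipsoid,
over a darker background with Gaussian noise. Defaults emulate adult donor
CT: 512×512 in-plane at 0.7 mm, 5 mm sections, a ~1.4 L liver with a ~27%
left-lobe fraction and a ~14 mL caudate (semi-axis products keep the caudate
under 5% of the liver, preserving the class imbalance that makes caudate
segmentation the hard case); liver 60 HU over −20 HU background with 15 HU
noise, all inside the default display window. A caudate crossing the lobe
plane into the left half-space is rejected, mirroring the anatomical
convention. `generate_cohort()` jitters sizes, centres and noise per case
from derived seeds, so a cohort is reproducible from `(seed, n)`.

What the phantom does *not* emulate: vasculature (including the middle
hepatic vein used to define the lobar plane anatomically), contrast-phase
variability, the heart/myocardium boundary that causes real failure cases,
and non-ellipsoidal liver shape. Tests passing on phantoms therefore
demonstrate that the machinery is correct — geometry in, geometry out — not
that clinical-grade accuracy has been reached; the headline accuracies of
liver-CT studies are functions of their private cohorts and GPU-scale
training, and reproducing them is explicitly out of scope.

## Numerical choices and problem sizes

- Dice smoothing ε = 1e-6; improvement threshold for the plateau/stop rules
  1e-8; binarisation threshold 0.5 (the network trains against binary
  targets with a sigmoid head, so 0.5 is the natural cut).
- Max-pool ties break to the first corner of the 2×2×2 cell, making pooling
  (and hence training) deterministic.
- Squared distances in the Hausdorff computation are evaluated in the
  expanded BLAS-friendly form; values below 1e-6 mm² are snapped to zero,
  which is exact on a voxel grid since genuine nonzero separations are at
  least the squared minimum spacing.
- Pixel-centre alignment in resampling, so constant images stay constant
  and resizing is volume-preserving up to boundary discretisation.
- Test and demonstration runs use deliberately small problem sizes chosen to
  exercise every code path at desk scale: 16×64×64 phantoms resized to
  16×32×32 blocks, 2-level networks with 4 base filters, cohorts of 12, a
  200-epoch budget for single-phantom overfitting, and n = 200 synthetic
  cohorts for agreement-statistic recovery. These sizes are the package's
  own choices for fast, deterministic verification; the code paths are
  size-independent.

## Known limitations

- One structure per trained network (`predict_mask()` emits a single
  `whole` mask); lobe-wise automation trains one model per lobe, matching
  the one-structure-per-dataset design the ablation grid assumes.
- The native R network is CPU-bound and meant for small studies, method
  development and verification, not for 191-scan training campaigns.
- The DICOM reader covers uncompressed explicit-VR little-endian series
  only; anything exotic should be converted to NIfTI first.
- Bias/LoA are reported with the auto − manual sign convention; flip signs
  when comparing against reports using the opposite one.
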