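---
title: "Converting pencil-beam proton dose to Monte-Carlo quality: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting pencil-beam proton dose to Monte-Carlo quality: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Analytical pencil-beam (PB) algorithms compute proton dose quickly but lose
accuracy in heterogeneous anatomy: behind air cavities and bone interfaces
they misplace the distal dose edge and misestimate dose by several percent,
precisely where head-and-neck targets sit.  Monte-Carlo (MC) transport is
the accuracy reference but takes hours per plan.  `pbmcdose` implements a
learned converter: a 3D convolutional network that takes the CT volume and
the PB dose of one proton field and outputs an MC-quality dose in seconds.
Two preprocessing ideas carry most of the accuracy gain and are the focus
of the package's experiments:

* **Beam-frame canonicalization (image rotation).**  Every field is rotated
  about its isocenter so that the beam virtually enters at gantry 270° and
  couch 0°.  All training samples then share one beam geometry, so the
  network sees depth always along the same axis and can learn the
  PB-to-MC residual structure (distal-edge corrections, scatter blur)
  once instead of once per angle.  At inference the converted dose is
  rotated back.
* **Zooming augmentation.**  Each rotated training sample is additionally
  zoomed about the isocenter by factors 0.8 and 1.2 (content-only scaling,
  dose values untouched), tripling the training set.

Three experiment arms reproduce the ablation: `baseline` (native angles,
no augmentation), `rotation` (canonicalization only), `rotation_zoom`
(canonicalization plus zoom augmentation).

## Data model and conventions

A `volume_grid` is a 3D scalar array (CT in HU, dose in GyRBE, masks in
{0,1}) with per-axis spacing and the world position of the first voxel
*center*.  The axis order is fixed package-wide as (superior–inferior,
anterior–posterior, right–left); the canonical beam travels toward +RL.
The canonicalization rotation undoes the couch angle about the AP axis
through the isocenter, then the gantry offset from 270° about the SI axis.
This composition is a convention (delivery systems differ); the test suite
pins it by property — a slab field oriented along the geometric beam
direction must come out axis-aligned to well under a degree — rather than
by sign lore.

Rotation, zoom and cropping to the network tensor are composed into a
*single* resampling per volume.  CT is interpolated trilinearly; doses use
separable Catmull–Rom (tricubic) interpolation with the small negative
overshoots clamped to zero.  The cubic kernel matters: at the coarse
voxel sizes of the desk-scale experiments, two trilinear passes
(canonicalize, then un-rotate the prediction) blur the distal dose edge
enough to dominate the converter's error budget, while the cubic round
trip is essentially lossless (a dose passed through the rotation round
trip retains a 100% gamma(3%/3 mm) passing rate against itself at
16×24×24 × 5 mm).  Masks are resampled nearest-neighbour.

Network inputs follow the normalization the conversion scheme prescribes:
CT is mapped through a fixed window of [-1000, 2000] HU onto [0, 1]
(per-volume min/max would make the mapping patient-dependent), and both
dose channels are divided by the maximum of the *cropped PB dose*, so
`max(pb_norm) == 1` exactly and the network can express amplitude
differences between PB and MC.  Zoomed copies are renormalized to restore
the unit PB maximum, with the MC channel divided by the same constant.

## The synthetic world

No public paired PB/MC head-and-neck data exist, so the package ships a
simulator that generates the *structure* of the problem end to end.  Its
defaults are one stated world, chosen once:

* **Phantom** — a soft-tissue ellipsoid "head" (0 HU) in air, with air
  cavities (-1000 HU) and bone slabs (+700 HU) placed strictly inside;
  the first insert is anchored within ~20 mm of the CTV so that the
  target region is heterogeneous, as in nasal-cavity cases.  CT maps to
  relative stopping power (RSP) through a stand-in piecewise-linear
  calibration: (-1000, 0.001), (0, 1.00), (700, 1.44), clamped.
* **Beam** — a spread-out Bragg peak (SOBP) built from K = 25 pristine
  peaks with ranges equally spaced in [R - M, R]; nonnegative weights are
  fitted by Lawson–Hanson NNLS against a flat target on the modulation
  interval and must give a plateau flat within ±2%.  The pristine peak is
  a smooth Bragg-like curve: an entrance plateau rising 0.35 → 0.45, a
  unit peak whose top spans [R - sigma_peak, R], and a Gaussian distal
  falloff of width sigma_d.  At the full 2 mm scale the defaults are
  sigma_peak = 3 mm and sigma_d = 1.5 mm; the 5 mm desk-scale world uses
  resolution-matched 5 mm / 3 mm (3–5 mm distal falloff is realistic
  range straggling for 150–210 MeV passive scattering).
* **Planning** — the nominal range is tied to the geometry like a real
  plan: R = (water-equivalent depth from body entry to the isocenter
  along the central axis) + a 10–18 mm distal margin, and the modulation
  is widened if needed so the plateau starts at least 12 mm proximal of
  the isocenter.  Each dose is normalized so the CTV median equals the
  per-beam prescription (2 GyRBE); this makes the R90 threshold
  meaningful for every beam.  Gantry angles are uniform; about 40% of
  beams are non-coplanar with couch magnitudes of 10–30°.
* **MC-like dose** — per lateral ray, the water-equivalent depth (WED) is
  integrated through the RSP volume from the body entry; the SOBP depth
  dose is evaluated at that WED, multiplied by a flat lateral aperture
  with error-function edges whose sigma grows with depth
  (sigma = entrance_sigma + sigma_growth × depth), scaled by the local
  stopping material (so air receives ~nothing), and finally each
  depth slice is smeared with a Gaussian of sigma_scatter =
  sigma_growth × depth to mimic in-patient scatter.  The entrance term
  is deliberately excluded from the slice smearing so that setting
  sigma_growth = 0 and a one-voxel beamlet makes the PB-like and MC-like
  fields *identical* — a structural identity the tests exploit.
* **PB-like dose** — identical, except each ray's WED is replaced by its
  lateral average over a `pb_beamlet_width` square footprint and no
  scatter smearing is applied.  This reproduces the clinically relevant
  failure signature: correct dose in homogeneous regions, range errors
  and washed-out distal edges behind heterogeneity boundaries.

The degradation magnitude is calibrated against one stated target: the
PB-like field should pass a global 3%/3 mm gamma test against the MC-like
field *broadly below 90%* (the desk-scale defaults — beamlet 30 mm,
sigma_growth 0.10 mm/mm, three cavities and three slabs — give a mean
around 80%, which is where clinical PB sits for head-and-neck fields).
It is emphatically not fitted to the clinical numbers; a green end-to-end
test establishes the qualitative ordering (converter beats PB; rotation
not worse than baseline), not clinical magnitudes.  Features of real data
the simulator does not emulate include nuclear halo dose, CT noise and
artifacts, realistic anatomy (it is piecewise-constant), aperture/
compensator scatter, and any measurement-based beam model.

## The network

The converter is a hierarchically dense 3D U-Net.  Dense convolution
blocks apply two 3×3×3 convolutions with ReLU, each layer seeing the
concatenation of everything before it in the block, and the block output
concatenates its input with both layers' features.  Down-sampling
concatenates a stride-2 convolution (ReLU) with a 2× max-pool of the same
features; up-sampling is nearest-neighbour 2× followed by a convolution
with ReLU and concatenation of the same-level encoder features; a final
1×1×1 convolution with ReLU yields the nonnegative dose.  Width and depth
are configurable (`model_config`); the desk-scale default is 3 levels
with 4 + 4 features — the architecture's width is a configuration
choice; the block structure is the contract.

No deep-learning framework exists in this environment, so the forward and
backward passes are written against the package's own C++ kernels
(per-offset shifted GEMM for the convolutions).  The backward pass is
verified against finite differences to ~1e-8 in the test suite.

Training protocol: Adam at 1e-3, MSE loss on the
normalized dose, learning rate ×0.1 after 10 epochs without validation
improvement, early stopping after 15, at most 500 epochs, 3-fold
cross-validation split at the plan level (all beams of a synthetic
patient stay together), best-validation weights restored, validation
folds never augmented (augmented copies in validation would leak the
augmentation policy into the stopping rule).  Inference averages the
three fold models.

Two small optimizer guards protect the very narrow desk-scale nets, which
unlike their full-width counterparts can collapse into an all-zero
absorbing state (a dead ReLU head receives no gradient): the learning
rate ramps linearly over the first 10 Adam steps, and a saturated head
voxel whose target is positive receives 5% of its gradient instead of
none.  Both are inert once the network is out of the danger zone, and
both are configurable (`warmup_steps`, `head_leak`).  The desk-scale
experiments also use batch size 1 rather than the protocol's 4: with a
dozen training beams, batch 4 would mean three optimizer steps per epoch,
and the extra steps matter more than gradient smoothing (the full-scale
default keeps batch 4).

## Evaluation battery

* **Global 3D gamma** — per reference voxel, the minimum over candidate
  points of the combined dose-difference (percent of the maximum
  reference dose inside the body) and distance-to-agreement metric;
  candidates sample the evaluated dose trilinearly on a dta/3 lattice
  within a 3×dta sphere, with an early exit once the geometric term
  alone exceeds the running minimum.  Voxels below 10% of the
  normalization dose are excluded.  The implementation is bounded
  against an exhaustive brute-force oracle in the tests (|Δγ| ≤ 0.02
  per voxel).  A passing voxel has γ ≤ 1 (+1e-9 for floating-point
  rounding at the exact boundary).
* **Range maps and ARD** — in the canonical frame, each lateral ray's
  depth-dose profile is scanned for the *distal-most* crossing of 90%
  (R90) or 50% (R50) of the prescribed dose, linearly interpolated
  between bracketing voxels; rays never reaching the threshold are NaN.
  The average range difference between reference and evaluated maps is
  the mean of (R_ref - R_eval)/R_ref over rays finite in both maps, in
  percent; deeper evaluated ranges give negative ARD.
* **MAE** — mean |D_MC - D| over body voxels receiving at least 10% of
  the prescription (threshold applied to the reference).
* **Isodose DSC** — Dice overlap of the voxel sets with dose in
  [low, high) percent of prescription, for the bands 10–30, 10–50,
  10–70, 10–90 (half-open, shared 10% floor).
* **DVH metrics and RDE** — D98/D95/D50/D2 of the CTV as type-7
  percentiles of the voxel doses (equivalently the interpolated inverse
  cumulative DVH), and the relative dose error (D - D_MC)/D_MC.

Plan dose is the voxelwise sum of the per-beam doses; plan-level reports
use gamma at 1%/1 mm, 2%/2 mm and 3%/3 mm plus MAE, DSC and RDE.

## Numerical choices and degenerate inputs

* Trilinear resampling is exact on constant and linear fields; the cubic
  kernel is exact on constants and does not widen the support beyond two
  voxels.  Out-of-support voxels take physically neutral fills (-1000 HU,
  0 dose, 0 mask).
* The rotation round-trip (forward then backward) is interpolation-
  limited; for fields whose curvature is resolved (feature sigma at
  least ~7 voxels) the interior error stays below 2% of the maximum.
* Gamma normalization uses the maximum reference dose inside the analysis
  mask; an empty mask, a nonpositive reference, or zero evaluable voxels
  are errors, never silent NaNs.
* Rays without a threshold crossing are excluded from ARD pairing; ARD
  with no jointly finite rays is an error.
* A beam whose axis misses the body, a cropped PB dose with no positive
  values, or a CTV receiving no dose all raise immediate errors naming
  the condition.
* `build_sobp` rejects K < 2 and M outside (0, R), and refuses to return
  a model whose plateau ripples beyond ±2% (the fix is more peaks).

## Desk-scale acceptance experiment

The shipped end-to-end experiment runs at 16×24×24 voxels × 5 mm with 18
training and 6 test beams (6 + 2 plans), a 3-level 4+4-feature network,
and at most 60 epochs — small enough for a single CPU inside a test-suite
budget, while preserving the geometry (a ~100 mm head with centimetre
heterogeneities and 40–75 mm SOBP ranges).  This is a deliberate
scale-down of the full configuration (96×160×160 × 2 mm, hundreds of
beams, batch 4, 500 epochs), which remains available through the same
configuration objects.  What a green run establishes: the trained
rotation-arm converter is strictly closer to the MC-like ground truth
than the PB-like dose in mean MAE and mean gamma(3%/3 mm) on held-out
beams, and canonicalization does not hurt relative to the baseline arm.
What it does not establish: clinical magnitudes, behaviour on real
anatomy, or the full-scale ranking of the zoom-augmentation arm.

## Known limitations

* The simulator's PB degradation is a transparent surrogate (lateral WED
  averaging), not a PB kernel; its error structure is right in kind, not
  in detail.
* ARD at 5 mm voxels is noisy for steep distal edges (the R90 threshold
  crossing moves a large fraction of a voxel for small amplitude
  changes); range conclusions at desk scale are qualitative.
* Training at desk scale is data-limited; the converter's absolute gamma
  ceiling is set by the 18-beam training set, not by the architecture.
* The canonical-frame tensor must be divisible by 2^(levels-1); the
  package refuses other shapes rather than padding silently.
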