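---
title: "Automated myocardial perfusion preprocessing: models, choices, limits"
author: "perfusionkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated myocardial perfusion preprocessing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the processing
model and its assumptions, the parameters that matter, what the synthetic
phantom does and does not emulate, the numerical choices, and the known
limitations. The README shows the user-facing workflow; here we explain why
the pieces are the way they are.

## The processing problem

Quantitative first-pass perfusion MRI acquires one short-axis image per
heartbeat per slice while a gadolinium bolus transits the heart. Before any
tracer-kinetic model can be fit, four preprocessing decisions must be made
for every series: which timeframe shows peak left-ventricular (LV)
enhancement, where the LV is, which voxels are myocardium, and where the
right-ventricular (RV) insertion points lie (they anchor the AHA 16-segment
reporting convention). Done manually these steps take minutes per scan and
are operator-dependent; the pipeline automates all four with small
convolutional networks and then quantifies perfusion.

The stage order matters: the peak-enhancement frame has the highest SNR and
blood/tissue contrast, so segmentation and landmark detection run on that
single frame only, and the rest of the series inherits its geometry. This is
also why the pipeline is robust to a frame or two of error in peak
detection: neighbouring frames look nearly identical.

## Stage models and their assumptions

**Peak-frame classifier.** Input is the frame plus its two predecessors and
two successors (edge-replicated at the series boundaries), so the network
sees the local temporal derivative of enhancement, not just brightness.
Output is a two-unit softmax; the per-frame positive probability is scanned
and the argmax taken, ties broken toward the earlier frame (deterministic).
Assumption: one global bolus passage per series — the phantom guarantees it,
and clinical first-pass protocols are designed for it.

**Bounding box.** Direct corner regression is brittle, so the network
predicts a *delta* against a fixed 75×75 proposal centred in the image:
centre displacement (dx, dy, normalised by the proposal side for
conditioning) and width/height scale factors, trained with mean squared
error. `apply_delta()`/`invert_delta()` form an exact bijection, which the
tests verify to 1e-9. Only the basal slice is used: short-axis planning
stacks the slices along the LV axis, so one box covers all three. Boxes keep
continuous centres and are rasterized (half-open, clipped) only at crop
time, avoiding double rounding.

**Segmentation.** A U-Net (sigmoid head, soft-Dice loss with epsilon 1e-6 —
the published account optimises the Dice overlap but states no smoothing
constant) on the 96×96 crop of the peak frame. Postprocessing keeps the
largest 4-connected component. The closed-loop QC test operationalises "the
expected ring shape": the mask must be a single 4-connected component whose
complement, flood-filled from the border, leaves at least one unreached hole.
4-connectivity is the strictest and fully deterministic choice. On QC
failure the network is re-applied within ±2 frames of the peak, nearest
first; at equal distance the *later* frame is tried first because contrast
persists after the peak, so later frames are typically brighter. If all five
fail the run records a flagged failure rather than guessing.

**RV insertion points.** Direct coordinate regression and one-hot heatmaps
both struggle (location variance, class imbalance), so each landmark is
encoded as an *action map*: every pixel is labelled with the direction
(left/right/up/down) toward the landmark. The four class regions are
separated by the two diagonals of slope ±1 through the landmark; a U-Net
with a 4-way softmax learns the map, and inference fits one fixed-slope line
per diagonal to the class-partition boundaries and intersects them. Fixing
the slopes at ±1 is exact for the generating geometry; a free-slope fit adds
variance without reducing bias. Because a predicted map contains label
noise, the line fit centres on the *modal* boundary diagonal and averages
only an inlier band (±3 px): the true boundary concentrates on one diagonal
while noise scatters uniformly, so this is a mode filter, not a tuning knob.
Exact maps are unaffected. One network per landmark (anterior, inferior):
two independently testable binary tasks rather than one 8-class map.

**AIF extraction.** Region growing from the brightest peak-frame voxel
inside the endocardial interior (the hole enclosed by the myocardial mask),
admitting 4-neighbours above 90% of the seed signal. On the phantom the seed
provably lands in the LV pool and, in noiseless mode, the extracted curve
reproduces the generating input to 1e-6 on the native grid.

## The kinetic model

The two-compartment exchange model (2CXM) describes plasma and interstitial
compartments exchanging through the capillary wall:

$$v_p \frac{dC_p}{dt} = F_p (C_a - C_p) + PS (C_e - C_p), \qquad
  v_e \frac{dC_e}{dt} = PS (C_p - C_e), \qquad C_t = v_p C_p + v_e C_e.$$

Parameters: plasma flow $F_p$ (mL/min/mL; reported as MBF), plasma volume
fraction $v_p$, permeability–surface-area product $PS$ (mL/min/mL), and
interstitial volume fraction $v_e$. Per-minute flows are converted to s⁻¹
internally by the single constant 1/60. The forward solution is the
convolution of the AIF with the model's bi-exponential impulse response,
computed *exactly* for a piecewise-linear AIF by a recursive exponential
integrator; the tests pin it against an independent fine-step Runge–Kutta
integration to 1e-4 and better. Degenerate volumes ($v_p$, $v_e$, $PS$ or
$F_p$ zero) use their analytic limits rather than numerical nudges.

**Fitting.** Voxelwise hierarchical Bayesian inference is the published
route but is specified in other work and out of scope; the package fits by
bounded nonlinear least squares ($F_p \le 10$, $v_p \le 0.5$, $PS \le 5$,
$v_e \le 0.8$, soft constraint $v_p + v_e \le 1$) with five starts along the
diagonal of the parameter box. Two practical findings shaped the defaults:

* *Identifiability.* At 1 s temporal resolution with realistic noise the
  2CXM is weakly identifiable: we measured the sum of squares at a
  degenerate corner ($F_p$ at its bound, $v_p \to 0$ — effectively a Tofts
  model) *below* the value at the generating truth. This is precisely the
  pathology that motivates spatial priors in the literature. The package's
  remedy is `cxm_prior()`: a quadratic penalty anchoring only the volume
  fractions ($v_p$: mean 0.06, scale 0.05; $v_e$: mean 0.2, scale 0.15;
  weight 0.003, calibrated once on a single phantom subject), leaving $F_p$
  and $PS$ unpenalised. It is on by default in the pipeline and off in
  `fit_2cxm()`, whose noiseless parameter-recovery contract (Fp within 1%)
  is plain least squares.
* *Partial volume.* Crop resampling blends blood-pool signal into boundary
  myocardial voxels; the early, high-amplitude bolus shape then inflates
  fitted flow badly. Quantification therefore erodes the mask by two pixels
  before curve extraction (reduced automatically if a thin apical ring would
  lose a segment), and voxelwise maps flag fits whose $F_p$ lands on the
  upper bound as missing — in practice these are blood voxels, not tissue.

**Segment vs voxel mode.** `run_pipeline(fit_mode = "segment")` (default)
fits each AHA segment's mean concentration curve — the standard segmental
analysis, ~30× cheaper than voxelwise fitting and what the CPU budget of the
end-to-end tests requires. Averaging heterogeneous voxel curves biases the
effective flow slightly low (a concavity effect we measured at roughly
10–20% under the phantom's deliberately wide per-voxel parameter spread);
the bias is shared by any two arms compared in the same mode, so agreement
statistics are unaffected. `fit_mode = "voxel"` implements the voxelwise
contract and recovers noiseless per-segment truth within 10%.

## The phantom: what it emulates, what it does not

`generate_series()` renders, per subject, three slices (apical radii scaled
0.7, mid 0.85) at rest and stress: LV pool disk, myocardial annulus, an RV
crescent abutting the epicardium between the two insertion angles (120° and
240° by default), and a static body ellipse. Dynamics: the RV pool takes an
early gamma-variate bolus, the LV pool the same bolus delayed by 3 frames
(the configured rest/stress arrival times and shapes give a faster, earlier
stress input), and every myocardial voxel follows the 2CXM driven by the LV
input with parameters drawn uniformly per voxel ($F_p$ 0.5–1.5 at rest,
1.5–3.5 at stress — bracketing reported clinical means of ~0.9 and ~2.0
mL/min/mL; $v_p$ 0.03–0.08, $PS$ 0.8–1.5, $v_e$ 0.15–0.25). The signal
model is deliberately linear, $S = S_0(1 + \gamma C)$ with $\gamma = 0.3$,
so quantification is exactly invertible and round-trip tests can assert
1e-6. Noise is additive Gaussian at 5% of the baseline myocardial signal
(Rician available behind a flag); motion is off by default with an optional
per-frame rigid translation, and a cross-correlation rigid registration
utility is provided as the fallback counterpart of the (out-of-scope)
published motion-correction scheme.

A green end-to-end test therefore establishes that the *method* — windowed
peak classification, proposal-delta localisation, Dice-trained
segmentation with QC, action-map landmarks, region-grown AIF, 2CXM
quantification — works as specified on data whose truth is known exactly.
It does not establish clinical performance: the phantom has no
saturation-recovery signal nonlinearity, no dark-rim or k-t reconstruction
artefacts, no through-plane motion, no pathology (perfusion defects), and
its anatomy is far cleaner than a patient's. The published clinical figures
(peak-frame error 1.49 frames, box DSC 0.93, myocardial DSC 0.80,
insertion-point error 2.8 mm, ICC 0.89) come from a 175-patient dataset that
is not public and are not reproducible here; the repository's thresholds
(mean peak error ≤ 2 frames, box and mask DSC ≥ 0.85, landmark error ≤ 3 px,
ICC ≥ 0.90 against ground-truth-mask processing) are properties of the
synthetic world, intentionally not claims about patients.

## Training at desk scale

`train_config()` defaults are the published hyperparameters: batch 32, Adam
at 1e-4, L2 weight 0.001 on convolution kernels only, dropout 0.5 in the
fully-connected layers, early stopping with patience 3000 iterations. The
`"desk"` preset (batch 16, learning rate 1e-3, ~350 iterations, patience
150; U-Nets at batch 8 and ~220 iterations; the cheap box regressor gets a
longer 800-iteration schedule) trains all five networks in about ten
CPU-minutes on the 40-subject phantom cohort. Channel widths are
configuration, not contract — the published architecture defers its widths
to supplementary material — and the desk profile uses 8/16/24/32 (FC 64)
CNNs on 64×64 inputs and 3-level U-Nets with 6 base filters on the 96×96
crop. Augmentation applies the same random translation/rotation/scaling to
image and label (masks nearest-neighbour, points and boxes by the coordinate
transform) plus intensity gain and noise, all seeded. The peak classifier
trains on one positive and four random negative windows per series;
class-balanced sampling keeps the cross-entropy stable given one positive
frame per series.

## Numerical choices worth knowing

* Coordinates are 0-based (row, col), row increasing downward; boxes are
  half-open `[row_min, row_max) × [col_min, col_max)`; all modules share the
  convention, and crop/uncrop coordinate maps are exact inverses.
* Resampling: Catmull-Rom bicubic for images (identity when sizes match),
  nearest-neighbour for anything label-valued.
* Action-map ties (`|dr| == |dc|`, including the landmark pixel) go to the
  horizontal class, right when `dc >= 0`; any fixed rule works, this one is
  documented and tested.
* Batch-norm uses batch statistics in training and running
  (momentum 0.9) statistics at inference; the L2 penalty applies to
  convolution kernels only, asserted by a parameter-partition test.
* All randomness flows from explicit seeds: phantom subjects from a derived
  per-subject seed, training from `train_config(seed)`; identical seeds give
  bit-identical phantoms and byte-identical run manifests (manifests contain
  no timestamps).

## Limitations

* The signal model is linear; clinical saturation-recovery conversion and
  dual-bolus AIF correction are out of scope (an `--aif-scale`-style gamma
  parameter lets the AIF be rescaled externally).
* Bolus arrival delay between AIF and tissue is not fitted by default; the
  phantom generates none beyond what the 2CXM itself produces.
* The closed-loop QC test is our operationalisation of "the expected ring
  shape"; the original criterion is not published.
* Segmental fitting trades a known, shared, conservative bias for a ~30×
  runtime reduction; voxelwise mode exists and is tested, but is the slower
  path.
* No DICOM ingestion (NIfTI only), no GPU, no transfer learning.
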