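---
title: "One-shot 3D cine-MRI reconstruction: model, simulation and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-shot 3D cine-MRI reconstruction: model, simulation and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconstruction problem

Free-breathing 3D cine-MRI acquires one readout line (spoke) of radial
k-space every repetition time TR.  Grouping a handful of consecutive
spokes into a "frame" gives ~100 ms temporal resolution, but each frame
is then under-sampled by three orders of magnitude (a fully sampled 3D
radial scan of a 100^3 matrix needs ~24,674 spokes; a 17-spoke frame is
~1451x under-sampled).  Direct frame-by-frame reconstruction is
hopeless; the extra information has to come from a model of how the
frames relate to each other.

`cineinr` treats the cine series as a *joint reconstruction and
deformable registration* problem.  Every frame is a warped copy of one
complex-valued reference volume,

    z_t(x) = z_ref(x + d_t(x)),

with `d_t` a pull-back deformation vector field (DVF).  Respiratory
DVFs are further restricted to a patient-specific PCA motion model,

    d_t(x) = e0(x) + sum_{i=1..3} w_i(t) e_i(x),

where `e0` is the mean inter-phase DVF and `e_1..e_3` are the leading
principal components of the DVFs between respiratory bins of a 4D-MRI
(orthonormal in the Hilbert-space inner product).  The unknowns are
then one complex volume and nine scalars per frame (three components x
three Cartesian directions, the per-direction extension of the
composition above), instead of ~10^8 DVF degrees of freedom.

Both unknowns are represented by implicit neural representations
(INRs) with multiresolution hash encodings:

* the **spatial INR** maps a coordinate in `[-1,1]^3` through a
  hash-encoded feature vector into two small sine-activated MLPs
  (real and imaginary parts share the encoding);
* the **temporal INR** maps a scaled frame index through its own 1D
  hash encoding into nine parallel ReLU MLPs, one per PC weight.

Training is "one-shot": driven only by the acquired k-space data of
the scan being reconstructed, through a non-uniform FFT (NUFFT)
forward model, with no external training corpus.

## Progressive training

Optimizing everything from scratch jointly is fragile, so training is
staged:

1. **Stage 1** fits the spatial INR to a density-compensated adjoint
   NUFFT reconstruction of the end-of-exhale bin (image-domain mean
   squared complex error).  The bins come from self-navigation: the
   k-space-origin sample of every spoke is low-pass filtered
   (Kaiser-window FIR), PCA across channels selects the component with
   the largest 0.1–0.5 Hz band power, and the spokes are sorted into
   10 equal-count amplitude bins.
2. **Stage 2** refines the reference against the raw end-of-exhale
   k-space samples (mean squared sample error plus total-variation
   regularization of the magnitude), which suppresses the streak
   artifacts the adjoint target carries.
3. **Stage 3** activates the temporal INR: each step draws `N_batch`
   random frames, composes their DVFs from the motion model, warps the
   rendered reference, forward-projects onto each frame's spokes, and
   backpropagates the batched k-space loss (plus TV) jointly into both
   networks and both hash tables.

The PCA basis can be supplied *offline* (from a previously acquired
4D-MRI; in simulation, from the ground-truth phase DVFs) or built
*online* from the scan itself: adjoint reconstructions of the 10 bins
are registered to the exhale bin by the built-in multiresolution
demons registration and passed through `pca_basis()`.

## Tunable parameters

| Parameter | Default (paper profile) | Meaning |
|---|---|---|
| TR | 5.8 ms | time per spoke |
| spokes/frame | 17 | frame temporal resolution = TR x spokes (98.6 ms) |
| respiratory bins | 10 | amplitude bins for self-navigation |
| PCA components | 3 | motion-model rank |
| hash levels / table / features | 16 / 2^19 / 2 | multiresolution encoding (coarsest 16, finest 10509) |
| MLP widths | 32 | spatial 32-32-1 (sine), temporal 32-32-32-1 (ReLU) |
| learning rates | 1e-3, 2e-5, 2e-6 | per stage, optimizer state reset at stage boundaries |
| epochs | 500 / 1500 / 1000 | per stage |
| N_batch | 60 | frames per stage-3 step |
| lambda_TV | 7e-5 | TV weight (stages 2–3) |

The **desk profile** (`train_config("desk")`) is the scaled-down CPU
configuration used by all of the package's heavy tests: 48^3 grid at
4 mm, 200 frames, 8 hash levels with 2^14-entry tables (coarsest 16,
finest 96), NUFFT grid oversampling 4/3 with a width-6 Kaiser–Bessel
kernel, N_batch 20, and schedules of a few hundred epochs.  These
problem sizes keep a complete end-to-end study (simulation, two
reconstructions, evaluation) in the tens of minutes on one CPU core
while exercising every code path of the full-scale profile.

## The synthetic study

The package ships its own procedural deformable thorax phantom rather
than depending on licensed anatomy software: a body ellipsoid, two
low-intensity lungs, a liver/diaphragm dome bulging into the right
lung, and a 30 mm spherical lung tumor, with intensities in `[0, 1]`
(magnitude-only MR convention) and a crisp label mask.  Complex images
are produced by multiplying with `exp(i phi)` where `phi` is a
superposition of four random spatial sinusoids (wave numbers in
`[0.0033, 0.02] mm^-1`), min–max normalized to `[0, 2 pi]`.

Motion is generated from three analytic, orthogonal-by-construction
modes: a superior–inferior mode with unit amplitude at the diaphragm
plane and a cosine-squared decay toward the apex, an
anterior–posterior chest-wall expansion, and a small left–right mode.
The diaphragm trace follows the classical `sin^4` breathing waveform
(5 s period, 20 mm peak-to-peak, exhale dwell at zero), with per-cycle
multiplicative Gaussian amplitude jitter (10% SD) and scenario
variants: baseline steps (e.g. -7 mm at 90 s), period/amplitude
changes, slow decaying breathing, and combinations (S1–S6).  The AP
and LR modes are driven by lagged copies of the trace (0.35 s and
0.70 s; ~30% and ~15% of the SI amplitude).  The lags keep the
generator linear in the trace while making the three weight courses
linearly independent, so the inter-phase DVF set has full rank 3 —
the feature the PCA model needs.  These coupling values follow the
commonly reported AP/LR-to-SI motion ratios for lower-lung/liver
anatomy.

What the generator deliberately does **not** emulate: anatomically
realistic tissue contrast, cardiac motion, intensity changes from
contrast agents (excluded by the quasi-static intensity assumption of
the warping model), coil-array geometry (a single uniform coil is
used), gradient imperfections, and noise by default (a complex
Gaussian noise option exists).  Passing tests on this phantom
demonstrates that the *estimator* works under its stated model; it
does not certify performance on clinical data, where intensity
non-stationarities, coil effects and imperfect motion models add
error sources the simulation excludes.

## Numerical choices

* **NUFFT.**  Kaiser–Bessel gridding on an oversampled FFT grid
  (factor 2 by default, width-6 kernel, Beatty's shape parameter,
  closed-form deapodization).  The adjoint is the exact algebraic
  transpose of the forward operator, so the adjoint identity holds to
  machine precision.  For gridding *reconstruction*
  (`nufft_adjoint`), density compensation defaults to `"auto"`:
  Pipe–Menon iterative refinement where the sampled k-space ball is at
  or above Nyquist density (it corrects the discrete-shell structure
  near the origin and the residual golden-mean non-uniformity), and
  the analytic radial `|k|^2` weights in the under-sampled regime,
  where the iterative density estimate is unreliable and inflates
  amplitudes.  The desk profile uses oversampling 4/3 on the training
  path; the forward-model error this introduces sits well below the
  optimization error of the training itself.
* **Self-navigation channels.**  The navigator uses the real and
  imaginary parts of the k-space-origin sample as separate channels
  per coil.  With many coils this carries the same information as
  per-coil moduli; with a single uniform coil the modulus alone
  discards the phase-encoded part of the respiratory modulation and
  correlates poorly with the true trace, while the complex navigator
  recovers it.
* **Exhale-bin identification.**  Breathing dwells at the exhale
  plateau, so the extreme decile of the surrogate on the exhale side
  is densely clustered in amplitude; the package compares the two
  extreme-decile widths (ties default to the upper extremum).
* **Zero-phase filtering.**  The Kaiser FIR designed for 60 dB
  attenuation and a 0.5 Hz transition at the spoke rate has ~600 taps;
  it is applied in one pass by FFT convolution with mirror padding and
  exact group-delay compensation, which is zero-phase for a symmetric
  FIR.
* **TV regularization** is anisotropic (L1 of forward differences of
  the magnitude, zero at the far boundary) so hand-checkable exact
  values exist; the isotropic form is available by flag.
* **PCA layout.**  One SVD over the concatenated (x, y, z) DVF
  components (joint PCA) with per-direction weighting at composition
  time — the per-direction reading of the nine temporal outputs.  A
  per-direction-PCA variant is available (`per_direction = TRUE`).
* **PC-weight whitening.**  The basis components have unit Hilbert
  norm, so physical PC coefficients reach O(10^3) while a
  zero-initialized output head moves O(learning rate) per step.
  Stage 3 therefore scales the temporal INR outputs by
  `sigma_i / sqrt(N_train)` (the per-component singular value of the
  training DVF matrix); reported weight traces are on the physical
  scale.  Without this, the weak components effectively never train.
* **Warping** is trilinear pull-back interpolation applied separately
  to real and imaginary parts, zero outside the grid, with analytic
  gradients with respect to both the reference and the displacement
  (required for the joint stage-3 updates).  Mask propagation uses the
  same interpolation with a 0.5 threshold, so tracking metrics are
  exactly consistent with the imaging operator.
* **Registration.**  The built-in inter-phase registration is a
  three-level demons scheme (Gaussian-regularized update and total
  fields, step-limited updates, best-so-far fallback with a warning if
  the residual stops decreasing).  The exhale entry is identically
  zero by construction.  Ground-truth or externally computed DVFs can
  be injected through `inter_phase_set()`.
* **Hash encoding.**  Levels grow geometrically between the coarsest
  and finest resolutions; a level is indexed directly (collision-free,
  row-major) when its vertex grid fits in the table and by the XOR
  spatial hash with primes `(1, 2654435761, 805459861)` otherwise.
  The 1D temporal encoding is always collision-free at these sizes.
  Table entries initialize uniform in `[-1e-4, 1e-4]`; the sine MLPs
  use omega0 = 30 with SIREN-style initialization; temporal output
  heads start at zero so training begins from the mean-DVF state.
  Frame indices are perturbed with Gaussian noise of half the scaled
  frame interval during stage 3 to force a continuous temporal
  representation.
* **Degenerate inputs.**  Constant surrogates, empty respiratory bins,
  all-identical inter-phase DVFs, zero ground-truth images and empty
  masks raise errors (or flagged warnings where the spec of the
  operation calls for a soft failure, e.g. empty propagated masks).

## Design questions that were genuinely open

* The amplitude-jitter distribution and exact waveform family of the
  breathing scenarios: `sin^4` with per-cycle multiplicative Gaussian
  jitter was chosen as the standard respiratory model with an exhale
  dwell; scenario presets implement the documented family
  characteristics only.
* Amplitude vs phase binning for the online 4D-MRI: amplitude
  (equal-count quantile) binning is used.
* Whether one epoch in stages 1–2 means a full pass or a subset: one
  epoch = one full-grid step (stage 1) / one spoke-subset step
  (stage 2, subset size configurable).
* Shared vs separate learning rates for hash tables and MLPs: shared.
* The temporal MLP output activation: linear.

## Known limitations

* Per-direction PC weights are only constrained by the data where the
  corresponding component has energy in that direction; comparisons
  against ground truth therefore use the three per-component
  projections of the composed DVFs (`recon_pc_trace()`), which is the
  well-posed quantity.
* The weakest motion component (sub-millimetre amplitudes at the
  fixture scale) is recovered with visibly lower fidelity than the
  dominant superior-inferior component — expected, since its k-space
  footprint at 17 spokes/frame is tiny.
* The demons registration is intensity-based and mono-modal; the
  online motion model inherits the artifact level of the bin
  reconstructions.
* Reconstruction is offline (the whole k-space series is consumed);
  streaming/real-time operation is out of scope.
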