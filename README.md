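# cineinr

One-shot reconstruction of free-breathing 3D cine-MRI from extremely
under-sampled 3D golden-mean radial (Koosh-ball) k-space, in R.

## The problem

Time-resolved volumetric MRI of breathing anatomy is a core need of
MRI-guided radiotherapy: a 30 mm lung or liver tumor moves by 1–2 cm
every breath, and treatment margins shrink dramatically if that motion
can be imaged rather than assumed.  At ~100 ms per volume, however,
each cine frame contains only a handful of radial spokes — three
orders of magnitude below Nyquist (a fully sampled 3D radial scan of a
100³ matrix needs ~24,674 spokes; 17 spokes per frame is an
under-sampling ratio of ~1451).

`cineinr` reconstructs the whole series jointly by modelling every
frame as a deformed copy of one reference volume,

    z_t(x) = z_ref(x + d_t(x)),      d_t(x) = e0(x) + Σ_i w_i(t) e_i(x),

where `e0, e_1..e_3` form a PCA respiratory motion model (mean plus
leading principal components of inter-phase deformation fields) and
`w_i(t)` are per-frame weights.  The reference volume is represented
by a spatial implicit neural representation (multiresolution hash
encoding feeding two small sine-activated MLPs for the real and
imaginary image parts); the weight traces by a temporal INR (1D hash
encoding feeding nine parallel ReLU MLPs).  Both are trained
one-shot — from the acquired k-space data alone, through a
Kaiser–Bessel gridding NUFFT forward model — in three progressive
stages: (1) image-domain fit to an adjoint reconstruction of the
self-navigated end-of-exhale bin, (2) k-space refinement of the
reference with total-variation regularization, (3) joint
reference+motion training on randomly batched frames.

The package also contains everything needed to exercise the method
without external data: a procedural deformable thorax phantom with a
spherical lung tumor, breathing scenarios (amplitude jitter, baseline
shifts, period changes, slow breathing), complex phase-modulation
simulation, golden-mean Koosh-ball trajectories, acquisition
simulation, self-navigated respiratory binning, a built-in
multiresolution demons registration for the online motion model, and
evaluation metrics (relative error, Dice, tumor center-of-mass error,
sharpness variance).

## A worked example

A complete desk-scale study — 48³ grid at 4 mm, 200 frames at 98.6 ms
(TR 5.8 ms, 17 spokes/frame), S1-style breathing with 20 mm
peak-to-peak diaphragm motion — runs in a few minutes on one CPU core:

```r
library(cineinr)

ds  <- desk_study(n_frames = 200, seed = 1)   # phantom + k-space series
cfg <- train_config("desk", seed = 2)

# recovered PC-weight traces vs the generator's coefficients
rec <- reconstruct(ds$ks, cfg, basis_source = "offline",
                   basis = as_pca_basis(ds$basis_true))
proj <- recon_pc_trace(rec)
min(abs(diag(cor(proj, ds$cine$weights))))
#> [1] 0.9926395

# image accuracy across the series, against per-frame gridding
fr <- round(seq(1, 200, length.out = 25))
mean(sapply(fr, function(t)
  relative_error(recon_frame(rec, t)$data, cine_frame(ds$cine, t)$data)))
#> [1] 0.1863566
```

Reading: all three PC-weight traces are recovered with correlation at
least 0.99 against the generating coefficients.  A mean frame relative
error of ~0.19 compares with ~1.7 for frame-by-frame adjoint gridding
of the same 17-spoke frames.  Tumor tracking — contouring the tumor on
the reconstructed reference (`segment_reference_mask()`) and
propagating it through the recovered fields — stays sub-voxel on the
same run: mean center-of-mass error 0.81 mm, 95th percentile 1.94 mm
at 4 mm voxels.

A thin command-line front end sits in `inst/cli/cineinr`
(`simulate`, `recon`, `eval` subcommands).

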