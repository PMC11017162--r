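#' Ground-truth inter-phase DVFs of one clean breathing cycle
#'
#' Samples one jitter-free breathing cycle at `n_bins` phase points and
#' composes the corresponding DVFs relative to the end-of-exhale phase
#' (phase 0), mirroring how a previously acquired, motion-binned 4D-MRI
#' provides inter-phase fields for the offline motion model.
#'
#' @param basis a `dvf_basis` from [make_analytic_basis()].
#' @param peak_to_peak_mm diaphragm peak-to-peak amplitude.
#' @param period_s breathing period.
#' @param n_bins number of phases (default 10).
#' @param couplings,lags_s as in [render_cine()].
#' @return An `inter_phase_dvfs` with `exhale_bin = 1`.
#' @export
offline_phase_dvfs <- function(basis, peak_to_peak_mm = 20, period_s = 5,
                               n_bins = 10,
                               couplings = c(ap = 0.30, lr = 0.15),
                               lags_s = c(ap = 0.35, lr = 0.70)) {
  # two cycles so the lagged copies are defined; keep the second cycle
  spec <- scenario_spec("custom", period_s = period_s,
                        peak_to_peak_mm = peak_to_peak_mm,
                        amplitude_jitter = 0)
  dt_ms <- period_s * 1000 / n_bins
  trace <- make_motion_trace(spec, duration_s = 2 * period_s, dt_ms = dt_ms)
  ref <- complex_volume(array(0i, basis$dims), basis$voxel_mm)  # geometry only
  cine <- render_cine(ref, basis, trace, couplings, lags_s)
  idx <- n_bins + seq_len(n_bins)
  dvfs <- lapply(idx, function(t) cine_dvf(cine, t))
  inter_phase_set(dvfs, exhale_bin = 1L)
}

#' Standard desk-scale simulation study
#'
#' Builds the package's reference CPU-scale experiment in one call: a
#' 48^3 thorax phantom at 4 mm with a 30 mm lung tumor, complex phase
#' modulation (four random sinusoids), an S1-style breathing trace
#' (5 s period, 20 mm peak-to-peak, 10% per-cycle jitter) sampled at the
#' 98.6 ms frame resolution (TR 5.8 ms, 17 spokes per frame), golden-mean
#' Koosh-ball readouts with 49 points per spoke, and the noise-free
#' k-space series of `n_frames` frames.  Also returns the offline PCA
#' motion model derived from one clean 10-phase breathing cycle, and the
#' true per-frame PC-weight projections.
#'
#' @param n_frames number of cine frames (default 200).
#' @param dims grid size (default 48).
#' @param seed master seed (phase map, jitter).
#' @param scenario_id breathing scenario (default "S1").
#' @param noise_sd complex noise SD for the acquisition (default 0).
#' @param oversamp NUFFT oversampling used for data simulation.
#' @return list with the phantom, reference volume, analytic basis,
#'   trace, ground-truth cine, k-space series, tumor mask, offline
#'   inter-phase DVFs and [pca_basis()], and the true weight trace
#'   (`n_frames` x 3 projections onto the offline basis).
#' @export
desk_study <- function(n_frames = 200, dims = c(48, 48, 48), seed = 1,
                       scenario_id = "S1", noise_sd = 0, oversamp = 4 / 3) {
  dims <- as.integer(dims)
  voxel_mm <- 4
  phant <- build_reference_phantom(dims, voxel_mm, tumor_diameter_mm = 30)
  phase <- simulate_phase_map(dims, voxel_mm, seed = seed + 11)
  reference <- apply_phase(phant, phase)
  basis_true <- make_analytic_basis(dims, voxel_mm)

  TR_ms <- 5.8
  spf <- 17L
  dt_ms <- frame_temporal_resolution(TR_ms, spf)
  duration_s <- n_frames * dt_ms / 1000
  spec <- scenario_spec(scenario_id, seed = seed + 23)
  trace <- make_motion_trace(spec, duration_s = duration_s, dt_ms = dt_ms)
  cine <- render_cine(reference, basis_true, trace)

  nr <- 2L * (dims[1] %/% 2L) + 1L
  traj <- make_trajectory(n_frames * spf, nr)
  acq <- acq_config(TR_ms = TR_ms, spokes_per_frame = spf,
                    readout_points = nr, duration_s = duration_s,
                    noise_sd = noise_sd)
  plan <- nufft_plan(dims, oversamp = oversamp)
  ks <- simulate_acquisition(cine, traj, coils = NULL, acq = acq,
                             seed = seed + 31, plan = plan)

  offline <- offline_phase_dvfs(basis_true)
  basis_offline <- pca_basis(offline$dvfs, n_pc = 3)
  true_weights <- t(vapply(seq_len(cine$n_t),
                           function(t) project_dvf(basis_offline,
                                                   cine_dvf(cine, t)),
                           numeric(3)))
  list(phantom = phant, reference = reference, basis_true = basis_true,
       trace = trace, cine = cine, traj = traj, acq = acq, ks = ks,
       tumor_mask = phant$labels == 4L,
       offline_dvfs = offline, basis_offline = basis_offline,
       true_weights = true_weights, plan = plan, dims = dims,
       voxel_mm = voxel_mm)
}
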