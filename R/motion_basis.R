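#' Analytic respiratory motion modes
#'
#' Constructs three smooth, orthogonal-by-construction displacement modes
#' used as the simulation-side motion basis: (1) a superior-inferior mode
#' with unit amplitude at the diaphragm plane, decaying smoothly (cosine
#' taper) toward the lung apex; (2) an anterior-posterior chest-wall
#' expansion mode; (3) a small left-right mode.  The modes live on
#' disjoint Cartesian components, so their pairwise Hilbert-space inner
#' products vanish by construction.  Each returned mode has unit
#' Hilbert-space norm; `gains` records the peak amplitude of each
#' normalized mode so that a physical displacement of `A` mm maps to the
#' weight `A / gains[i]`.
#'
#' @param dims voxel counts per axis.
#' @param voxel_mm voxel size in mm.
#' @param diaphragm_plane 0-based z index of the diaphragm plane
#'   (default `0.42 * nz`).
#' @param decay_length_mm decay length of the SI taper toward the apex.
#' @return An object of class `dvf_basis`: list of three unit-norm
#'   [dvf_field()] `modes`, numeric `gains`, and grid metadata.
#' @export
make_analytic_basis <- function(dims, voxel_mm, diaphragm_plane = NULL,
                                decay_length_mm = 80) {
  dims <- as.integer(dims)
  voxel_mm <- normalize_voxel_mm(voxel_mm)
  stopifnot(decay_length_mm > 0)
  if (is.null(diaphragm_plane)) diaphragm_plane <- round(0.42 * dims[3])

  z <- seq_len(dims[3]) - 1
  dz_mm <- (z - diaphragm_plane) * voxel_mm[3]
  # 1 at and below the diaphragm plane, cosine-squared taper above
  taper <- ifelse(dz_mm <= 0, 1,
                  ifelse(dz_mm >= decay_length_mm, 0,
                         cos(pi / 2 * dz_mm / decay_length_mm)^2))
  # lateral modes act where the lungs/chest wall are: taper peaked over
  # the thoracic z-range, zero well below the diaphragm
  chest <- exp(-0.5 * ((z - (diaphragm_plane + 0.18 * dims[3])) /
                         (0.22 * dims[3]))^2)

  x1 <- (seq_len(dims[1]) - 1 - (dims[1] - 1) / 2) / ((dims[1] - 1) / 2)
  y1 <- (seq_len(dims[2]) - 1 - (dims[2] - 1) / 2) / ((dims[2] - 1) / 2)

  zero <- array(0, dims)
  m1 <- array(0, c(dims, 3))
  m1[, , , 3] <- array(rep(taper, each = dims[1] * dims[2]), dims)

  m2 <- array(0, c(dims, 3))
  ap <- outer(rep(1, dims[1]), y1)           # AP expansion about the midline
  m2[, , , 2] <- outer(ap, chest)

  m3 <- array(0, c(dims, 3))
  lr <- outer(x1, rep(1, dims[2]))
  m3[, , , 1] <- outer(lr, chest)

  modes <- lapply(list(m1, m2, m3), function(v) dvf_field(v, voxel_mm))
  gains <- numeric(3)
  for (i in 1:3) {
    nrm <- dvf_norm(modes[[i]])
    modes[[i]]$vectors <- modes[[i]]$vectors / nrm
    gains[i] <- max(abs(modes[[i]]$vectors))
  }
  structure(list(modes = modes, gains = gains, dims = dims,
                 voxel_mm = voxel_mm, diaphragm_plane = diaphragm_plane),
            class = "dvf_basis")
}

#' Compose a DVF from basis modes and weights
#' @param basis a `dvf_basis`.
#' @param w numeric weight per mode.
#' @return A [dvf_field()].
#' @keywords internal
basis_combine <- function(basis, w) {
  acc <- array(0, c(basis$dims, 3))
  for (i in seq_along(basis$modes))
    if (w[i] != 0) acc <- acc + w[i] * basis$modes[[i]]$vectors
  dvf_field(acc, basis$voxel_mm)
}

#' Render a ground-truth cine sequence from a motion trace
#'
#' Maps the diaphragm trace to per-frame pull-back DVFs as a trace-scaled
#' linear combination of the basis modes, and represents the cine frames
#' lazily as warps of the reference: frame `t` equals
#' `warp_volume(reference, dvfs[t])`.  The SI mode is driven by the trace
#' itself; the AP and LR modes are driven by lagged copies of the trace
#' (respiratory hysteresis), keeping the mapping linear in the trace while
#' making the three weight courses linearly independent.  A zero trace
#' amplitude (the end-of-exhale state) maps to the zero DVF.
#'
#' @param reference a [complex_volume()] (the end-of-exhale frame).
#' @param basis a `dvf_basis` from [make_analytic_basis()].
#' @param trace a [make_motion_trace()] result.
#' @param couplings AP and LR coupling fractions relative to the SI
#'   amplitude.
#' @param lags_s AP and LR hysteresis lags in seconds.
#' @return An object of class `ground_truth_cine` holding the reference,
#'   the basis, the per-frame weight matrix (`n_t` x 3), and timestamps.
#' @export
render_cine <- function(reference, basis, trace,
                        couplings = c(ap = 0.30, lr = 0.15),
                        lags_s = c(ap = 0.35, lr = 0.70)) {
  stopifnot(inherits(reference, "complex_volume"),
            inherits(basis, "dvf_basis"), inherits(trace, "motion_trace"))
  if (!identical(as.integer(reference$dims), basis$dims))
    stop("reference and basis grids do not match")
  a <- trace$amplitude
  t_s <- trace$time_s
  a_ap <- linear_interp1(t_s, a, t_s - lags_s[["ap"]])
  a_lr <- linear_interp1(t_s, a, t_s - lags_s[["lr"]])
  # pull-back sign: anatomy shifted by s is sampled at x - s, d = -s
  W <- cbind(-a / basis$gains[1],
             -couplings[["ap"]] * a_ap / basis$gains[2],
             -couplings[["lr"]] * a_lr / basis$gains[3])
  structure(list(reference = reference, basis = basis, weights = W,
                 trace = trace, timestamps_ms = (t_s * 1000),
                 n_t = trace$n_t, dims = basis$dims,
                 voxel_mm = basis$voxel_mm),
            class = "ground_truth_cine")
}

#' Ground-truth DVF of one cine frame
#' @param cine a `ground_truth_cine`.
#' @param t frame index (1-based).
#' @return A [dvf_field()].
#' @export
cine_dvf <- function(cine, t) {
  stopifnot(t >= 1, t <= cine$n_t)
  basis_combine(cine$basis, cine$weights[t, ])
}

#' Materialize one cine frame
#' @param cine a `ground_truth_cine`.
#' @param t frame index (1-based).
#' @return A [complex_volume()] equal to `warp_volume(reference, cine_dvf(cine, t))`.
#' @export
cine_frame <- function(cine, t) {
  warp_volume(cine$reference, cine_dvf(cine, t))
}
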