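#' Procedural deformable thorax phantom
#'
#' Builds a thorax-like magnitude phantom on a regular grid: a body
#' ellipsoid of soft tissue, two low-intensity lungs, a liver/diaphragm
#' dome bulging into the right lung, and (optionally) a bright spherical
#' lung tumor.  Intensities are normalized magnitude values in `[0, 1]`,
#' mimicking magnitude-only MR images.  The construction is fully
#' deterministic given its arguments.
#'
#' Axis convention: axis 1 = left-right (LR), axis 2 = anterior-posterior
#' (AP), axis 3 = inferior-superior (SI, index increasing toward the
#' head).  The diaphragm edge is the top of the liver dome.
#'
#' @param dims voxel counts per axis (each >= 16).
#' @param voxel_mm isotropic or per-axis voxel size in mm.
#' @param tumor_diameter_mm tumor diameter in mm (0 = no tumor).
#' @param tumor_center_voxel 0-based voxel coordinates of the tumor
#'   center; default places it in the lower lobe of the right lung.
#' @param smooth_sigma_vox Gaussian band-limiting width (voxels) applied
#'   to the intensity image (labels are kept crisp); 0 disables.
#' @return A [mag_volume()] whose `labels` encode 0 = background,
#'   1 = body, 2 = lung, 3 = liver, 4 = tumor.
#' @export
build_reference_phantom <- function(dims = c(100, 100, 100), voxel_mm = 4,
                                    tumor_diameter_mm = 30,
                                    tumor_center_voxel = NULL,
                                    smooth_sigma_vox = 0.7) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L)
  if (any(dims < 16L)) stop("dims must be >= 16 per axis")
  voxel_mm <- normalize_voxel_mm(voxel_mm)
  if (tumor_diameter_mm < 0) stop("tumor diameter must be >= 0")

  idx <- index_grid(dims)
  # normalized coordinates in [0, 1] per axis (voxel centres)
  q1 <- (idx[, 1] + 0.5) / dims[1]
  q2 <- (idx[, 2] + 0.5) / dims[2]
  q3 <- (idx[, 3] + 0.5) / dims[3]

  labels <- integer(nrow(idx))
  vals <- numeric(nrow(idx))

  body <- ((q1 - 0.5) / 0.42)^2 + ((q2 - 0.5) / 0.36)^2 <= 1 &
    q3 > 0.04 & q3 < 0.96
  vals[body] <- 0.45
  labels[body] <- 1L

  lung <- rep(FALSE, nrow(idx))
  for (cx in c(0.32, 0.68)) {
    ell <- ((q1 - cx) / 0.155)^2 + ((q2 - 0.48) / 0.21)^2 +
      ((q3 - 0.64) / 0.26)^2 <= 1
    lung <- lung | ell
  }
  lung <- lung & body
  vals[lung] <- 0.15
  labels[lung] <- 2L

  # liver / diaphragm dome: fills the right (cx = 0.68) inferior region up
  # to a dome surface that cuts into the right lung.
  dome <- 0.40 + 0.10 * exp(-(((q1 - 0.68) / 0.12)^2 + ((q2 - 0.48) / 0.16)^2))
  liver <- body & q1 > 0.5 & q3 < dome & q3 > 0.08
  vals[liver] <- 0.75
  labels[liver] <- 3L

  tumor <- rep(FALSE, nrow(idx))
  if (tumor_diameter_mm > 0) {
    if (is.null(tumor_center_voxel))
      tumor_center_voxel <- round(c(0.68, 0.48, 0.60) * dims)
    tc <- as.numeric(tumor_center_voxel)
    r_vox <- (tumor_diameter_mm / 2) / voxel_mm   # per-axis radius in voxels
    if (any(tc - r_vox < 0) || any(tc + r_vox > dims - 1))
      stop("tumor does not fit inside the grid")
    lab3 <- array(labels, dims)
    cl <- lab3[round(tc[1]) + 1, round(tc[2]) + 1, round(tc[3]) + 1]
    if (cl != 2L)
      stop("tumor center must lie inside the lung region")
    d2 <- ((idx[, 1] - tc[1]) / r_vox[1])^2 + ((idx[, 2] - tc[2]) / r_vox[2])^2 +
      ((idx[, 3] - tc[3]) / r_vox[3])^2
    tumor <- d2 <= 1
    vals[tumor] <- 1.0
    labels[tumor] <- 4L
  }

  vol <- array(vals, dims)
  if (smooth_sigma_vox > 0) {
    vol <- array(gaussian_smooth3(as.vector(vol), dims, smooth_sigma_vox), dims)
    vol <- pmin(pmax(vol, 0), 1)
  }
  mag_volume(vol, voxel_mm, labels = array(labels, dims))
}

#' Smooth random phase map for complex-image simulation
#'
#' Superposes `n_waves` spatial sinusoids with wave numbers drawn
#' uniformly from `k_range_mm_inv`, uniformly random unit-vector
#' orientations and uniform phase shifts, then min-max normalizes the sum
#' to `[0, 2*pi]`.  Deterministic given `seed`.
#'
#' @param dims voxel counts per axis.
#' @param voxel_mm voxel size in mm.
#' @param n_waves number of sinusoids (default 4).
#' @param k_range_mm_inv wave-number range in 1/mm.
#' @param seed RNG seed.
#' @param orientations,wave_numbers,phases optional explicit overrides
#'   (each per wave) replacing the random draws, for controlled tests.
#' @param normalize if `FALSE`, return the raw superposition without the
#'   min-max normalization.
#' @return 3D numeric array, values in `[0, 2*pi]` when normalized.
#' @export
simulate_phase_map <- function(dims, voxel_mm, n_waves = 4,
                               k_range_mm_inv = c(0.0033, 0.02), seed = 1,
                               orientations = NULL, wave_numbers = NULL,
                               phases = NULL, normalize = TRUE) {
  dims <- as.integer(dims)
  if (any(dims < 1L)) stop("zero-size grid")
  stopifnot(n_waves >= 1, k_range_mm_inv[1] > 0,
            k_range_mm_inv[1] <= k_range_mm_inv[2])
  voxel_mm <- normalize_voxel_mm(voxel_mm)
  draws <- with_seed(seed, {
    list(orient = random_unit_vectors(n_waves),
         k = runif(n_waves, k_range_mm_inv[1], k_range_mm_inv[2]),
         phi = runif(n_waves, 0, 2 * pi))
  })
  if (!is.null(orientations)) draws$orient <- matrix(orientations, ncol = 3)
  if (!is.null(wave_numbers)) draws$k <- wave_numbers
  if (!is.null(phases)) draws$phi <- phases

  idx <- index_grid(dims)
  pos_mm <- sweep(idx, 2L, voxel_mm, "*")
  acc <- numeric(nrow(idx))
  for (w in seq_len(n_waves)) {
    proj <- pos_mm %*% draws$orient[w, ]
    acc <- acc + sin(2 * pi * draws$k[w] * proj + draws$phi[w])
  }
  if (normalize) {
    rng <- range(acc)
    if (rng[2] > rng[1]) acc <- (acc - rng[1]) / (rng[2] - rng[1]) * 2 * pi
    else acc <- rep(0, length(acc))
  }
  array(acc, dims)
}

#' Apply a phase map to a magnitude volume
#'
#' Forms the complex-valued image `m(x) * exp(i * phi(x))`; the modulus of
#' the result equals the input magnitude to float tolerance.
#'
#' @param mag a [mag_volume()].
#' @param phase_map numeric array of matching dims (radians).
#' @return A [complex_volume()].
#' @export
apply_phase <- function(mag, phase_map) {
  stopifnot(inherits(mag, "mag_volume"))
  if (!identical(dim(phase_map), dim(mag$data)))
    stop("phase map shape does not match the magnitude volume")
  complex_volume(mag$data * exp(1i * phase_map), mag$voxel_mm)
}
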