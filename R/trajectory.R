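#' Golden-mean Koosh-ball spoke directions
#'
#' Quasi-uniform unit vectors on the sphere ordered by the 2D golden-mean
#' scheme: spoke `m` has z-component `2 * frac(m * phi1) - 1` and azimuth
#' `2 * pi * frac(m * phi2)` with `phi1 = 0.4656`, `phi2 = 0.6823` (the
#' modified-Fibonacci golden means).  The sequence is deterministic and
#' order-dependent: consecutive subsets of any length remain quasi-uniform,
#' which is what makes the trajectory suitable for retrospective motion
#' binning.
#'
#' @param n_spokes number of spokes (>= 1).
#' @param offset index of the first spoke (default 0), so a long scan can
#'   be generated in chunks.
#' @return `n_spokes` x 3 matrix of unit vectors.
#' @export
koosh_ball_directions <- function(n_spokes, offset = 0) {
  if (n_spokes < 1) stop("n_spokes must be >= 1")
  phi1 <- 0.4656
  phi2 <- 0.6823
  m <- offset + seq_len(n_spokes) - 1
  z <- 2 * ((m * phi1) %% 1) - 1
  th <- 2 * pi * ((m * phi2) %% 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(th), r * sin(th), z)
}

#' Radial Koosh-ball trajectory
#'
#' Spoke directions plus the shared readout sampling: an odd number of
#' uniformly spaced samples per spoke spanning `[-k_max, k_max]`
#' cycles/voxel with the middle sample exactly at the k-space origin (the
#' self-navigation navigator).
#'
#' @param n_spokes total number of spokes.
#' @param readout_points samples per spoke (odd).
#' @param k_max maximum spatial frequency in cycles/voxel (default 0.5,
#'   the grid Nyquist limit).
#' @return An object of class `trajectory` with `dirs`, `radii`,
#'   `readout_points`.
#' @export
make_trajectory <- function(n_spokes, readout_points, k_max = 0.5) {
  stopifnot(readout_points >= 3, k_max > 0, k_max <= 0.5)
  if (readout_points %% 2 == 0)
    stop("readout_points must be odd so one sample sits exactly at k = 0")
  structure(list(dirs = koosh_ball_directions(n_spokes),
                 radii = seq(-k_max, k_max, length.out = readout_points),
                 n_spokes = as.integer(n_spokes),
                 readout_points = as.integer(readout_points),
                 k_max = k_max),
            class = "trajectory")
}

#' k-space coordinates of a subset of spokes
#' @param traj a `trajectory`.
#' @param spokes spoke indices (1-based).
#' @return `(readout_points * length(spokes))` x 3 matrix, readout
#'   fastest-varying, in cycles/voxel.
#' @export
spoke_coords <- function(traj, spokes) {
  d <- traj$dirs[spokes, , drop = FALSE]
  nr <- traj$readout_points
  ns <- nrow(d)
  cbind(as.vector(outer(traj$radii, d[, 1])),
        as.vector(outer(traj$radii, d[, 2])),
        as.vector(outer(traj$radii, d[, 3])))
}

#' Nyquist spoke count for a fully sampled 3D radial scan
#'
#' Estimated by assuming uniform sampling of the polar and azimuthal
#' angles: `round((pi * n_azim / 2) * (pi * n_polar / 2))` spokes for a
#' matrix with `n_azim` in-plane and `n_polar` through-plane samples.
#'
#' @param n_azim,n_polar matrix sizes.
#' @return integer spoke count.
#' @export
full_spoke_count <- function(n_azim, n_polar) {
  stopifnot(n_azim > 0, n_polar > 0)
  round((pi * n_azim / 2) * (pi * n_polar / 2))
}

#' Radial under-sampling ratio
#'
#' Ratio of the Nyquist spoke count to the spokes actually used per frame.
#'
#' @param n_azim,n_polar matrix sizes.
#' @param spokes_per_frame spokes per cine frame (>= 1).
#' @return numeric ratio.
#' @export
undersampling_ratio <- function(n_azim, n_polar, spokes_per_frame) {
  stopifnot(spokes_per_frame >= 1)
  full_spoke_count(n_azim, n_polar) / spokes_per_frame
}

#' Frame temporal resolution
#' @param TR_ms repetition time per readout line in ms.
#' @param spokes_per_frame spokes per frame.
#' @return frame duration in ms (`TR_ms * spokes_per_frame`).
#' @export
frame_temporal_resolution <- function(TR_ms, spokes_per_frame) {
  stopifnot(TR_ms > 0, spokes_per_frame > 0)
  TR_ms * spokes_per_frame
}
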