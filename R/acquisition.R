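#' Coil sensitivity profile
#'
#' @param sens complex 4D array `c(dims, n_coils)` of sensitivities.
#' @return An object of class `coil_profile`.
#' @export
coil_profile <- function(sens) {
  stopifnot(is.array(sens), length(dim(sens)) == 4L)
  if (!is.complex(sens)) storage.mode(sens) <- "complex"
  structure(list(sens = sens, dims = dim(sens)[1:3],
                 n_coils = dim(sens)[4]),
            class = "coil_profile")
}

#' Single uniform coil
#' @param dims grid dims.
#' @return A `coil_profile` with one coil of unit sensitivity everywhere.
#' @export
uniform_coils <- function(dims) {
  coil_profile(array(1 + 0i, c(dims, 1L)))
}

#' Acquisition configuration
#'
#' @param TR_ms repetition time per spoke in ms.
#' @param spokes_per_frame consecutive spokes grouped into one cine frame.
#' @param readout_points samples per spoke (odd).
#' @param duration_s total scan duration in seconds.
#' @param noise_sd complex Gaussian noise SD added per sample (default 0).
#' @return An object of class `acq_config`.
#' @export
acq_config <- function(TR_ms = 5.8, spokes_per_frame = 17,
                       readout_points = 101, duration_s = 180,
                       noise_sd = 0) {
  stopifnot(TR_ms > 0, spokes_per_frame >= 1, readout_points >= 3,
            duration_s > 0, noise_sd >= 0)
  structure(list(TR_ms = TR_ms,
                 spokes_per_frame = as.integer(spokes_per_frame),
                 readout_points = as.integer(readout_points),
                 duration_s = duration_s,
                 noise_sd = noise_sd),
            class = "acq_config")
}

#' Simulate a free-breathing radial k-space acquisition
#'
#' Assigns consecutive trajectory spokes to cine frames
#' (`spokes_per_frame` per frame, in acquisition order) and evaluates the
#' forward NUFFT of each ground-truth frame at its spokes' coordinates
#' (the quasi-static frame assumption: all spokes of a frame see that
#' frame's anatomy).  Optional complex Gaussian noise is added with the
#' given seed; with `noise_sd = 0` the output is independent of the seed.
#'
#' @param cine a `ground_truth_cine` from [render_cine()].
#' @param traj a [make_trajectory()] with at least
#'   `n_t * spokes_per_frame` spokes.
#' @param coils a [coil_profile()] or NULL (single uniform coil).
#' @param acq an [acq_config()]; its `readout_points` must match `traj`.
#' @param seed RNG seed for the noise draws.
#' @param plan optional [nufft_plan()] to reuse.
#' @return An object of class `kspace_series`: complex `samples` indexed
#'   `[readout, spoke-in-frame, coil, frame]`, per-frame spoke direction
#'   array `dirs [spoke, 3, frame]`, shared `radii`, timestamps, and the
#'   acquisition metadata.
#' @export
simulate_acquisition <- function(cine, traj, coils = NULL, acq = acq_config(),
                                 seed = 1, plan = NULL) {
  stopifnot(inherits(cine, "ground_truth_cine"), inherits(traj, "trajectory"),
            inherits(acq, "acq_config"))
  if (traj$readout_points != acq$readout_points)
    stop("trajectory and acquisition readout_points differ")
  n_t <- cine$n_t
  spf <- acq$spokes_per_frame
  if (traj$n_spokes < n_t * spf)
    stop("trajectory has too few spokes for the scan duration")
  if (is.null(plan)) plan <- nufft_plan(cine$dims)
  n_coils <- if (is.null(coils)) 1L else coils$n_coils
  nr <- traj$readout_points
  samples <- array(0i, c(nr, spf, n_coils, n_t))
  dirs <- array(0, c(spf, 3L, n_t))
  noise <- acq$noise_sd > 0
  gen <- function() {
    for (t in seq_len(n_t)) {
      sp <- (t - 1L) * spf + seq_len(spf)
      dirs[, , t] <<- traj$dirs[sp, , drop = FALSE]
      coords <- spoke_coords(traj, sp)
      vol <- cine_frame(cine, t)
      y <- nufft_forward(plan, vol, coords, coils)
      if (noise)
        y <- y + complex(real = rnorm(length(y), 0, acq$noise_sd),
                         imaginary = rnorm(length(y), 0, acq$noise_sd))
      samples[, , , t] <<- y
    }
  }
  if (noise) with_seed(seed, gen()) else gen()
  structure(list(samples = samples, dirs = dirs, radii = traj$radii,
                 timestamps_ms = cine$timestamps_ms, TR_ms = acq$TR_ms,
                 n_t = n_t, spokes_per_frame = spf,
                 readout_points = nr, n_coils = n_coils,
                 coils = coils, dims = cine$dims, voxel_mm = cine$voxel_mm),
            class = "kspace_series")
}

#' k-space coordinates of one frame of a series
#' @param ks a `kspace_series`.
#' @param t frame index.
#' @return `(readout * spokes_per_frame)` x 3 coordinate matrix.
#' @export
frame_coords <- function(ks, t) {
  d <- ks$dirs[, , t, drop = FALSE]
  cbind(as.vector(outer(ks$radii, d[, 1, 1])),
        as.vector(outer(ks$radii, d[, 2, 1])),
        as.vector(outer(ks$radii, d[, 3, 1])))
}

#' Samples of one frame as a matrix
#' @param ks a `kspace_series`.
#' @param t frame index.
#' @return `(readout * spokes_per_frame)` x n_coils complex matrix.
#' @export
frame_samples <- function(ks, t) {
  matrix(ks$samples[, , , t], ncol = ks$n_coils)
}

#' Per-frame sample count
#' @param ks a `kspace_series`.
#' @return integer `N_k` (readout x spokes x coils).
#' @export
frame_nk <- function(ks) ks$readout_points * ks$spokes_per_frame * ks$n_coils

#' Save / load a k-space frame series
#'
#' Serializes the series (samples, coordinates, sensitivities, timestamps
#' and acquisition attributes) as a single RDS container.
#'
#' @param ks a `kspace_series`.
#' @param path output file.
#' @return `path` invisibly; `read_kspace_series` returns the series.
#' @export
write_kspace_series <- function(ks, path) {
  saveRDS(ks, path)
  invisible(path)
}

#' @rdname write_kspace_series
#' @export
read_kspace_series <- function(path) {
  ks <- readRDS(path)
  stopifnot(inherits(ks, "kspace_series"))
  ks
}
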