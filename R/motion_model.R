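#' Reconstruct motion-binned 4D-MRI volumes
#'
#' Pools the spokes assigned to each respiratory bin and reconstructs one
#' volume per bin by density-compensated adjoint NUFFT — the "online"
#' 4D-MRI from which a motion model can be built without prior data.
#'
#' @param ks a `kspace_series`.
#' @param bins a [sort_bins()] assignment over the series' spokes.
#' @param plan optional [nufft_plan()] to reuse.
#' @return List of `n_bins` [complex_volume()] objects.
#' @export
reconstruct_bins <- function(ks, bins, plan = NULL) {
  stopifnot(inherits(ks, "kspace_series"), inherits(bins, "bin_assignment"))
  ns <- ks$spokes_per_frame * ks$n_t
  if (length(bins$bin_of_spoke) != ns)
    stop("bin assignment does not cover the series' spokes")
  if (is.null(plan)) plan <- nufft_plan(ks$dims)
  nr <- ks$readout_points
  # global spoke index -> (frame, spoke-in-frame)
  fr <- (seq_len(ns) - 1L) %/% ks$spokes_per_frame + 1L
  sif <- (seq_len(ns) - 1L) %% ks$spokes_per_frame + 1L
  out <- vector("list", bins$n_bins)
  for (b in seq_len(bins$n_bins)) {
    sel <- which(bins$bin_of_spoke == b)
    if (!length(sel)) stop("respiratory bin ", b, " is empty")
    coords <- matrix(0, nr * length(sel), 3L)
    samp <- matrix(0i, nr * length(sel), ks$n_coils)
    for (i in seq_along(sel)) {
      s <- sel[i]
      d <- ks$dirs[sif[s], , fr[s]]
      rows <- (i - 1L) * nr + seq_len(nr)
      coords[rows, ] <- cbind(ks$radii * d[1], ks$radii * d[2], ks$radii * d[3])
      samp[rows, ] <- matrix(ks$samples[, sif[s], , fr[s]], ncol = ks$n_coils)
    }
    out[[b]] <- complex_volume(
      array(nufft_adjoint(plan, samp, coords, coils = ks$coils), ks$dims),
      ks$voxel_mm)
  }
  out
}

#' Spokes belonging to one bin, as coordinates and samples
#'
#' Convenience accessor used for the end-of-exhale k-space subset that
#' drives the early training stages.
#'
#' @inheritParams reconstruct_bins
#' @param bin bin index.
#' @return list with `coords` (m x 3) and `samples` (m x n_coils).
#' @export
bin_kspace <- function(ks, bins, bin) {
  ns <- ks$spokes_per_frame * ks$n_t
  fr <- (seq_len(ns) - 1L) %/% ks$spokes_per_frame + 1L
  sif <- (seq_len(ns) - 1L) %% ks$spokes_per_frame + 1L
  sel <- which(bins$bin_of_spoke == bin)
  if (!length(sel)) stop("respiratory bin ", bin, " is empty")
  nr <- ks$readout_points
  coords <- matrix(0, nr * length(sel), 3L)
  samp <- matrix(0i, nr * length(sel), ks$n_coils)
  for (i in seq_along(sel)) {
    s <- sel[i]
    d <- ks$dirs[sif[s], , fr[s]]
    rows <- (i - 1L) * nr + seq_len(nr)
    coords[rows, ] <- cbind(ks$radii * d[1], ks$radii * d[2], ks$radii * d[3])
    samp[rows, ] <- matrix(ks$samples[, sif[s], , fr[s]], ncol = ks$n_coils)
  }
  list(coords = coords, samples = samp, spokes = sel)
}

#' PCA motion basis from inter-phase DVFs
#'
#' The mean inter-phase DVF `e0` plus the leading principal components of
#' the centered, flattened DVF matrix.  The SVD is taken jointly over the
#' concatenated (x, y, z) components (one SVD; the default), or
#' per-direction when `per_direction = TRUE`.  Components are returned
#' with unit Hilbert-space norm and are mutually orthonormal.
#'
#' @param dvfs list of [dvf_field()] inter-phase DVFs `D_p` (one per
#'   respiratory bin, the exhale entry identically zero).
#' @param n_pc number of principal motion components (default 3).
#' @param per_direction run three independent SVDs over the Cartesian
#'   components instead of one joint SVD.
#' @return An object of class `pca_basis`: `e0` (a `dvf_field`),
#'   `components` (list of `n_pc` unit-norm `dvf_field`s),
#'   `singular_values`, `explained` (fraction of variance per component),
#'   `n_pc`.
#' @export
pca_basis <- function(dvfs, n_pc = 3, per_direction = FALSE) {
  stopifnot(length(dvfs) > n_pc, n_pc >= 1)
  dims <- dvfs[[1]]$dims
  voxel_mm <- dvfs[[1]]$voxel_mm
  nb <- length(dvfs)
  X <- t(vapply(dvfs, function(d) as.numeric(d$vectors),
                numeric(prod(dims) * 3)))        # nb x (3 nvox)
  e0 <- colMeans(X)
  Xc <- sweep(X, 2L, e0)
  if (sum(Xc^2) < 1e-24) stop("inter-phase DVFs are all identical (zero variance)")
  nvox <- prod(dims)
  make_field <- function(v) dvf_field(array(v, c(dims, 3L)), voxel_mm)
  if (!per_direction) {
    sv <- svd(Xc, nu = 0, nv = n_pc)
    comps <- lapply(seq_len(n_pc), function(i) make_field(sv$v[, i]))
    d2 <- sv$d^2
    basis <- list(e0 = make_field(e0), components = comps,
                  singular_values = sv$d[seq_len(min(n_pc, length(sv$d)))],
                  explained = d2[seq_len(min(n_pc, length(d2)))] / sum(d2),
                  n_pc = n_pc, n_train = nb, per_direction = FALSE)
  } else {
    comps <- sing <- vector("list", 3L)
    for (c in 1:3) {
      cols <- (c - 1L) * nvox + seq_len(nvox)
      sv <- svd(Xc[, cols], nu = 0, nv = n_pc)
      comps[[c]] <- sv$v
      sing[[c]] <- sv$d
    }
    fields <- lapply(seq_len(n_pc), function(i) {
      v <- numeric(3 * nvox)
      for (c in 1:3) v[(c - 1L) * nvox + seq_len(nvox)] <- comps[[c]][, i]
      f <- make_field(v)
      f$vectors <- f$vectors / sqrt(3)   # unit joint norm
      f
    })
    basis <- list(e0 = make_field(e0), components = fields,
                  singular_values = sing[[1]][seq_len(n_pc)],
                  explained = NULL, n_pc = n_pc, n_train = nb,
                  per_direction = TRUE)
  }
  structure(basis, class = "pca_basis")
}

#' Compose a frame DVF from the PCA basis and PC weights
#'
#' Implements the motion model `d_t(x) = e0(x) + sum_i w_i(t) e_i(x)`
#' with per-direction weighting: for Cartesian direction `c`,
#' `d^c = e0^c + sum_i w[i, c] * e_i^c`.  A scalar-per-component weight
#' vector is broadcast across the three directions.
#'
#' @param basis a [pca_basis()] (or `dvf_basis`, whose modes then act as
#'   components with a zero mean field).
#' @param weights 3 x 3 matrix (component x direction) or length-3
#'   vector of PC weights.
#' @return A [dvf_field()].
#' @export
compose_dvf <- function(basis, weights) {
  comps <- if (inherits(basis, "dvf_basis")) basis$modes else basis$components
  e0 <- if (inherits(basis, "dvf_basis")) NULL else basis$e0
  np <- length(comps)
  if (is.vector(weights) && !is.matrix(weights))
    weights <- matrix(rep(weights, 3L), np, 3L)
  stopifnot(nrow(weights) == np, ncol(weights) == 3L)
  dims <- comps[[1]]$dims
  acc <- if (is.null(e0)) array(0, c(dims, 3L)) else e0$vectors
  for (i in seq_len(np)) for (c in 1:3)
    if (weights[i, c] != 0)
      acc[, , , c] <- acc[, , , c] + weights[i, c] * comps[[i]]$vectors[, , , c]
  dvf_field(acc, comps[[1]]$voxel_mm)
}

#' Promote an analytic mode basis to a PCA-basis object
#'
#' Wraps a simulation-side `dvf_basis` (orthonormal analytic modes) as a
#' [pca_basis()] with a zero mean field, so it can drive the motion
#' model directly (ground-truth basis bypass).
#'
#' @param basis a `dvf_basis` from [make_analytic_basis()].
#' @return A `pca_basis`.
#' @export
as_pca_basis <- function(basis) {
  stopifnot(inherits(basis, "dvf_basis"))
  structure(list(e0 = dvf_zero(basis$dims, basis$voxel_mm),
                 components = basis$modes,
                 singular_values = rep(NA_real_, length(basis$modes)),
                 explained = NULL, n_pc = length(basis$modes),
                 per_direction = FALSE),
            class = "pca_basis")
}

#' Project a DVF onto the PCA basis
#'
#' Per-component Hilbert-space projections of `d - e0` onto the
#' orthonormal components: the "true" PC weights of a given DVF.
#'
#' @param basis a [pca_basis()].
#' @param dvf a [dvf_field()].
#' @return length-`n_pc` numeric vector of projections.
#' @export
project_dvf <- function(basis, dvf) {
  resid <- dvf$vectors - basis$e0$vectors
  vapply(basis$components, function(e) sum(resid * e$vectors), numeric(1))
}
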