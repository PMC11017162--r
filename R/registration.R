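# Built-in multiresolution demons registration used to derive the
# inter-phase DVFs from the motion-binned volumes when no externally
# computed fields are supplied.

grad3 <- function(vol, dims) {
  # central differences, replicated borders, voxel units
  g <- array(0, c(dims, 3L))
  ip <- function(n) pmin(seq_len(n) + 1L, n)
  im <- function(n) pmax(seq_len(n) - 1L, 1L)
  g[, , , 1] <- (vol[ip(dims[1]), , ] - vol[im(dims[1]), , ]) / 2
  g[, , , 2] <- (vol[, ip(dims[2]), ] - vol[, im(dims[2]), ]) / 2
  g[, , , 3] <- (vol[, , ip(dims[3])] - vol[, , im(dims[3])]) / 2
  g
}

smooth_field <- function(d, dims, sigma) {
  if (sigma <= 0) return(d)
  for (c in 1:3)
    d[, , , c] <- array(gaussian_smooth3(as.vector(d[, , , c]),
                                         as.integer(dims), sigma), dims)
  d
}

warp_real <- function(vol, dims, d_vox) {
  n <- prod(dims)
  out <- warp_trilinear(as.complex(as.vector(vol)), as.integer(dims),
                        matrix(d_vox, n, 3L))
  array(Re(out), dims)
}

demons_pair <- function(fixed, moving, dims, iters, sigma_fluid, sigma_elastic,
                        alpha, d_init = NULL) {
  n <- prod(dims)
  d <- if (is.null(d_init)) array(0, c(dims, 3L)) else d_init
  best <- d
  best_err <- Inf
  stall <- 0L
  for (it in seq_len(iters)) {
    w <- warp_real(moving, dims, d)
    diff <- w - fixed
    err <- mean(abs(diff))
    if (err < best_err - 1e-12) {
      best_err <- err
      best <- d
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= 8L) {
      warning("demons update norm stopped decreasing; returning best result")
      return(best)
    }
    g <- grad3(w, dims)
    g2 <- g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2
    den <- g2 + alpha^2 * diff^2
    den[den < 1e-12] <- Inf
    u <- array(0, c(dims, 3L))
    for (c in 1:3) u[, , , c] <- -diff * g[, , , c] / den
    u <- smooth_field(u, dims, sigma_fluid)
    d <- smooth_field(d + u, dims, sigma_elastic)
  }
  w <- warp_real(moving, dims, d)
  if (mean(abs(w - fixed)) <= best_err) d else best
}

resize_vol <- function(vol, dims, newdims) {
  array(resize_trilinear(as.vector(vol), as.integer(dims),
                         as.integer(newdims)), newdims)
}

#' Inter-phase DVFs by multiresolution demons registration
#'
#' Registers the end-of-exhale bin image onto every other bin image with
#' a three-level demons scheme (Gaussian-regularized update and total
#' fields), producing pull-back fields `D_p` such that
#' `warp_volume(exhale, D_p)` approximates bin `p`.  The exhale entry is
#' identically zero.  Magnitude images are used and normalized to their
#' joint maximum before registration.
#'
#' @param bin_volumes list of per-bin [complex_volume()] (or
#'   [mag_volume()]) images on one grid.
#' @param exhale_bin index of the end-of-exhale bin.
#' @param levels down-sampling factors of the multiresolution pyramid
#'   (coarse to fine).
#' @param iters demons iterations per level.
#' @param sigma_fluid,sigma_elastic Gaussian widths (voxels) for the
#'   update-field and total-field regularization.
#' @param alpha demons step-limiting constant (larger = smaller steps).
#' @return An object of class `inter_phase_dvfs`: list `dvfs` of
#'   [dvf_field()] (mm), plus `exhale_bin`.
#' @export
register_phases <- function(bin_volumes, exhale_bin, levels = c(4, 2, 1),
                            iters = c(60, 40, 20), sigma_fluid = 1.0,
                            sigma_elastic = 1.0, alpha = 0.4) {
  nb <- length(bin_volumes)
  stopifnot(nb >= 2, exhale_bin >= 1, exhale_bin <= nb,
            length(levels) == length(iters))
  dims <- as.integer(bin_volumes[[1]]$dims)
  voxel_mm <- bin_volumes[[1]]$voxel_mm
  mags <- lapply(bin_volumes, function(v) {
    if (!identical(as.integer(v$dims), dims)) stop("bin volumes on different grids")
    Mod(v$data)
  })
  mx <- max(vapply(mags, max, numeric(1)))
  if (mx > 0) mags <- lapply(mags, function(m) m / mx)
  exh <- mags[[exhale_bin]]

  dvfs <- vector("list", nb)
  for (p in seq_len(nb)) {
    if (p == exhale_bin) {
      dvfs[[p]] <- dvf_zero(dims, voxel_mm)
      next
    }
    d <- NULL
    for (li in seq_along(levels)) {
      f <- levels[li]
      ld <- pmax(4L, as.integer(round(dims / f)))
      fx <- resize_vol(mags[[p]], dims, ld)
      mv <- resize_vol(exh, dims, ld)
      if (!is.null(d)) {
        dn <- array(0, c(ld, 3L))
        for (c in 1:3)
          dn[, , , c] <- resize_vol(d[, , , c], dim(d)[1:3], ld) *
            (ld[c] / dim(d)[c])
        d <- dn
      }
      d <- demons_pair(fx, mv, ld, iters[li], sigma_fluid, sigma_elastic,
                       alpha, d_init = d)
    }
    # fields were computed in voxel units at full resolution; convert to mm
    dmm <- array(0, c(dims, 3L))
    for (c in 1:3) dmm[, , , c] <- d[, , , c] * voxel_mm[c]
    dvfs[[p]] <- dvf_field(dmm, voxel_mm)
  }
  structure(list(dvfs = dvfs, exhale_bin = as.integer(exhale_bin)),
            class = "inter_phase_dvfs")
}

#' Wrap externally supplied inter-phase DVFs
#'
#' Bypass for [register_phases()]: accept precomputed (e.g. ground-truth)
#' fields, forcing the exhale entry to zero.
#'
#' @param dvfs list of [dvf_field()].
#' @param exhale_bin exhale bin index.
#' @return An `inter_phase_dvfs` object.
#' @export
inter_phase_set <- function(dvfs, exhale_bin) {
  stopifnot(length(dvfs) >= 2, exhale_bin >= 1, exhale_bin <= length(dvfs))
  dvfs[[exhale_bin]] <- dvf_zero(dvfs[[1]]$dims, dvfs[[1]]$voxel_mm)
  structure(list(dvfs = dvfs, exhale_bin = as.integer(exhale_bin)),
            class = "inter_phase_dvfs")
}
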