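test_that("surrogate extraction recovers the breathing trace", {
  ds <- tiny_study()                # 0.2 Hz breathing, noise free
  surr <- extract_surrogate(ds$ks)
  expect_equal(mean(surr$values), 0, tolerance = 1e-9)
  expect_equal(var(surr$values), 1, tolerance = 1e-9)
  tr <- rep(ds$trace$amplitude, each = ds$ks$spokes_per_frame)
  expect_gt(abs(cor(surr$values, tr)), 0.95)
})

test_that("band-power selection picks the respiratory component", {
  # two synthetic channels, 0.25 Hz and 2 Hz, equal variance
  fs <- 100
  t <- (1:4000) / fs
  slow <- sin(2 * pi * 0.25 * t)
  fast <- sin(2 * pi * 2 * t)
  bp_slow <- cineinr:::band_power(slow, fs, c(0.1, 0.5))
  bp_fast <- cineinr:::band_power(fast, fs, c(0.1, 0.5))
  expect_gt(bp_slow, 10 * bp_fast)
})

test_that("equal-count binning and dwell-based exhale detection", {
  ramp <- seq_len(1000)
  bins <- sort_bins(ramp, 10)
  expect_true(all(table(bins$bin_of_spoke) == 100))
  expect_error(sort_bins(rep(1, 100)), "constant")

  # pure sinusoid: extremal bins dwell longer (longer membership runs),
  # and the symmetric tie defaults to the upper extremum
  s <- sin(2 * pi * (1:5000) / 250)
  b <- sort_bins(s, 10)
  run_mean <- function(bin) {
    r <- rle(b$bin_of_spoke == bin)
    mean(r$lengths[r$values])
  }
  expect_gt(run_mean(1), run_mean(5))
  expect_gt(run_mean(10), run_mean(6))
  expect_identical(b$exhale_bin, 10L)
  # a sin^4-dwell waveform: exhale detected at the plateau side under
  # either sign of the surrogate
  w <- -sin(pi * (1:8000) / 400)^4
  expect_identical(sort_bins(w, 10)$exhale_bin, 10L)
  expect_identical(sort_bins(-w, 10)$exhale_bin, 1L)

  # sin^4-style breathing dwells at exhale (the upper extreme of the
  # standardized surrogate after sign fixing): exhale is detected there
  ds <- tiny_study()
  surr <- extract_surrogate(ds$ks)
  bins2 <- sort_bins(surr, 10)
  tr <- rep(ds$trace$amplitude, each = ds$ks$spokes_per_frame)
  exhale_mean <- mean(tr[bins2$bin_of_spoke == bins2$exhale_bin])
  expect_gt(exhale_mean, -2)        # exhale bin sits near 0 mm
})

test_that("bin reconstructions are stationary for a static phantom and track motion", {
  # static phantom on a small grid with enough spokes per bin that the
  # residual streak patterns stay below 5% between bins
  dims <- c(16, 16, 16)
  ph <- build_reference_phantom(dims, 4, tumor_diameter_mm = 30)
  ref <- apply_phase(ph, simulate_phase_map(dims, 4, seed = 5))
  basis <- make_analytic_basis(dims, 4)
  trz <- make_motion_trace(scenario_spec("S1", peak_to_peak_mm = 0,
                                         amplitude_jitter = 0), 39.5, 98.6)
  cz <- render_cine(ref, basis, trz)
  plan16 <- nufft_plan(dims)
  traj <- make_trajectory(cz$n_t * 17, 17)
  acq <- acq_config(readout_points = 17, duration_s = 39.5)
  ksz <- simulate_acquisition(cz, traj, NULL, acq, plan = plan16)
  # static series: k0 modulus identical across frames
  k0 <- which.min(abs(ksz$radii))
  expect_lt(max(abs(diff(Mod(ksz$samples[k0, 1, 1, ])))), 1e-6)
  bins <- structure(list(bin_of_spoke = rep(1:10, length.out =
                                              ksz$spokes_per_frame * ksz$n_t),
                         n_bins = 10L, exhale_bin = 1L),
                    class = "bin_assignment")
  vols <- reconstruct_bins(ksz, bins, plan16)
  for (b in 2:10)
    expect_lt(relative_error(vols[[b]]$data, vols[[1]]$data), 0.05)

  ds <- tiny_study()

  # breathing phantom: exhale vs inhale bin diaphragm edge differs by the
  # simulated amplitude within ~1 voxel
  surr <- extract_surrogate(ds$ks)
  rb <- sort_bins(surr, 10)
  vols2 <- reconstruct_bins(ds$ks, rb, ds$plan)
  expect_identical(length(vols2), 10L)
  counts <- table(rb$bin_of_spoke)
  expect_identical(sum(counts), as.integer(ds$ks$spokes_per_frame * ds$ks$n_t))
  inhale_bin <- if (rb$exhale_bin == 10L) 1L else 10L
  col <- round(0.68 * 32) + 1
  zprof <- function(v)
    apply(Mod(v$data)[(col - 1):(col + 1), 15:17, , drop = FALSE], 3, mean)
  # SI shift between the bins from the cross-correlation of the
  # diaphragm-column profiles (parabolic sub-voxel refinement)
  pe <- zprof(vols2[[rb$exhale_bin]])
  pi_ <- zprof(vols2[[inhale_bin]])
  lags <- -8:8
  cc <- vapply(lags, function(s) {
    z <- 10:26
    sum(pe[z] * pi_[z - s])
  }, numeric(1))
  i <- which.max(cc)
  num <- cc[max(1, i - 1)] - cc[min(length(cc), i + 1)]
  den <- cc[max(1, i - 1)] - 2 * cc[i] + cc[min(length(cc), i + 1)]
  shift_vox <- lags[i] + if (abs(den) > 1e-12) 0.5 * num / den else 0
  tr <- rep(ds$trace$amplitude, each = ds$ks$spokes_per_frame)
  expected_vox <- (mean(tr[rb$bin_of_spoke == rb$exhale_bin]) -
                     mean(tr[rb$bin_of_spoke == inhale_bin])) / 4
  expect_lt(abs(abs(shift_vox) - abs(expected_vox)), 1.6)
})

test_that("demons registration: self, known shift, exhale zero", {
  dims <- c(24, 24, 24)
  ph <- small_phantom()
  v <- complex_volume(ph$data + 0i, 4)
  # identical inputs: negligible recovered displacement
  out <- suppressWarnings(register_phases(list(v, v), exhale_bin = 1,
                                          levels = c(2, 1),
                                          iters = c(20, 10)))
  expect_lt(max(abs(out$dvfs[[2]]$vectors)) / 4, 0.1)
  expect_true(all(out$dvfs[[1]]$vectors == 0))

  # 3-voxel integer translation recovered within 0.5 voxel (mean over
  # the moving structure)
  sm <- array(gaussian_smooth3(as.vector(ph$data), as.integer(dims), 1.5),
              dims)
  shifted <- array(0, dims)
  shifted[, , 1:(dims[3] - 3)] <- sm[, , 4:dims[3]]
  fx <- complex_volume(shifted + 0i, 4)
  mv <- complex_volume(sm + 0i, 4)
  reg <- suppressWarnings(register_phases(list(mv, fx), exhale_bin = 1))
  d <- reg$dvfs[[2]]
  core <- sm > 0.3
  core[, , c(1:4, (dims[3] - 4):dims[3])] <- FALSE
  mean_dz <- mean(d$vectors[, , , 3][core]) / 4
  expect_equal(mean_dz, 3, tolerance = 0.5 / 3)
})

test_that("PCA basis: orthonormality, rank-3 recovery, rank-1 pair", {
  dims <- c(12, 12, 12)
  basis <- make_analytic_basis(dims, 4)
  set.seed(31)
  Wtrue <- matrix(rnorm(10 * 3), 10, 3)
  dvfs <- lapply(1:10, function(p) {
    f <- basis_combine <- cineinr:::basis_combine(basis, Wtrue[p, ])
    f
  })
  pb <- pca_basis(dvfs, n_pc = 3)
  # orthonormality to 1e-8
  for (i in 1:3) for (j in 1:3)
    expect_equal(dvf_inner(pb$components[[i]], pb$components[[j]]),
                 as.numeric(i == j), tolerance = 1e-8)
  expect_true(all(diff(pb$singular_values) <= 1e-8))
  # explained variance of 3 components > 99.99%
  expect_gt(sum(pb$explained), 0.9999)
  # span recovery: projection residual of each centered training DVF
  for (p in c(1, 5, 10)) {
    resid <- dvfs[[p]]$vectors - pb$e0$vectors
    proj <- project_dvf(pb, dvfs[[p]])
    for (i in 1:3)
      resid <- resid - proj[i] * pb$components[[i]]$vectors
    expect_lt(sqrt(sum(resid^2)) / sqrt(sum(dvfs[[p]]$vectors^2)), 1e-6)
  }
  # two distinct DVFs: exactly one nonzero singular value
  pb2 <- pca_basis(dvfs[1:2], n_pc = 1)
  expect_gt(pb2$singular_values[1], 1e-8)
  full <- svd(rbind(as.numeric(dvfs[[1]]$vectors) -
                      as.numeric(pb2$e0$vectors),
                    as.numeric(dvfs[[2]]$vectors) -
                      as.numeric(pb2$e0$vectors)))$d
  expect_lt(full[2] / full[1], 1e-10)
  # all-identical DVFs: error
  expect_error(pca_basis(list(dvfs[[1]], dvfs[[1]], dvfs[[1]],
                              dvfs[[1]]), n_pc = 3), "variance")
})

test_that("compose_dvf implements the per-direction weighting model", {
  dims <- c(10, 10, 10)
  basis <- make_analytic_basis(dims, 4)
  set.seed(7)
  dvfs <- lapply(1:6, function(p)
    cineinr:::basis_combine(basis, rnorm(3)))
  pb <- pca_basis(dvfs, n_pc = 3)
  # zero weights reproduce e0 exactly
  z <- compose_dvf(pb, matrix(0, 3, 3))
  expect_identical(z$vectors, pb$e0$vectors)
  # linearity in the weights
  W <- matrix(rnorm(9), 3, 3)
  d2 <- compose_dvf(pb, 2 * W)$vectors - z$vectors
  d1 <- compose_dvf(pb, W)$vectors - z$vectors
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # projection weights reproduce a training DVF up to truncation error,
  # matching a direct least-squares fit
  target <- dvfs[[3]]
  w <- project_dvf(pb, target)
  rec <- compose_dvf(pb, matrix(rep(w, 3), 3, 3))
  resid <- sqrt(sum((rec$vectors - target$vectors)^2))
  # independent least squares on the flattened component matrix
  A <- vapply(pb$components, function(e) as.numeric(e$vectors),
              numeric(prod(dims) * 3))
  b <- as.numeric(target$vectors) - as.numeric(pb$e0$vectors)
  wls <- qr.solve(A, b)
  expect_equal(w, wls, tolerance = 1e-8)
  expect_lt(resid / sqrt(sum(target$vectors^2)), 1e-6)
})
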