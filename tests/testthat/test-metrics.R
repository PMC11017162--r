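test_that("relative error: identities, hand value, scale invariance", {
  dims <- c(8, 8, 8)
  z <- random_complex_vol(dims, 1)
  expect_equal(relative_error(z, z), 0)
  expect_equal(relative_error(z * 0, z), 1)
  a <- array(c(3, 0, rep(0, 6)) + 0i, c(2, 2, 2))
  b <- array(c(3, 4, rep(0, 6)) + 0i, c(2, 2, 2))
  expect_equal(relative_error(a, b), 0.8)          # sqrt(16/25)
  z2 <- random_complex_vol(dims, 2)
  expect_equal(relative_error(3.7 * z, 3.7 * z2), relative_error(z, z2),
               tolerance = 1e-12)
  expect_error(relative_error(z, z * 0), "zero")
  expect_equal(relative_error(z, z2), loop_relative_error(z, z2),
               tolerance = 1e-12)
})

test_that("Dice coefficient: identities, hand value, erosion monotonicity", {
  dims <- c(12, 12, 12)
  sphere <- function(r) {
    idx <- index_mat <- as.matrix(expand.grid(1:12, 1:12, 1:12)) - 6.5
    array(rowSums(idx^2) <= r^2, dims)
  }
  s <- sphere(4)
  expect_equal(dice(s, s), 1)
  expect_equal(dice(s, !s & FALSE), 0)
  y <- array(FALSE, c(2, 2, 2)); y[1:4] <- c(TRUE, TRUE, TRUE, TRUE)
  yg <- array(FALSE, c(2, 2, 2)); yg[3:6] <- TRUE
  expect_equal(dice(y, yg), 0.5)                   # |Y|=|Ygt|=4, inter=2
  expect_equal(dice(y, yg), loop_dice(y, yg))
  expect_equal(dice(array(FALSE, dims), array(FALSE, dims)), 1)
  # monotone non-increasing under erosion of one argument
  prev <- 1
  for (r in c(4, 3.5, 3, 2.5)) {
    d <- dice(sphere(r), s)
    expect_lte(d, prev + 1e-12)
    prev <- d
  }
})

test_that("center-of-mass error: identity, rigid shift, symmetry", {
  dims <- c(10, 10, 10)
  m <- array(FALSE, dims)
  m[4:6, 4:6, 4:6] <- TRUE
  expect_equal(center_of_mass_error(m, m, 4), 0)
  m2 <- array(FALSE, dims)
  m2[5:7, 4:6, 4:6] <- TRUE                       # +1 voxel along x
  expect_equal(center_of_mass_error(m, m2, 4), 4)
  expect_equal(center_of_mass_error(m, m2, c(2, 4, 4)), 2)
  expect_equal(center_of_mass_error(m2, m, 4),
               center_of_mass_error(m, m2, 4))
  expect_error(center_of_mass_error(m, array(FALSE, dims), 4), "empty")
})

test_that("mask propagation mirrors the warping operator", {
  dims <- c(26, 26, 26)
  idx <- as.matrix(expand.grid(1:26, 1:26, 1:26))
  ctr <- c(13.5, 13.5, 13.5)
  mask <- array(rowSums(sweep(idx, 2, ctr)^2) <= 10^2, dims)
  expect_identical(propagate_mask(mask, dvf_zero(dims, 4)), mask)
  # integer-voxel constant DVF: exactly shifted mask
  d <- dvf_zero(dims, 4)
  d$vectors[, , , 3] <- -8                        # -2 voxels, pull-back
  shifted <- propagate_mask(mask, d)
  expect_identical(shifted[, , 3:26], mask[, , 1:24])
  # sub-voxel constant DVF on a large sphere: Dice with the
  # analytically shifted sphere stays high
  d2 <- dvf_zero(dims, 4)
  d2$vectors[, , , 1] <- 4 * 0.4
  sub <- propagate_mask(mask, d2)
  ana <- array(rowSums(sweep(idx, 2, ctr + c(0.4, 0, 0))^2) <= 10^2, dims)
  expect_gt(dice(sub, ana), 0.95)
  expect_warning(propagate_mask(mask, dvf_field(
    array(400, c(dims, 3)), 4)), "empty")
})

test_that("sharpness variance: zero, blur monotonicity, checkerboard", {
  dims <- c(12, 12, 12)
  expect_equal(sharpness_variance(array(0.5, dims)), 0)
  ph <- small_phantom()
  s0 <- sharpness_variance(ph$data)
  blurred <- array(gaussian_smooth3(as.vector(ph$data),
                                    as.integer(ph$dims), 1.5), ph$dims)
  expect_lt(sharpness_variance(blurred), s0)
  # binary 3D checkerboard: every 3^3 window holds 14/13 (or 13/14)
  # zeros/ones -> variance p(1-p) with p = 14/27 or 13/27; interior
  # windows alternate between the two, border windows (replicated
  # edges) differ; check the interior value by brute force on one
  # window and compare the metric restricted to the interior
  idx <- as.matrix(expand.grid(1:12, 1:12, 1:12))
  cb <- array((rowSums(idx) %% 2 == 0) * 1.0, dims)
  win <- as.vector(cb[1:3, 1:3, 1:3])
  v1 <- mean(win^2) - mean(win)^2
  win2 <- as.vector(cb[2:4, 1:3, 1:3])
  v2 <- mean(win2^2) - mean(win2)^2
  interior_expected <- (v1 + v2) / 2    # alternating window variances
  # recompute the metric by brute force over all interior windows
  vals <- c()
  for (x in 2:11) for (y in 2:11) for (z in 2:11) {
    w <- as.vector(cb[(x - 1):(x + 1), (y - 1):(y + 1), (z - 1):(z + 1)])
    vals <- c(vals, mean(w^2) - mean(w)^2)
  }
  expect_equal(mean(vals), interior_expected, tolerance = 1e-12)
  # package metric agrees with the brute-force mean on the interior
  # (border handling replicates edges, so compare full-volume values
  # against a full brute force with clamped windows)
  vals_full <- numeric(0)
  cl <- function(i) pmin(pmax(i, 1), 12)
  for (x in 1:12) for (y in 1:12) for (z in 1:12) {
    w <- as.vector(cb[cl((x - 1):(x + 1)), cl((y - 1):(y + 1)),
                      cl((z - 1):(z + 1))])
    vals_full <- c(vals_full, mean(w^2) - mean(w)^2)
  }
  expect_equal(sharpness_variance(cb), mean(vals_full), tolerance = 1e-12)
})

test_that("recovered motion traces: flat for zero motion, tracking for breathing", {
  dims <- c(20, 20, 20)
  ph <- build_reference_phantom(dims, 4, 30)
  basis <- as_pca_basis(make_analytic_basis(dims, 4))
  mask <- ph$labels == 4L
  mk_result <- function(W) {
    structure(list(z_ref = complex_volume(ph$data + 0i, 4), basis = basis,
                   weight_trace = W, n_t = nrow(W), dims = dims,
                   voxel_mm = 4, timestamps_ms = seq_len(nrow(W)) * 100),
              class = "recon_result")
  }
  flat <- mk_result(matrix(0, 30, 9))
  tr0 <- motion_trace_from_recon(flat, mask)
  expect_lt(max(apply(tr0[, 2:4], 2, function(x) diff(range(x)))), 1e-9)

  # SI-mode weights following a sinusoid: the SI centroid trace follows
  # (weights are coefficients of the unit-norm mode, so a few-mm
  # displacement at the diaphragm needs O(100) weight units)
  a <- 300 * sin(2 * pi * seq_len(30) / 10)
  W <- matrix(0, 30, 9)
  W[, 7] <- a   # component 1, z-direction (column (c-1)*3+i with c=3, i=1)
  res <- mk_result(W)
  tr <- motion_trace_from_recon(res, mask)
  expect_gt(abs(cor(tr$SI_mm, a)), 0.99)
  expect_lt(max(abs(tr$LR_mm - tr$LR_mm[1])), 0.3)
})
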