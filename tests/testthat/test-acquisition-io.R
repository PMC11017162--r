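test_that("acquisition simulation: layout, stationarity, determinism", {
  dims <- c(16, 16, 16)
  ph <- build_reference_phantom(dims, 4, 30)
  ref <- apply_phase(ph, simulate_phase_map(dims, 4, seed = 2))
  basis <- make_analytic_basis(dims, 4)
  tr <- make_motion_trace(scenario_spec("S1", seed = 3), 3, 98.6)
  cine <- render_cine(ref, basis, tr)
  plan <- nufft_plan(dims)
  traj <- make_trajectory(cine$n_t * 17, 17)
  acq <- acq_config(readout_points = 17, duration_s = 3)
  ks <- simulate_acquisition(cine, traj, NULL, acq, plan = plan)
  expect_identical(dim(ks$samples),
                   c(17L, 17L, 1L, as.integer(cine$n_t)))
  expect_identical(frame_nk(ks), 17L * 17L)
  expect_identical(nrow(frame_coords(ks, 1)), 17L * 17L)
  # noise-free runs are seed independent
  ks2 <- simulate_acquisition(cine, traj, NULL, acq, seed = 99, plan = plan)
  expect_identical(ks$samples, ks2$samples)
  # noisy runs are seed deterministic and differ across seeds
  acqn <- acq_config(readout_points = 17, duration_s = 3, noise_sd = 0.1)
  kn1 <- simulate_acquisition(cine, traj, NULL, acqn, seed = 5, plan = plan)
  kn2 <- simulate_acquisition(cine, traj, NULL, acqn, seed = 5, plan = plan)
  kn3 <- simulate_acquisition(cine, traj, NULL, acqn, seed = 6, plan = plan)
  expect_identical(kn1$samples, kn2$samples)
  expect_false(identical(kn1$samples, kn3$samples))
  # too few spokes
  short <- make_trajectory(5 * 17, 17)
  expect_error(simulate_acquisition(cine, short, NULL, acq, plan = plan),
               "too few")
})

test_that("k-space series RDS round trip", {
  ds <- tiny_study()
  path <- tempfile(fileext = ".rds")
  write_kspace_series(ds$ks, path)
  back <- read_kspace_series(path)
  expect_identical(back$samples, ds$ks$samples)
  expect_identical(back$dirs, ds$ks$dirs)
  expect_identical(back$TR_ms, ds$ks$TR_ms)
})

test_that("volume and DVF NIfTI round trips preserve data and voxel size", {
  dims <- c(10, 12, 14)
  ph <- build_reference_phantom(c(16, 16, 16), 4)
  p1 <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph, p1)
  back <- read_volume_nifti(p1)
  expect_equal(back$data, ph$data, tolerance = 1e-6)
  expect_equal(back$voxel_mm, ph$voxel_mm)
  d <- dvf_field(array(rnorm(prod(dims) * 3), c(dims, 3)), c(2, 2, 4))
  p2 <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(d, p2)
  img <- RNifti::readNifti(p2)
  expect_equal(array(as.numeric(img), dim(img)), d$vectors,
               tolerance = 1e-6)
})

test_that("PCA basis serialization round trip", {
  dims <- c(8, 8, 8)
  basis0 <- make_analytic_basis(dims, 4)
  set.seed(12)
  dvfs <- lapply(1:6, function(p) cineinr:::basis_combine(basis0, rnorm(3)))
  pb <- pca_basis(dvfs, n_pc = 3)
  prefix <- tempfile()
  write_pca_basis(pb, prefix)
  back <- read_pca_basis(prefix)
  expect_equal(back$n_pc, 3)
  expect_equal(back$singular_values, pb$singular_values, tolerance = 1e-8)
  for (i in 1:3)
    expect_equal(back$components[[i]]$vectors, pb$components[[i]]$vectors,
                 tolerance = 1e-6)
  # composing with equal weights matches
  w <- matrix(rnorm(9), 3, 3)
  expect_equal(compose_dvf(back, w)$vectors, compose_dvf(pb, w)$vectors,
               tolerance = 1e-5)
})

test_that("metric and loss-report writers emit well-formed files", {
  rep <- data.frame(stage = 1L, epoch = 1:3, L_image = c(1, 0.5, 0.2),
                    L_kspace = NA, L_TV = NA, L_total = c(1, 0.5, 0.2))
  p <- tempfile(fileext = ".csv")
  write_loss_report(rep, p)
  back <- utils::read.csv(p)
  expect_equal(back$L_total, c(1, 0.5, 0.2))
  m <- structure(list(
    per_frame = data.frame(frame = 1:2, RE = c(0.1, 0.2),
                           DSC = c(0.9, 0.8), COME_mm = c(1, 2)),
    summary = data.frame(metric = c("RE", "DSC", "COME_mm"),
                         mean = c(0.15, 0.85, 1.5),
                         sd = c(0.05, 0.05, 0.5))), class = "metric_series")
  pc <- tempfile(fileext = ".csv")
  pj <- tempfile(fileext = ".json")
  write_metrics(m, pc, pj)
  expect_equal(utils::read.csv(pc)$RE, c(0.1, 0.2))
  js <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(js$summary$mean[1], 0.15)
})
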