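# a very small but complete acquisition used for training smoke tests
train_fixture <- function() {
  fixture("train_fixture", function()
    desk_study(n_frames = 40, dims = c(24, 24, 24), seed = 6))
}

tiny_cfg <- function(epochs = c(30, 20, 30), seed = 1)
  train_config("desk",
               lr = c(2e-3, 5e-4, 3e-4), epochs = epochs, n_batch = 8,
               spatial_config = hash_config(n_levels = 6, table_size = 2^12,
                                            res_min = 8, res_max = 48),
               temporal_config = hash_config(n_levels = 6, table_size = 2^12,
                                             res_min = 8, res_max = 48,
                                             input_dim = 1),
               stage2_spokes = 60, seed = seed)

test_that("one joint training step updates both networks (gradient flow)", {
  ds <- train_fixture()
  cfg <- tiny_cfg(epochs = c(5, 3, 3))
  sp <- spatial_inr(cfg$spatial_config, seed = 2)
  tm <- temporal_inr(cfg$temporal_config, seed = 3)
  basis <- ds$basis_offline
  set.seed(4)
  res <- stage3(sp, tm, basis, ds$ks, cfg, plan = ds$plan)
  # spatial hash tables and temporal output heads both moved
  expect_false(identical(res$spatial$tables[[1]], sp$tables[[1]]))
  moved <- vapply(1:9, function(j)
    !identical(res$temporal$heads[[j]]$W3, tm$heads[[j]]$W3), logical(1))
  expect_true(all(moved))
  # temporal hash tables receive gradient through the heads once the
  # first step has made the zero-initialized W3 heads nonzero
  expect_false(identical(res$temporal$tables[[1]], tm$tables[[1]]))
})

test_that("materialized cine frames equal warp(z_ref, composed DVF) exactly", {
  ds <- train_fixture()
  cfg <- tiny_cfg(epochs = c(10, 3, 5))
  sp <- spatial_inr(cfg$spatial_config, seed = 2)
  tm <- temporal_inr(cfg$temporal_config, seed = 3)
  set.seed(5)
  res <- stage3(sp, tm, ds$basis_offline, ds$ks, cfg, plan = ds$plan)
  t <- 7
  manual <- warp_volume(res$z_ref,
                        compose_dvf(res$basis,
                                    pc_weights(res$weight_trace[t, ])))
  expect_identical(recon_frame(res, t)$data, manual$data)
})

test_that("full reconstruction is deterministic under a fixed seed", {
  ds <- train_fixture()
  cfg <- tiny_cfg(epochs = c(8, 5, 8), seed = 42)
  r1 <- reconstruct(ds$ks, cfg, "offline", basis = ds$basis_offline)
  r2 <- reconstruct(ds$ks, cfg, "offline", basis = ds$basis_offline)
  expect_identical(r1$z_ref$data, r2$z_ref$data)
  expect_identical(r1$weight_trace, r2$weight_trace)
  expect_identical(r1$report$L_total, r2$report$L_total)
  # loss report carries all three stages
  expect_identical(sort(unique(r1$report$stage)), 1:3)
  expect_error(reconstruct(ds$ks, cfg, "offline"), "basis")
})

test_that("stage-2 k-space refinement reduces the reference-frame error", {
  ds <- train_fixture()
  cfg <- tiny_cfg(epochs = c(60, 60, 1))
  surr <- extract_surrogate(ds$ks)
  bins <- sort_bins(surr, 10)
  exh <- bin_kspace(ds$ks, bins, bins$exhale_bin)
  zex <- complex_volume(
    array(nufft_adjoint(ds$plan, exh$samples, exh$coords), ds$dims), 4)
  sp <- spatial_inr(cfg$spatial_config, seed = 2)
  s1 <- stage1(sp, zex, cfg)
  gcd <- cineinr:::grid_coords_scaled(ds$dims)
  re1 <- relative_error(array(spatial_forward(s1$model, gcd), ds$dims),
                        ds$reference$data)
  set.seed(6)
  s2 <- stage2(s1$model, exh, ds$ks$readout_points, ds$dims, cfg,
               plan = ds$plan)
  re2 <- relative_error(array(spatial_forward(s2$model, gcd), ds$dims),
                        ds$reference$data)
  expect_lt(re2, re1)
  expect_true(all(is.finite(s2$report$L_total)))

  # TV regularization: a lambda = 0 run yields a reference with TV no
  # smaller than the regularized default
  cfg0 <- tiny_cfg(epochs = c(60, 60, 1))
  cfg0$lambda_tv <- 0
  set.seed(6)
  s2f <- stage2(s1$model, exh, ds$ks$readout_points, ds$dims, cfg0,
                plan = ds$plan)
  tv_reg <- loss_tv(array(spatial_forward(s2$model, gcd), ds$dims))
  tv_free <- loss_tv(array(spatial_forward(s2f$model, gcd), ds$dims))
  expect_gte(tv_free, tv_reg)
})

test_that("null motion stays null: static phantom yields sub-voxel DVFs", {
  dims <- c(24, 24, 24)
  ph <- build_reference_phantom(dims, 4, 30)
  ref <- apply_phase(ph, simulate_phase_map(dims, 4, seed = 9))
  basis_true <- make_analytic_basis(dims, 4)
  trz <- make_motion_trace(scenario_spec("S1", peak_to_peak_mm = 0,
                                         amplitude_jitter = 0), 3.9, 98.6)
  cine <- render_cine(ref, basis_true, trz)
  plan <- nufft_plan(dims, 4 / 3)
  traj <- make_trajectory(cine$n_t * 17, 25)
  acq <- acq_config(readout_points = 25, duration_s = 3.9)
  ks <- simulate_acquisition(cine, traj, NULL, acq, plan = plan)
  cfg <- tiny_cfg(epochs = c(40, 20, 30))
  sp <- spatial_inr(cfg$spatial_config, seed = 2)
  tm <- temporal_inr(cfg$temporal_config, seed = 3)
  s1 <- stage1(sp, complex_volume(
    array(nufft_adjoint(plan,
                        matrix(ks$samples, ncol = 1),
                        do.call(rbind, lapply(seq_len(ks$n_t),
                                              function(t) frame_coords(ks, t)))),
    dims), 4), cfg)
  set.seed(7)
  res <- stage3(s1$model, tm, as_pca_basis(basis_true), ks, cfg, plan = plan)
  mags <- sapply(seq_len(res$n_t), function(t)
    max(abs(recon_dvf(res, t)$vectors)))
  expect_lt(quantile(mags, 0.95) / 4, 0.5)
})
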