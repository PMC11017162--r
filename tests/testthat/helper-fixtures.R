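# Shared fixtures, built once per test run and cached in an environment.
# All fixtures are generated in code under fixed seeds; nothing is read
# from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_phantom <- function(dims = c(24, 24, 24)) {
  fixture(paste0("phantom", dims[1]), function()
    build_reference_phantom(dims, 4, tumor_diameter_mm = 30))
}

small_complex_phantom <- function(dims = c(24, 24, 24)) {
  fixture(paste0("cphantom", dims[1]), function() {
    ph <- small_phantom(dims)
    apply_phase(ph, simulate_phase_map(dims, 4, seed = 7))
  })
}

random_complex_vol <- function(dims, seed = 1) {
  with_seed <- cineinr:::with_seed
  with_seed(seed, array(complex(real = rnorm(prod(dims)),
                                imaginary = rnorm(prod(dims))), dims))
}

# a tiny free-breathing acquisition (32^3, 60 frames) for pipeline tests
tiny_study <- function() {
  fixture("tiny_study", function()
    desk_study(n_frames = 60, dims = c(32, 32, 32), seed = 4))
}

# the full desk-scale study + both reconstructions, shared by the
# acceptance blocks (expensive; built once per run)
desk_fixture <- function() {
  fixture("desk_study", function() desk_study(n_frames = 200, seed = 1))
}

desk_pipeline <- function() {
  fixture("desk_pipeline", function() {
    ds <- desk_fixture()
    cfg <- train_config("desk", seed = 2)
    plan <- ds$plan
    surr <- extract_surrogate(ds$ks)
    bins <- sort_bins(surr, cfg$n_bins)
    exh <- bin_kspace(ds$ks, bins, bins$exhale_bin)
    z_exhale <- complex_volume(
      array(nufft_adjoint(plan, exh$samples, exh$coords), ds$dims),
      ds$voxel_mm)
    sp <- spatial_inr(cfg$spatial_config, seed = cfg$seed)
    set.seed(cfg$seed)
    s1 <- stage1(sp, z_exhale, cfg)
    s2 <- stage2(s1$model, exh, ds$ks$readout_points, ds$dims, cfg,
                 plan = plan)
    tm <- temporal_inr(cfg$temporal_config, seed = cfg$seed + 100)
    set.seed(cfg$seed + 1)
    res_off <- stage3(s2$model, tm, as_pca_basis(ds$basis_true), ds$ks,
                      cfg, plan = plan)
    vols <- reconstruct_bins(ds$ks, bins, plan)
    phases <- suppressWarnings(register_phases(vols, bins$exhale_bin))
    basis_on <- pca_basis(phases$dvfs, cfg$n_pc)
    tm2 <- temporal_inr(cfg$temporal_config, seed = cfg$seed + 100)
    set.seed(cfg$seed + 2)
    res_on <- stage3(s2$model, tm2, basis_on, ds$ks, cfg, plan = plan)
    list(ds = ds, cfg = cfg, plan = plan, surr = surr, bins = bins,
         z_exhale = z_exhale, s1 = s1, s2 = s2,
         res_off = res_off, res_on = res_on)
  })
}
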