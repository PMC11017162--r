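#' Training configuration
#'
#' Stage learning rates, epoch counts, TV weight, batch size and model
#' hyper-parameters for the progressive three-stage optimization.  Two
#' profiles are provided: `"paper"` uses the published large-scale
#' settings (16 hash levels, 2^19 tables, epochs 500/1500/1000,
#' N_batch 60); `"desk"` is the scaled-down CPU profile used throughout
#' the package's tests (48^3-class grids, 8 hash levels, 2^14 tables,
#' lighter FFT oversampling and shorter schedules).
#'
#' @param profile `"desk"` or `"paper"`.
#' @param lr stage learning rates (length 3).
#' @param epochs stage epoch counts (length 3).
#' @param lambda_tv TV regularization weight.
#' @param n_batch frames per stage-3 step.
#' @param n_bins respiratory bins.
#' @param n_pc principal motion components.
#' @param adam_beta1,adam_beta2,adam_eps Adam moments/epsilon.
#' @param spatial_config,temporal_config [hash_config()] overrides.
#' @param oversamp,kb_width NUFFT grid oversampling and kernel width.
#' @param stage2_spokes spoke subset size per stage-2 step (`Inf` = all
#'   exhale spokes).
#' @param omega0 sine activation frequency of the spatial INR.
#' @param perturb temporal input perturbation ("frame" = Gaussian SD of
#'   half the scaled frame interval; 0 disables).
#' @param seed master seed for the run.
#' @return An object of class `train_config`.
#' @export
train_config <- function(profile = c("desk", "paper"), lr = NULL,
                         epochs = NULL, lambda_tv = 7e-5, n_batch = NULL,
                         n_bins = 10, n_pc = 3, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         spatial_config = NULL, temporal_config = NULL,
                         oversamp = NULL, kb_width = 6, stage2_spokes = NULL,
                         omega0 = 30, perturb = "frame", seed = 1) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    if (is.null(lr)) lr <- c(1e-3, 2e-5, 2e-6)
    if (is.null(epochs)) epochs <- c(500, 1500, 1000)
    if (is.null(n_batch)) n_batch <- 60
    if (is.null(spatial_config)) spatial_config <- hash_config()
    if (is.null(temporal_config)) temporal_config <- hash_config(input_dim = 1)
    if (is.null(oversamp)) oversamp <- 2
    if (is.null(stage2_spokes)) stage2_spokes <- Inf
  } else {
    if (is.null(lr)) lr <- c(1e-3, 5e-4, 3e-3)
    if (is.null(epochs)) epochs <- c(150, 200, 200)
    if (is.null(n_batch)) n_batch <- 20
    if (is.null(spatial_config))
      spatial_config <- hash_config(n_levels = 8, table_size = 2^14,
                                    res_min = 16, res_max = 96)
    if (is.null(temporal_config))
      temporal_config <- hash_config(n_levels = 8, table_size = 2^14,
                                     res_min = 16, res_max = 96,
                                     input_dim = 1)
    if (is.null(oversamp)) oversamp <- 4 / 3
    if (is.null(stage2_spokes)) stage2_spokes <- 120
  }
  stopifnot(length(lr) == 3, all(lr > 0), length(epochs) == 3,
            all(epochs >= 1), lambda_tv >= 0, n_batch >= 1)
  structure(list(profile = profile, lr = lr, epochs = as.integer(epochs),
                 lambda_tv = lambda_tv, n_batch = as.integer(n_batch),
                 n_bins = as.integer(n_bins), n_pc = as.integer(n_pc),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, spatial_config = spatial_config,
                 temporal_config = temporal_config, oversamp = oversamp,
                 kb_width = kb_width, stage2_spokes = stage2_spokes,
                 omega0 = omega0, perturb = perturb, seed = as.integer(seed)),
            class = "train_config")
}

grid_coords_scaled <- function(dims) {
  scale_coords_unit(index_grid(dims), dims)
}

check_finite_loss <- function(l, stage) {
  if (!is.finite(l))
    stop("non-finite loss in ", stage,
         " (check learning rates and input scaling)")
}

#' Stage 1: fit the spatial INR to the NUFFT exhale reconstruction
#'
#' Supervised image-domain fit: minimizes the mean squared complex error
#' between the INR rendering and the density-compensated adjoint
#' reconstruction of the end-of-exhale bin.  One epoch is one full-grid
#' Adam step.
#'
#' @param spatial a [spatial_inr()].
#' @param z_exhale target [complex_volume()] (or complex array).
#' @param cfg a [train_config()].
#' @param dims grid dims (required when `z_exhale` is a plain array).
#' @return list with the trained `model` and a `report` data frame of
#'   per-epoch losses.
#' @export
stage1 <- function(spatial, z_exhale, cfg = train_config(), dims = NULL) {
  target <- if (inherits(z_exhale, "complex_volume")) z_exhale$data else z_exhale
  if (is.null(dims)) dims <- dim(target)
  tvec <- as.vector(target)
  n <- length(tvec)
  coords <- grid_coords_scaled(dims)
  pre <- hash_precompute(coords, spatial$config)
  params <- spatial_params(spatial)
  st <- adam_init(params)
  report <- vector("list", cfg$epochs[1])
  for (ep in seq_len(cfg$epochs[1])) {
    fw <- spatial_forward_cached(spatial, coords, pre)
    resid <- fw$z - tvec
    l <- mean(Mod(resid)^2)
    check_finite_loss(l, "stage 1")
    g <- 2 * resid / n
    grads <- spatial_backward(spatial, coords, fw, Re(g), Im(g), pre)
    up <- adam_step(params, grads, st, cfg$lr[1], cfg$adam_beta1,
                    cfg$adam_beta2, cfg$adam_eps)
    params <- up$params
    st <- up$state
    spatial <- spatial_set_params(spatial, params)
    report[[ep]] <- data.frame(stage = 1L, epoch = ep, L_image = l,
                               L_kspace = NA_real_, L_TV = NA_real_,
                               L_total = l)
  }
  list(model = spatial, report = do.call(rbind, report))
}

#' Stage 2: refine the reference frame against the exhale k-space data
#'
#' Each epoch renders the full reference volume, forward-projects a
#' random subset of the end-of-exhale spokes, and minimizes the k-space
#' similarity loss plus TV regularization of the reference magnitude.
#'
#' @param spatial a trained [spatial_inr()] (stage-1 output).
#' @param exhale_kspace list with `coords` (m x 3) and `samples`
#'   (m x n_coils), e.g. from [bin_kspace()]; samples are grouped in
#'   whole spokes of `readout_points` rows.
#' @param readout_points samples per spoke (defines the spoke grouping
#'   for subsetting).
#' @param dims image grid dims.
#' @param cfg a [train_config()].
#' @param coils optional [coil_profile()].
#' @param plan optional [nufft_plan()] to reuse.
#' @return list with `model` and `report`.
#' @export
stage2 <- function(spatial, exhale_kspace, readout_points, dims,
                   cfg = train_config(), coils = NULL, plan = NULL) {
  if (is.null(plan)) plan <- nufft_plan(dims, cfg$oversamp, cfg$kb_width)
  coords_all <- exhale_kspace$coords
  samp_all <- as.matrix(exhale_kspace$samples)
  n_spokes <- nrow(coords_all) / readout_points
  stopifnot(n_spokes == round(n_spokes))
  sub_n <- min(n_spokes, cfg$stage2_spokes)
  gcoords <- grid_coords_scaled(dims)
  pre <- hash_precompute(gcoords, spatial$config)
  params <- spatial_params(spatial)
  st <- adam_init(params)
  report <- vector("list", cfg$epochs[2])
  for (ep in seq_len(cfg$epochs[2])) {
    sel_spokes <- if (sub_n < n_spokes) sample.int(n_spokes, sub_n)
                  else seq_len(n_spokes)
    rows <- as.vector(outer(seq_len(readout_points),
                            (sel_spokes - 1L) * readout_points, "+"))
    co <- coords_all[rows, , drop = FALSE]
    me <- samp_all[rows, , drop = FALSE]
    nk <- nrow(co)
    fw <- spatial_forward_cached(spatial, gcoords, pre)
    zvol <- array(fw$z, dims)
    pred <- nufft_forward(plan, zvol, co, coils)
    resid <- pred - me
    lk <- sum(colMeans(Mod(resid)^2))
    ltv <- loss_tv(zvol)
    l <- total_loss(lk, ltv, cfg$lambda_tv)
    check_finite_loss(l, "stage 2")
    gvol <- (2 / nk) * nufft_adjoint_raw(plan, resid, co, coils)
    gvol <- gvol + cfg$lambda_tv * loss_tv_grad(zvol)
    gv <- as.vector(gvol)
    grads <- spatial_backward(spatial, gcoords, fw, Re(gv), Im(gv), pre)
    up <- adam_step(params, grads, st, cfg$lr[2], cfg$adam_beta1,
                    cfg$adam_beta2, cfg$adam_eps)
    params <- up$params
    st <- up$state
    spatial <- spatial_set_params(spatial, params)
    report[[ep]] <- data.frame(stage = 2L, epoch = ep, L_image = NA_real_,
                               L_kspace = lk, L_TV = ltv, L_total = l)
  }
  list(model = spatial, report = do.call(rbind, report))
}

# precomputed flat views of a PCA basis for the stage-3 inner loop
basis_matrices <- function(basis) {
  comps <- basis$components
  np <- length(comps)
  dims <- comps[[1]]$dims
  nvox <- prod(dims)
  E <- vector("list", 3L)
  for (c in 1:3) {
    Ec <- matrix(0, nvox, np)
    for (i in seq_len(np)) Ec[, i] <- as.vector(comps[[i]]$vectors[, , , c])
    E[[c]] <- Ec
  }
  e0 <- matrix(as.numeric(basis$e0$vectors), nvox, 3L)
  list(E = E, e0 = e0, n_pc = np, dims = dims,
       voxel_mm = comps[[1]]$voxel_mm)
}

#' Stage 3: joint spatial/temporal training from the cine k-space series
#'
#' Each epoch draws `n_batch` random frames; for each frame the temporal
#' INR (with perturbed frame index) yields the nine PC weights, the
#' motion model composes the frame DVF, the rendered reference is warped
#' and forward-projected onto that frame's spokes, and the batched
#' k-space loss plus TV regularization is backpropagated jointly into
#' both networks and both hash encodings.
#'
#' @param spatial trained [spatial_inr()] (stage-2 output).
#' @param temporal a [temporal_inr()].
#' @param basis a [pca_basis()] (offline or online).
#' @param ks the `kspace_series`.
#' @param cfg a [train_config()].
#' @param plan optional [nufft_plan()].
#' @return An object of class `recon_result`: trained models, `z_ref`
#'   [complex_volume()], per-frame `weight_trace` (n_t x 9), the basis,
#'   and the training `report`.
#' @export
stage3 <- function(spatial, temporal, basis, ks, cfg = train_config(),
                   plan = NULL) {
  dims <- as.integer(ks$dims)
  if (is.null(plan)) plan <- nufft_plan(dims, cfg$oversamp, cfg$kb_width)
  bm <- basis_matrices(basis)
  stopifnot(identical(bm$dims, dims))
  nvox <- prod(dims)
  n_t <- ks$n_t
  # per-component weight scaling: the components have unit Hilbert norm,
  # so physical PC coefficients are large; whitening by the training
  # singular values keeps the temporal INR outputs O(1) and the joint
  # optimization well conditioned.  The stored weight trace is on the
  # physical (unwhitened) scale.
  wscale <- basis$singular_values
  if (!is.null(basis$n_train) && all(is.finite(wscale)))
    wscale <- wscale / sqrt(basis$n_train)
  if (any(!is.finite(wscale)) || any(wscale <= 0))
    wscale <- vapply(basis$components,
                     function(e) 10 / max(abs(e$vectors)), numeric(1))
  gcoords <- grid_coords_scaled(dims)
  pre <- hash_precompute(gcoords, spatial$config)
  t_scaled <- if (n_t > 1) 2 * (seq_len(n_t) - 1) / (n_t - 1) - 1 else 0
  sigma <- if (identical(cfg$perturb, "frame")) {
    if (n_t > 1) 0.5 * (t_scaled[2] - t_scaled[1]) else 0
  } else as.numeric(cfg$perturb)
  vox <- bm$voxel_mm

  sp_par <- spatial_params(spatial)
  tp_par <- temporal_params(temporal)
  sp_st <- adam_init(sp_par)
  tp_st <- adam_init(tp_par)
  report <- vector("list", cfg$epochs[3])

  for (ep in seq_len(cfg$epochs[3])) {
    batch <- sample.int(n_t, min(cfg$n_batch, n_t))
    fw <- spatial_forward_cached(spatial, gcoords, pre)
    zvec <- fw$z
    zvol <- array(zvec, dims)
    tf <- temporal_forward_cached(temporal, t_scaled[batch],
                                  perturb = sigma > 0, sigma = sigma)
    gz <- complex(length(zvec))
    gW <- matrix(0, length(batch), 9L)
    lk_sum <- 0
    nb <- length(batch)
    for (bi in seq_len(nb)) {
      t <- batch[bi]
      wmat <- pc_weights(tf$W[bi, ]) * wscale
      dmm <- bm$e0
      for (c in 1:3) dmm[, c] <- dmm[, c] + bm$E[[c]] %*% wmat[, c]
      dvox <- sweep(dmm, 2L, vox, "/")
      warped <- warp_trilinear(zvec, dims, dvox)
      co <- frame_coords(ks, t)
      me <- frame_samples(ks, t)
      pred <- nufft_forward(plan, array(warped, dims), co, ks$coils)
      resid <- pred - me
      lk_sum <- lk_sum + sum(colMeans(Mod(resid)^2))
      gvol <- (2 / (nrow(co) * nb)) *
        nufft_adjoint_raw(plan, resid, co, ks$coils)
      bw <- warp_trilinear_backward(Re(gvol), Im(gvol), zvec,
                                    dims, dvox)
      gz <- gz + bw$grad_ref
      gdmm <- sweep(bw$grad_dvf, 2L, vox, "/")
      for (c in 1:3)
        gW[bi, (c - 1L) * 3L + seq_len(3L)] <-
          wscale * as.numeric(crossprod(bm$E[[c]], gdmm[, c]))
    }
    lk <- lk_sum / nb
    ltv <- loss_tv(zvol)
    l <- total_loss(lk, ltv, cfg$lambda_tv)
    check_finite_loss(l, "stage 3")
    gz <- gz + cfg$lambda_tv * loss_tv_grad(zvol)
    sp_gr <- spatial_backward(spatial, gcoords, fw, Re(gz), Im(gz), pre)
    tp_gr <- temporal_backward(temporal, tf, gW)
    up <- adam_step(sp_par, sp_gr, sp_st, cfg$lr[3], cfg$adam_beta1,
                    cfg$adam_beta2, cfg$adam_eps)
    sp_par <- up$params; sp_st <- up$state
    spatial <- spatial_set_params(spatial, sp_par)
    up <- adam_step(tp_par, tp_gr, tp_st, cfg$lr[3], cfg$adam_beta1,
                    cfg$adam_beta2, cfg$adam_eps)
    tp_par <- up$params; tp_st <- up$state
    temporal <- temporal_set_params(temporal, tp_par)
    report[[ep]] <- data.frame(stage = 3L, epoch = ep, L_image = NA_real_,
                               L_kspace = lk, L_TV = ltv, L_total = l)
  }
  z_ref <- complex_volume(array(spatial_forward(spatial, gcoords), dims),
                          ks$voxel_mm)
  weight_trace <- temporal_forward(temporal, t_scaled, perturb = FALSE)
  weight_trace <- weight_trace * rep(wscale, 3)[rep(1:9, each = nrow(weight_trace))]
  dim(weight_trace) <- c(n_t, 9L)
  structure(list(spatial = spatial, temporal = temporal, basis = basis,
                 z_ref = z_ref, weight_trace = weight_trace,
                 t_scaled = t_scaled, n_t = n_t, dims = dims,
                 voxel_mm = ks$voxel_mm, timestamps_ms = ks$timestamps_ms,
                 report = do.call(rbind, report)),
            class = "recon_result")
}

#' Per-component PC weight trace of a reconstruction
#'
#' Projects the recovered per-frame DVFs (minus the basis mean field)
#' onto the orthonormal basis components, reducing the nine
#' per-direction weights to the three per-component coefficients of the
#' motion model — directly comparable with [project_dvf()] applied to
#' ground-truth DVFs.
#'
#' @param result a `recon_result`.
#' @return `n_t` x `n_pc` matrix of projections.
#' @export
recon_pc_trace <- function(result) {
  basis <- result$basis
  np <- basis$n_pc
  # inner products m[i, j, c] = <e_i^c, e_j^c> per Cartesian direction
  m <- array(0, c(np, np, 3))
  for (c in 1:3) for (i in seq_len(np)) for (j in seq_len(np))
    m[i, j, c] <- sum(basis$components[[i]]$vectors[, , , c] *
                        basis$components[[j]]$vectors[, , , c])
  W <- result$weight_trace
  out <- matrix(0, nrow(W), np)
  for (j in seq_len(np)) for (c in 1:3) for (i in seq_len(np))
    out[, j] <- out[, j] + W[, (c - 1L) * np + i] * m[i, j, c]
  out
}

#' Frame DVF of a reconstruction
#' @param result a `recon_result`.
#' @param t frame index.
#' @return A [dvf_field()] composed from the basis and the frame's
#'   recovered PC weights.
#' @export
recon_dvf <- function(result, t) {
  compose_dvf(result$basis, pc_weights(result$weight_trace[t, ]))
}

#' Materialize one reconstructed cine frame
#' @param result a `recon_result`.
#' @param t frame index.
#' @return A [complex_volume()], `warp_volume(z_ref, recon_dvf(result, t))`.
#' @export
recon_frame <- function(result, t) {
  warp_volume(result$z_ref, recon_dvf(result, t))
}

#' One-shot reconstruction from a k-space series
#'
#' Full pipeline: surrogate extraction, respiratory binning, adjoint
#' NUFFT of the end-of-exhale bin, then the three progressive training
#' stages.  With `basis_source = "online"` the PCA motion model is first
#' built from the data themselves (bin reconstructions registered to the
#' exhale bin); with `"offline"` a prior [pca_basis()] must be supplied.
#' Deterministic end-to-end given `cfg$seed`.
#'
#' @param ks a `kspace_series`.
#' @param cfg a [train_config()].
#' @param basis_source `"offline"` or `"online"`.
#' @param basis a [pca_basis()] (required for `"offline"`).
#' @return A `recon_result` (see [stage3()]); the intermediate stage
#'   reports are row-bound into `$report`, and the binning, surrogate
#'   and exhale reconstruction are attached.
#' @export
reconstruct <- function(ks, cfg = train_config(),
                        basis_source = c("offline", "online"), basis = NULL) {
  basis_source <- match.arg(basis_source)
  if (basis_source == "offline" && is.null(basis))
    stop("offline reconstruction requires a supplied PCA basis")
  dims <- as.integer(ks$dims)
  with_seed(cfg$seed, {
    plan <- nufft_plan(dims, cfg$oversamp, cfg$kb_width)
    surr <- extract_surrogate(ks)
    bins <- sort_bins(surr, cfg$n_bins)
    exh <- bin_kspace(ks, bins, bins$exhale_bin)
    z_exhale <- complex_volume(
      array(nufft_adjoint(plan, exh$samples, exh$coords, coils = ks$coils),
            dims), ks$voxel_mm)
    if (basis_source == "online") {
      vols <- reconstruct_bins(ks, bins, plan)
      phases <- register_phases(vols, bins$exhale_bin)
      basis <- pca_basis(phases$dvfs, cfg$n_pc)
    }
    spatial <- spatial_inr(cfg$spatial_config, seed = cfg$seed,
                           omega0 = cfg$omega0)
    temporal <- temporal_inr(cfg$temporal_config, seed = cfg$seed + 100)
    s1 <- stage1(spatial, z_exhale, cfg)
    s2 <- stage2(s1$model, exh, ks$readout_points, dims, cfg,
                 coils = ks$coils, plan = plan)
    res <- stage3(s2$model, temporal, basis, ks, cfg, plan = plan)
    res$report <- rbind(s1$report, s2$report, res$report)
    res$surrogate <- surr
    res$bins <- bins
    res$z_exhale <- z_exhale
    res$basis_source <- basis_source
    res
  })
}

#' Write a training loss report as CSV
#' @param result a `recon_result` (or a report data frame).
#' @param path output CSV.
#' @return `path` invisibly.
#' @export
write_loss_report <- function(result, path) {
  rep <- if (is.data.frame(result)) result else result$report
  utils::write.csv(rep, path, row.names = FALSE)
  invisible(path)
}
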