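#' Image-domain similarity loss
#'
#' Mean squared complex modulus of the voxelwise difference,
#' `(1/N_voxel) * sum |z_ref(x) - z_exhale(x)|^2` (the stage-1 loss).
#'
#' @param z_ref,z_exhale complex arrays or [complex_volume()] objects of
#'   matching shape.
#' @return scalar loss.
#' @export
loss_image <- function(z_ref, z_exhale) {
  a <- if (inherits(z_ref, "complex_volume")) z_ref$data else z_ref
  b <- if (inherits(z_exhale, "complex_volume")) z_exhale$data else z_exhale
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  mean(Mod(a - b)^2)
}

#' k-space similarity loss
#'
#' Mean squared complex modulus of the sample residuals.  With multiple
#' coils the per-coil losses (each a mean over that coil's samples) are
#' summed.
#'
#' @param pred,meas complex sample vectors or m x n_coils matrices.
#' @return scalar loss.
#' @export
loss_kspace <- function(pred, meas) {
  pred <- as.matrix(pred)
  meas <- as.matrix(meas)
  if (!identical(dim(pred), dim(meas))) stop("shape mismatch")
  sum(colMeans(Mod(pred - meas)^2))
}

#' Batched k-space loss over frames
#'
#' `(1/N_batch) * sum_t (1/N_k^t) * sum_k |F[z_t](k) - w_t(k)|^2`: the
#' per-frame means averaged over the sampled batch of frames.
#'
#' @param pred_list,meas_list lists of per-frame sample matrices.
#' @return scalar loss.
#' @export
loss_kspace_batched <- function(pred_list, meas_list) {
  stopifnot(length(pred_list) == length(meas_list))
  mean(mapply(loss_kspace, pred_list, meas_list))
}

#' Total-variation regularization of the reference magnitude
#'
#' `(1/N_voxel) * sum_x |grad |z_ref(x)||` with forward differences
#' (zero at the far boundary).  The default is the anisotropic form (L1
#' of the axis differences); `isotropic = TRUE` uses the Euclidean norm
#' of the gradient vector instead.
#'
#' @param z_ref complex (or real) array or [complex_volume()].
#' @param isotropic use the isotropic gradient norm.
#' @return scalar loss.
#' @export
loss_tv <- function(z_ref, isotropic = FALSE) {
  a <- if (inherits(z_ref, "complex_volume")) z_ref$data else z_ref
  m <- Mod(a)
  d <- dim(m)
  ip <- function(n) pmin(seq_len(n) + 1L, n)
  dx <- m[ip(d[1]), , , drop = FALSE] - m
  dy <- m[, ip(d[2]), , drop = FALSE] - m
  dz <- m[, , ip(d[3]), drop = FALSE] - m
  dx[d[1], , ] <- 0; dy[, d[2], ] <- 0; dz[, , d[3]] <- 0
  if (isotropic) mean(sqrt(dx^2 + dy^2 + dz^2))
  else mean(abs(dx) + abs(dy) + abs(dz))
}

# gradient of loss_tv with respect to Re/Im of z (complex array in, the
# complex Wirtinger-style gradient pair out as a complex array)
loss_tv_grad <- function(z, isotropic = FALSE) {
  m <- Mod(z)
  d <- dim(m)
  n <- length(m)
  ip <- function(nn) pmin(seq_len(nn) + 1L, nn)
  dx <- m[ip(d[1]), , , drop = FALSE] - m
  dy <- m[, ip(d[2]), , drop = FALSE] - m
  dz <- m[, , ip(d[3]), drop = FALSE] - m
  dx[d[1], , ] <- 0; dy[, d[2], ] <- 0; dz[, , d[3]] <- 0
  if (isotropic) {
    nr <- sqrt(dx^2 + dy^2 + dz^2)
    nr[nr < 1e-12] <- Inf
    sx <- dx / nr; sy <- dy / nr; sz <- dz / nr
  } else {
    sx <- sign(dx); sy <- sign(dy); sz <- sign(dz)
  }
  gm <- array(0, d)
  gm <- gm - sx - sy - sz
  gm[2:d[1], , ] <- gm[2:d[1], , ] + sx[1:(d[1] - 1), , ]
  gm[, 2:d[2], ] <- gm[, 2:d[2], ] + sy[, 1:(d[2] - 1), ]
  gm[, , 2:d[3]] <- gm[, , 2:d[3]] + sz[, , 1:(d[3] - 1)]
  gm <- gm / n
  safe <- m
  safe[safe < 1e-12] <- Inf
  complex(real = gm * Re(z) / safe, imaginary = gm * Im(z) / safe)
}

#' Total training loss
#'
#' Weighted sum `L_kspace + lambda_tv * L_TV`.
#'
#' @param l_kspace k-space similarity loss.
#' @param l_tv total-variation loss.
#' @param lambda_tv TV weighting factor (>= 0).
#' @return scalar.
#' @export
total_loss <- function(l_kspace, l_tv, lambda_tv) {
  stopifnot(lambda_tv >= 0)
  l_kspace + lambda_tv * l_tv
}

# ---------------------------------------------------------------------------
# Adam over nested parameter lists
# ---------------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      list(p = p - lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps), m = m2, v = v2)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# trainable views of the models -------------------------------------------

spatial_params <- function(model)
  list(tables = unclass(model$tables), re = model$re, im = model$im)

spatial_set_params <- function(model, p) {
  attrs <- attributes(model$tables)
  model$tables <- structure(p$tables, class = "hash_tables",
                            config = attrs$config)
  model$re <- p$re
  model$im <- p$im
  model
}

temporal_params <- function(model)
  list(tables = unclass(model$tables), heads = model$heads)

temporal_set_params <- function(model, p) {
  attrs <- attributes(model$tables)
  model$tables <- structure(p$tables, class = "hash_tables",
                            config = attrs$config)
  model$heads <- p$heads
  model
}
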