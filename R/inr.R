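# Spatial and temporal implicit neural representations.
#
# The spatial INR maps a 3D coordinate in [-1,1]^3 through the shared
# multiresolution hash encoding into two small sine-activated MLPs
# (32 -> 32 -> 1) for the real and imaginary image parts.  The temporal
# INR maps a scaled frame index through its own (1D) hash encoding into
# nine parallel ReLU MLPs (32 -> 32 -> 32 -> 1), one per PC weight
# (three principal motion components x three Cartesian directions).
# Forward passes return caches; backward passes are hand-derived.

runif_mat <- function(nr, nc, a) matrix(runif(nr * nc, -a, a), nr, nc)

#' Construct a spatial INR
#'
#' @param config a [hash_config()] with `input_dim = 3`.
#' @param seed RNG seed for table and weight initialization.
#' @param omega0 sine activation frequency scale (SIREN-style).
#' @param hidden hidden layer width.
#' @return An object of class `spatial_inr`.
#' @export
spatial_inr <- function(config = hash_config(), seed = 1, omega0 = 30,
                        hidden = 32) {
  stopifnot(config$input_dim == 3L)
  nin <- config$n_levels * config$n_features
  with_seed(seed, {
    tables <- hash_tables_init(config, seed = seed + 1)
    mk <- function() list(
      W1 = runif_mat(nin, hidden, 1 / nin), b1 = numeric(hidden),
      W2 = runif_mat(hidden, 1, sqrt(6 / hidden) / omega0), b2 = 0)
    structure(list(config = config, omega0 = omega0, hidden = hidden,
                   tables = tables, re = mk(), im = mk()),
              class = "spatial_inr")
  })
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# precomputed encoding topology for a fixed coordinate set (levels'
# corner rows + interpolation weights); makes repeated forward/backward
# passes over the same grid cheap
hash_precompute <- function(coords, config) {
  hash_precompute_cpp(coords, level_resolutions(config), config$table_size)
}

encode_with <- function(tables, config, coords, pre = NULL) {
  if (is.null(pre))
    hash_encode_cpp(coords, unclass(tables), level_resolutions(config),
                    config$table_size, config$n_features)
  else hash_encode_pre_cpp(unclass(tables), pre$idx, pre$wts, pre$ncorner,
                           config$n_features)
}

encode_backward_with <- function(tables, config, coords, gfeat, pre = NULL) {
  if (is.null(pre))
    hash_encode_backward_cpp(coords, gfeat, unclass(tables),
                             level_resolutions(config), config$table_size,
                             config$n_features)
  else hash_encode_backward_pre_cpp(unclass(tables), pre$idx, pre$wts, gfeat,
                                    pre$ncorner, config$n_features)
}

# full forward with cache (internal)
spatial_forward_cached <- function(model, coords, pre = NULL) {
  feat <- encode_with(model$tables, model$config, coords, pre)
  w0 <- model$omega0
  pre_r <- add_bias(feat %*% model$re$W1, model$re$b1)
  h_r <- sin(w0 * pre_r)
  y_r <- as.vector(h_r %*% model$re$W2) + model$re$b2
  pre_i <- add_bias(feat %*% model$im$W1, model$im$b1)
  h_i <- sin(w0 * pre_i)
  y_i <- as.vector(h_i %*% model$im$W2) + model$im$b2
  list(z = complex(real = y_r, imaginary = y_i), feat = feat,
       pre_r = pre_r, h_r = h_r, pre_i = pre_i, h_i = h_i)
}

#' Evaluate the spatial INR
#'
#' Batch evaluation at arbitrary (also non-integer, enabling
#' super-resolution queries) coordinates.
#'
#' @param model a [spatial_inr()].
#' @param coords n x 3 matrix in `[-1, 1]^3`.
#' @return complex vector of length n.
#' @export
spatial_forward <- function(model, coords) {
  spatial_forward_cached(model, coords)$z
}

# backward: gr, gi = dL/d(Re z), dL/d(Im z).  Returns gradients for all
# trainable parameters (hash tables + both MLPs).
spatial_backward <- function(model, coords, cache, gr, gi, pre = NULL) {
  w0 <- model$omega0
  gfeat <- matrix(0, nrow(cache$feat), ncol(cache$feat))
  branch <- function(g, part, pre, h) {
    gW2 <- crossprod(h, g)                       # hidden x 1
    gb2 <- sum(g)
    gh <- g %*% t(part$W2)                       # n x hidden
    gpre <- gh * (w0 * cos(w0 * pre))
    gW1 <- crossprod(cache$feat, gpre)
    gb1 <- colSums(gpre)
    gfeat <<- gfeat + gpre %*% t(part$W1)
    list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  g_re <- branch(matrix(gr, ncol = 1), model$re, cache$pre_r, cache$h_r)
  g_im <- branch(matrix(gi, ncol = 1), model$im, cache$pre_i, cache$h_i)
  g_tab <- encode_backward_with(model$tables, model$config, coords, gfeat, pre)
  list(tables = g_tab, re = g_re, im = g_im)
}

#' Construct a temporal INR
#'
#' @param config a [hash_config()] with `input_dim = 1` (by default the
#'   spatial hyper-parameters reused on a 1D grid, where the tables are
#'   collision-free and indexing is direct).
#' @param seed RNG seed.
#' @param hidden hidden layer width.
#' @param n_out number of PC weight outputs (default 9).
#' @return An object of class `temporal_inr`.
#' @export
temporal_inr <- function(config = hash_config(input_dim = 1), seed = 1,
                         hidden = 32, n_out = 9) {
  stopifnot(config$input_dim == 1L)
  nin <- config$n_levels * config$n_features
  with_seed(seed, {
    tables <- hash_tables_init(config, seed = seed + 1)
    heads <- lapply(seq_len(n_out), function(i) list(
      W1 = runif_mat(nin, hidden, sqrt(6 / nin)), b1 = numeric(hidden),
      W2 = runif_mat(hidden, hidden, sqrt(6 / hidden)), b2 = numeric(hidden),
      W3 = matrix(0, hidden, 1), b3 = 0))   # zero head: weights start at 0
    structure(list(config = config, hidden = hidden, n_out = n_out,
                   tables = tables, heads = heads),
              class = "temporal_inr")
  })
}

temporal_forward_cached <- function(model, t_scaled, perturb = FALSE,
                                    sigma = 0) {
  t_in <- t_scaled
  if (perturb && sigma > 0) t_in <- t_in + rnorm(length(t_in), 0, sigma)
  coords <- matrix(pmin(1, pmax(-1, t_in)), ncol = 1L)
  feat <- hash_encode(coords, model$tables, model$config)
  n <- nrow(coords)
  W <- matrix(0, n, model$n_out)
  caches <- vector("list", model$n_out)
  for (j in seq_len(model$n_out)) {
    hd <- model$heads[[j]]
    pre1 <- add_bias(feat %*% hd$W1, hd$b1)
    h1 <- pmax(pre1, 0)
    pre2 <- add_bias(h1 %*% hd$W2, hd$b2)
    h2 <- pmax(pre2, 0)
    W[, j] <- as.vector(h2 %*% hd$W3) + hd$b3
    caches[[j]] <- list(pre1 = pre1, h1 = h1, pre2 = pre2, h2 = h2)
  }
  list(W = W, feat = feat, coords = coords, caches = caches)
}

#' Evaluate the temporal INR
#'
#' Returns the nine PC weights at the queried scaled frame indices,
#' optionally perturbing the input within the frame interval with
#' Gaussian noise (to force a continuous representation; draws use the
#' current RNG stream).
#'
#' @param model a [temporal_inr()].
#' @param t_scaled numeric vector of scaled frame indices in `[-1, 1]`.
#' @param perturb add Gaussian input perturbation.
#' @param sigma perturbation SD in scaled units (default half the frame
#'   interval, supplied by the caller).
#' @return n x 9 matrix of PC weights; use [pc_weights()] to reshape one
#'   row into the 3 x 3 (component x direction) form.
#' @export
temporal_forward <- function(model, t_scaled, perturb = FALSE, sigma = 0) {
  temporal_forward_cached(model, t_scaled, perturb, sigma)$W
}

temporal_backward <- function(model, cache, gW) {
  gfeat <- matrix(0, nrow(cache$feat), ncol(cache$feat))
  gheads <- vector("list", model$n_out)
  for (j in seq_len(model$n_out)) {
    hd <- model$heads[[j]]
    cj <- cache$caches[[j]]
    g3 <- matrix(gW[, j], ncol = 1)
    gW3 <- crossprod(cj$h2, g3)
    gb3 <- sum(g3)
    gh2 <- g3 %*% t(hd$W3)
    gpre2 <- gh2 * (cj$pre2 > 0)
    gW2 <- crossprod(cj$h1, gpre2)
    gb2 <- colSums(gpre2)
    gh1 <- gpre2 %*% t(hd$W2)
    gpre1 <- gh1 * (cj$pre1 > 0)
    gW1 <- crossprod(cache$feat, gpre1)
    gb1 <- colSums(gpre1)
    gfeat <- gfeat + gpre1 %*% t(hd$W1)
    gheads[[j]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                        W3 = gW3, b3 = gb3)
  }
  g_tab <- hash_encode_backward(cache$coords, gfeat, model$tables,
                                model$config)
  list(tables = g_tab, heads = gheads)
}

#' Reshape one nine-vector of PC weights to component x direction form
#'
#' Column order convention: the nine outputs are grouped by Cartesian
#' direction (x, y, z), three principal components within each.
#'
#' @param w9 numeric vector of length 9 (or n x 9 matrix row).
#' @return 3 x 3 matrix `w[i, c]` (component i, direction c).
#' @export
pc_weights <- function(w9) matrix(as.numeric(w9), 3L, 3L)

#' Save / load model checkpoints
#'
#' Serializes the full model state (hash tables, MLP weights, config and
#' the caller-supplied RNG state) so that a save/load round trip is
#' bit-exact.
#'
#' @param models named list of model objects (and any training state).
#' @param path checkpoint file.
#' @return `path` invisibly; `load_checkpoint` returns the list.
#' @export
save_checkpoint <- function(models, path) {
  genv <- globalenv()
  models$.rng <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  saveRDS(models, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param restore_rng restore the saved RNG state into the session.
#' @export
load_checkpoint <- function(path, restore_rng = FALSE) {
  models <- readRDS(path)
  if (restore_rng && !is.null(models$.rng))
    assign(".Random.seed", models$.rng, envir = globalenv())
  models$.rng <- NULL
  models
}
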