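# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

# Uniformly distributed unit 3-vectors.
random_unit_vectors <- function(n) {
  z <- runif(n, -1, 1)
  th <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(th), r * sin(th), z)
}

# Voxel-centre coordinate grids, 0-based index space, as an n x 3 matrix.
index_grid <- function(dims) {
  cbind(
    rep.int(seq_len(dims[1]) - 1, times = dims[2] * dims[3]),
    rep.int(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]),
    rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])
  )
}

# Scale 0-based voxel indices to [-1, 1] per axis (the INR input domain).
scale_coords_unit <- function(idx, dims) {
  sweep(sweep(idx, 2L, (dims - 1) / 2, "-"), 2L, pmax((dims - 1) / 2, 1e-9), "/")
}

linear_interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout, rule = 2)$y
}
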