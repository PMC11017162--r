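# Independent brute-force oracles used across the suite.  These are
# deliberately naive (loops, direct sums) so they stay independent of the
# implementation paths they check.

# direct type-2 non-uniform DFT: y_j = sum_x z(x) exp(-2i pi nu_j.(x - c))
direct_nudft <- function(vol, coords) {
  dims <- dim(vol)
  ctr <- dims %/% 2
  idx <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                               z = 0:(dims[3] - 1)))
  idxc <- sweep(idx, 2, ctr)
  ph <- exp(-2i * pi * (coords %*% t(idxc)))
  as.vector(ph %*% as.vector(vol))
}

# loop implementations of the training losses
loop_loss_image <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + Mod(a[i] - b[i])^2
  s / length(a)
}

loop_loss_kspace <- function(pred, meas) {
  pred <- as.matrix(pred); meas <- as.matrix(meas)
  tot <- 0
  for (c in seq_len(ncol(pred))) {
    s <- 0
    for (i in seq_len(nrow(pred))) s <- s + Mod(pred[i, c] - meas[i, c])^2
    tot <- tot + s / nrow(pred)
  }
  tot
}

loop_loss_tv <- function(z) {
  m <- Mod(z)
  d <- dim(m)
  s <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (zz in 1:d[3]) {
    if (x < d[1]) s <- s + abs(m[x + 1, y, zz] - m[x, y, zz])
    if (y < d[2]) s <- s + abs(m[x, y + 1, zz] - m[x, y, zz])
    if (zz < d[3]) s <- s + abs(m[x, y, zz + 1] - m[x, y, zz])
  }
  s / length(m)
}

# naive metric implementations
loop_relative_error <- function(a, b) {
  num <- den <- 0
  for (i in seq_along(a)) {
    num <- num + (Mod(a[i]) - Mod(b[i]))^2
    den <- den + Mod(b[i])^2
  }
  sqrt(num / den)
}

loop_dice <- function(y, ygt) {
  inter <- 0; sy <- 0; sg <- 0
  for (i in seq_along(y)) {
    if (y[i] && ygt[i]) inter <- inter + 1
    if (y[i]) sy <- sy + 1
    if (ygt[i]) sg <- sg + 1
  }
  if (sy + sg == 0) 1 else 2 * inter / (sy + sg)
}

# brute-force lattice count of a sphere (tumor voxel oracle)
lattice_sphere_count <- function(radius_vox) {
  r <- ceiling(radius_vox)
  n <- 0L
  for (x in -r:r) for (y in -r:r) for (z in -r:r)
    if (x^2 + y^2 + z^2 <= radius_vox^2) n <- n + 1L
  n
}

# brute-force d-linear interpolation of one hash level (collision-free)
bf_hash_level <- function(coord, tab, res) {
  d <- length(coord)
  x <- (coord + 1) / 2 * res
  v0 <- pmin(pmax(floor(x), 0), res - 1)
  fr <- x - v0
  acc <- numeric(ncol(tab))
  for (corner in 0:(2^d - 1)) {
    bits <- as.integer(intToBits(corner))[1:d]
    v <- v0 + bits
    wt <- prod(ifelse(bits == 1, fr, 1 - fr))
    idx <- 0
    for (k in d:1) idx <- idx * (res + 1) + v[k]
    acc <- acc + wt * tab[idx + 1, ]
  }
  acc
}

# naive trilinear pull-back warp of a complex volume (zero outside)
loop_warp <- function(ref, d_vox) {
  dims <- dim(ref)
  out <- array(0i, dims)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    p <- c(x - 1, y - 1, z - 1) + d_vox[x, y, z, ]
    f0 <- floor(p)
    fr <- p - f0
    acc <- 0i
    for (corner in 0:7) {
      bits <- as.integer(intToBits(corner))[1:3]
      v <- f0 + bits
      if (any(v < 0) || any(v > dims - 1)) next
      wt <- prod(ifelse(bits == 1, fr, 1 - fr))
      acc <- acc + wt * ref[v[1] + 1, v[2] + 1, v[3] + 1]
    }
    out[x, y, z] <- acc
  }
  out
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(Mod(actual - expected)) / max(Mod(expected)), tol)
}
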