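#' Multiresolution hash encoding configuration
#'
#' @param n_levels number of resolution levels `L` (>= 2).
#' @param table_size maximum entries per level `T` (a power of two).
#' @param n_features features per entry `F`.
#' @param res_min coarsest grid resolution.
#' @param res_max finest grid resolution (> `res_min`).
#' @param input_dim input dimensionality `d` (3 spatial, 1 temporal).
#' @return An object of class `hash_config`.
#' @export
hash_config <- function(n_levels = 16, table_size = 2^19, n_features = 2,
                        res_min = 16, res_max = 10509, input_dim = 3) {
  stopifnot(n_levels >= 2, res_min >= 1, res_min < res_max,
            n_features >= 1, input_dim %in% c(1L, 2L, 3L))
  if (bitwAnd(table_size, table_size - 1) != 0)
    stop("table_size must be a power of two")
  structure(list(n_levels = as.integer(n_levels),
                 table_size = as.integer(table_size),
                 n_features = as.integer(n_features),
                 res_min = as.integer(res_min), res_max = as.integer(res_max),
                 input_dim = as.integer(input_dim)),
            class = "hash_config")
}

#' Per-level grid resolutions
#'
#' Geometric growth `N_l = floor(res_min * b^l)` with
#' `b = exp((log res_max - log res_min) / (L - 1))`, so level 0 is the
#' coarsest and level `L - 1` hits the finest resolution exactly.
#'
#' @param config a [hash_config()].
#' @return integer vector of length `n_levels`.
#' @export
level_resolutions <- function(config) {
  L <- config$n_levels
  b <- exp((log(config$res_max) - log(config$res_min)) / (L - 1))
  # guard the top level against floor(res_min * b^(L-1)) dropping below
  # res_max through floating-point round-off
  r <- floor(config$res_min * b^(0:(L - 1)) + 1e-9)
  as.integer(r)
}

#' Hash-table row of a grid vertex
#'
#' Direct (collision-free) row-major indexing when the level's vertex
#' grid fits into the table, otherwise the XOR spatial hash with primes
#' `(1, 2654435761, 805459861)` modulo the table size.
#'
#' @param vertex integer vertex index vector (length `input_dim`), or a
#'   matrix of vertices (rows).
#' @param level level index (1-based).
#' @param config a [hash_config()].
#' @return 0-based table row index (vector).
#' @export
hash_index <- function(vertex, level, config) {
  res <- level_resolutions(config)[level]
  v <- if (is.matrix(vertex)) vertex else matrix(vertex, nrow = 1)
  hash_index_cpp(matrix(as.integer(v), nrow(v), ncol(v)), res,
                 config$table_size)
}

#' Initialize the learnable hash tables
#'
#' One table per level, `min(T, (N_l + 1)^d)` rows by `n_features`
#' columns, entries uniform in `[-init_scale, init_scale]`.
#'
#' @param config a [hash_config()].
#' @param seed RNG seed.
#' @param init_scale initialization half-width (default `1e-4`).
#' @return list of per-level matrices (class `hash_tables`).
#' @export
hash_tables_init <- function(config, seed = 1, init_scale = 1e-4) {
  res <- level_resolutions(config)
  with_seed(seed, {
    tabs <- lapply(res, function(r) {
      rows <- min(config$table_size, (r + 1)^config$input_dim)
      matrix(runif(rows * config$n_features, -init_scale, init_scale),
             rows, config$n_features)
    })
    structure(tabs, class = "hash_tables", config = config)
  })
}

#' Multiresolution hash encoding of coordinates
#'
#' Per level: scale the `[-1, 1]` coordinate to the level's grid, gather
#' the `2^d` surrounding vertex entries, d-linearly interpolate, and
#' concatenate across levels.  Coordinates outside `[-1, 1]` are clamped
#' with a warning.  Differentiable with respect to the table entries
#' (see [hash_encode_backward()]); piecewise-linear in the coordinates.
#'
#' @param coords n x d matrix in `[-1, 1]^d` (a vector is treated as one
#'   point for `d > 1`, or as n points for `d = 1`).
#' @param tables a [hash_tables_init()] result.
#' @param config the matching [hash_config()].
#' @return n x (`n_levels * n_features`) feature matrix.
#' @export
hash_encode <- function(coords, tables, config = attr(tables, "config")) {
  if (!is.matrix(coords))
    coords <- if (config$input_dim == 1L) matrix(coords, ncol = 1L)
              else matrix(coords, nrow = 1L)
  stopifnot(ncol(coords) == config$input_dim)
  if (max(abs(coords)) > 1 + 1e-12)
    warning("coordinates outside [-1, 1] were clamped")
  hash_encode_cpp(coords, unclass(tables), level_resolutions(config),
                  config$table_size, config$n_features)
}

#' Backward pass of the hash encoding
#'
#' Scatters the feature gradients back into per-level table gradients.
#'
#' @param coords the coordinates of the forward pass.
#' @param gfeat n x (`n_levels * n_features`) gradient of the loss with
#'   respect to the encoded features.
#' @inheritParams hash_encode
#' @return list of per-level gradient matrices shaped like the tables.
#' @export
hash_encode_backward <- function(coords, gfeat, tables,
                                 config = attr(tables, "config")) {
  if (!is.matrix(coords))
    coords <- if (config$input_dim == 1L) matrix(coords, ncol = 1L)
              else matrix(coords, nrow = 1L)
  hash_encode_backward_cpp(coords, gfeat, unclass(tables),
                           level_resolutions(config), config$table_size,
                           config$n_features)
}
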