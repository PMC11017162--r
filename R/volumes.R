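#' @useDynLib cineinr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd cor quantile
NULL

normalize_voxel_mm <- function(voxel_mm) {
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  stopifnot(length(voxel_mm) == 3L, all(voxel_mm > 0))
  as.numeric(voxel_mm)
}

#' Magnitude image volume
#'
#' A real-valued 3D image on a regular grid with intensities in `[0, 1]`,
#' optionally carrying an integer tissue/tumor label mask.
#'
#' @param data 3D numeric array with values in `[0, 1]`.
#' @param voxel_mm voxel size in mm (scalar isotropic or length-3).
#' @param labels optional integer array of the same dims (0 = background).
#' @return An object of class `mag_volume`.
#' @export
mag_volume <- function(data, voxel_mm, labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(dim(data) < 1L)) stop("volume dimensions must be positive")
  rng <- range(data)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("magnitude volume values must lie in [0, 1]")
  if (!is.null(labels)) stopifnot(identical(dim(labels), dim(data)))
  structure(list(data = data, dims = dim(data),
                 voxel_mm = normalize_voxel_mm(voxel_mm), labels = labels),
            class = "mag_volume")
}

#' Complex image volume
#'
#' @param data 3D complex array.
#' @param voxel_mm voxel size in mm (scalar or length-3).
#' @return An object of class `complex_volume`.
#' @export
complex_volume <- function(data, voxel_mm) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.complex(data)) {
    storage.mode(data) <- "complex"
  }
  structure(list(data = data, dims = dim(data),
                 voxel_mm = normalize_voxel_mm(voxel_mm)),
            class = "complex_volume")
}

#' Deformation vector field
#'
#' Per-voxel 3-vector displacement in mm, pull-back convention: a warped
#' image samples the reference at `x + d(x)`.
#'
#' @param vectors 4D numeric array `c(dims, 3)`, mm units.
#' @param voxel_mm voxel size in mm.
#' @return An object of class `dvf_field`.
#' @export
dvf_field <- function(vectors, voxel_mm) {
  stopifnot(is.array(vectors), length(dim(vectors)) == 4L, dim(vectors)[4] == 3L)
  structure(list(vectors = vectors, dims = dim(vectors)[1:3],
                 voxel_mm = normalize_voxel_mm(voxel_mm)),
            class = "dvf_field")
}

#' Zero deformation field on a grid
#' @param dims voxel counts per axis.
#' @param voxel_mm voxel size in mm.
#' @return A `dvf_field` of zeros.
#' @export
dvf_zero <- function(dims, voxel_mm) {
  dvf_field(array(0, c(dims, 3L)), voxel_mm)
}

same_grid <- function(a, b) {
  identical(as.integer(a$dims), as.integer(b$dims)) &&
    isTRUE(all.equal(a$voxel_mm, b$voxel_mm))
}

dvf_as_matrix_vox <- function(dvf) {
  n <- prod(dvf$dims)
  m <- matrix(dvf$vectors, n, 3L)
  sweep(m, 2L, dvf$voxel_mm, "/")
}

#' Hilbert-space inner product of two deformation fields
#'
#' Plain sum over voxels and Cartesian components of the pointwise products,
#' the inner product under which the PCA motion components are orthonormal.
#'
#' @param a,b `dvf_field` objects on the same grid.
#' @return scalar.
#' @export
dvf_inner <- function(a, b) {
  stopifnot(same_grid(a, b))
  sum(a$vectors * b$vectors)
}

#' @rdname dvf_inner
#' @export
dvf_norm <- function(a) sqrt(dvf_inner(a, a))

#' Warp a complex volume by a deformation field
#'
#' Pull-back warping of `z_t(x) = z_ref(x + d_t(x))`: the output voxel at
#' `x` samples the reference at the displaced position via trilinear
#' interpolation applied separately to the real and imaginary parts.
#' Samples falling outside the grid contribute zero.  The operation is
#' linear in `ref` and differentiable with respect to the displacement
#' (used during joint training).
#'
#' @param ref a `complex_volume` (or `mag_volume`, promoted to complex).
#' @param dvf a `dvf_field` on the same grid, mm units.
#' @return A `complex_volume`.
#' @export
warp_volume <- function(ref, dvf) {
  if (inherits(ref, "mag_volume"))
    ref <- complex_volume(ref$data + 0i, ref$voxel_mm)
  stopifnot(inherits(ref, "complex_volume"), inherits(dvf, "dvf_field"))
  if (!same_grid(ref, dvf)) stop("reference and DVF grids do not match")
  out <- warp_trilinear(as.vector(ref$data), as.integer(ref$dims),
                        dvf_as_matrix_vox(dvf))
  complex_volume(array(out, ref$dims), ref$voxel_mm)
}

#' Magnitude of a complex volume
#' @param z a `complex_volume`.
#' @return A `mag_volume` carrying `Mod(z)` (no clipping; magnitudes may
#'   exceed 1 for unnormalized reconstructions).
#' @export
vol_mod <- function(z) {
  m <- Mod(z$data)
  structure(list(data = m, dims = z$dims, voxel_mm = z$voxel_mm,
                 labels = NULL), class = "mag_volume")
}

#' Write a volume or DVF as NIfTI
#'
#' Volumes are written as 3D NIfTI (complex volumes as a 4D array with the
#' real and imaginary parts stacked in the fourth dimension); deformation
#' fields as 4D NIfTI with the vector components (mm, displacement,
#' pull-back convention) in the last dimension.
#'
#' @param x a `mag_volume`, `complex_volume` or `dvf_field`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  arr <- switch(class(x)[1],
    mag_volume = x$data,
    complex_volume = {
      a <- array(0, c(x$dims, 2L))
      a[, , , 1] <- Re(x$data); a[, , , 2] <- Im(x$data); a
    },
    dvf_field = x$vectors,
    stop("unsupported object"))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(x$voxel_mm, length.out = length(dim(arr)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI file as a magnitude volume
#' @param path NIfTI file.
#' @return A `mag_volume`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  mag_volume(array(as.numeric(img), dim(img)[1:3]), vox)
}
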