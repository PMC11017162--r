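#' Serialize a PCA motion basis as NIfTI + JSON sidecar
#'
#' Writes the mean field and each component as 4D NIfTI (vector
#' components in the last dimension, mm, pull-back displacement
#' convention) next to a JSON sidecar holding the singular values,
#' explained-variance fractions, number of components and grid metadata.
#'
#' @param basis a [pca_basis()].
#' @param prefix output path prefix; files are
#'   `<prefix>_e0.nii.gz`, `<prefix>_comp<i>.nii.gz`, `<prefix>.json`.
#' @return the sidecar path, invisibly.
#' @export
write_pca_basis <- function(basis, prefix) {
  write_volume_nifti(basis$e0, paste0(prefix, "_e0.nii.gz"))
  for (i in seq_len(basis$n_pc))
    write_volume_nifti(basis$components[[i]],
                       paste0(prefix, "_comp", i, ".nii.gz"))
  side <- list(n_pc = basis$n_pc,
               singular_values = basis$singular_values,
               explained = basis$explained,
               per_direction = isTRUE(basis$per_direction),
               dims = basis$e0$dims, voxel_mm = basis$e0$voxel_mm)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' @rdname write_pca_basis
#' @export
read_pca_basis <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(p) {
    img <- RNifti::readNifti(p)
    dvf_field(array(as.numeric(img), dim(img)), side$voxel_mm)
  }
  comps <- lapply(seq_len(side$n_pc),
                  function(i) rd(paste0(prefix, "_comp", i, ".nii.gz")))
  structure(list(e0 = rd(paste0(prefix, "_e0.nii.gz")), components = comps,
                 singular_values = side$singular_values,
                 explained = side$explained, n_pc = side$n_pc,
                 per_direction = side$per_direction),
            class = "pca_basis")
}

#' Serialize inter-phase DVFs
#' @param phases an `inter_phase_dvfs`.
#' @param prefix path prefix (`<prefix>_phase<p>.nii.gz` + JSON sidecar).
#' @return sidecar path, invisibly.
#' @export
write_inter_phase <- function(phases, prefix) {
  for (p in seq_along(phases$dvfs))
    write_volume_nifti(phases$dvfs[[p]], paste0(prefix, "_phase", p, ".nii.gz"))
  jsonlite::write_json(list(n_bins = length(phases$dvfs),
                            exhale_bin = phases$exhale_bin,
                            voxel_mm = phases$dvfs[[1]]$voxel_mm),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' @rdname write_inter_phase
#' @export
read_inter_phase <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dvfs <- lapply(seq_len(side$n_bins), function(p) {
    img <- RNifti::readNifti(paste0(prefix, "_phase", p, ".nii.gz"))
    dvf_field(array(as.numeric(img), dim(img)), side$voxel_mm)
  })
  inter_phase_set(dvfs, side$exhale_bin)
}

#' Run metadata JSON
#'
#' Records the configuration, seed and package version of a
#' reconstruction run.
#'
#' @param cfg a [train_config()].
#' @param path output JSON path.
#' @param extra optional named list merged into the record.
#' @return `path` invisibly.
#' @export
write_run_metadata <- function(cfg, path, extra = list()) {
  rec <- c(list(package = "cineinr",
                version = as.character(utils::packageVersion("cineinr")),
                profile = cfg$profile, seed = cfg$seed,
                lr = cfg$lr, epochs = cfg$epochs,
                lambda_tv = cfg$lambda_tv, n_batch = cfg$n_batch,
                n_bins = cfg$n_bins, n_pc = cfg$n_pc),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
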