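#' Relative error between magnitude images
#'
#' `RE = sqrt( sum((|z| - |z_gt|)^2) / sum(|z_gt|^2) )`, computed on the
#' magnitudes; scale-invariant when both arguments are scaled by the
#' same positive constant.
#'
#' @param z,z_gt complex/real arrays or volume objects of one shape.
#' @return scalar RE.
#' @export
relative_error <- function(z, z_gt) {
  a <- if (is.list(z)) z$data else z
  b <- if (is.list(z_gt)) z_gt$data else z_gt
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  den <- sum(Mod(b)^2)
  if (den == 0) stop("ground-truth image is identically zero")
  sqrt(sum((Mod(a) - Mod(b))^2) / den)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |Y & Ygt| / (|Y| + |Ygt|)`; two empty masks are defined as
#' perfectly overlapping (DSC 1), one empty mask gives 0.
#'
#' @param y,y_gt logical arrays (or 0/1) on one grid.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(y, y_gt) {
  y <- as.logical(y); y_gt <- as.logical(y_gt)
  if (length(y) != length(y_gt)) stop("masks on different grids")
  sy <- sum(y); sg <- sum(y_gt)
  if (sy + sg == 0) return(1)
  2 * sum(y & y_gt) / (sy + sg)
}

#' Center-of-mass error between two masks
#'
#' Euclidean distance in mm between the unweighted voxel centroids.
#'
#' @param y,y_gt nonempty logical arrays on one grid.
#' @param voxel_mm voxel size in mm.
#' @return distance in mm.
#' @export
center_of_mass_error <- function(y, y_gt, voxel_mm) {
  voxel_mm <- normalize_voxel_mm(voxel_mm)
  com <- function(m) {
    if (!any(m)) stop("empty mask in center-of-mass computation")
    idx <- which(m, arr.ind = TRUE) - 1
    colMeans(idx) * voxel_mm
  }
  sqrt(sum((com(array(as.logical(y), dim(y))) -
              com(array(as.logical(y_gt), dim(y_gt))))^2))
}

#' Propagate a binary mask through a DVF
#'
#' Warps the mask as a real-valued volume with the same pull-back
#' trilinear scheme as [warp_volume()] and thresholds at 0.5, so mask
#' propagation is exactly consistent with the image warping operator.
#'
#' @param mask logical array.
#' @param dvf a [dvf_field()] on the mask's grid.
#' @return logical array; a warning is emitted if the result is empty.
#' @export
propagate_mask <- function(mask, dvf) {
  dims <- as.integer(dim(mask))
  stopifnot(identical(dims, as.integer(dvf$dims)))
  w <- warp_trilinear(as.complex(as.numeric(mask)), dims,
                      dvf_as_matrix_vox(dvf))
  out <- array(Re(w) >= 0.5, dims)
  if (!any(out)) warning("propagated mask is empty")
  out
}

#' Variance-based image sharpness
#'
#' Mean over voxels of the local intensity variance in a sliding cubic
#' window; higher values indicate a sharper image.
#'
#' @param vol magnitude array or [mag_volume()] (values in `[0, 1]`).
#' @param window odd cubic window edge length (default 3).
#' @return scalar sharpness.
#' @export
sharpness_variance <- function(vol, window = 3) {
  m <- if (is.list(vol)) vol$data else vol
  stopifnot(window %% 2 == 1, window >= 3)
  d <- dim(m)
  r <- (window - 1) / 2
  # local means via box filtering with replicated borders
  box1 <- function(a, axis) {
    idx <- lapply(seq_len(3), function(i) seq_len(d[i]))
    acc <- array(0, d)
    for (o in -r:r) {
      ii <- idx
      ii[[axis]] <- pmin(pmax(idx[[axis]] + o, 1), d[axis])
      acc <- acc + a[ii[[1]], ii[[2]], ii[[3]]]
    }
    acc / window
  }
  box <- function(a) box1(box1(box1(a, 1), 2), 3)
  mu <- box(m)
  mu2 <- box(m^2)
  mean(pmax(mu2 - mu^2, 0))
}

#' Delineate a bright target on a reconstructed reference
#'
#' Thresholds the reference magnitude at the mid-level between the
#' brightest and darkest intensity inside a spherical search region
#' around a guide mask — the contour-on-the-reconstruction step of
#' DVF-based target tracking: the propagated contour then lives in the
#' reconstruction's own reference frame, so tracking metrics are not
#' biased by the reconstruction's (data-unconstrained) choice of
#' reference position.
#'
#' @param z_ref the reconstructed reference ([complex_volume()] or
#'   magnitude array).
#' @param guide logical array marking the approximate target location.
#' @param dilate_vox search-region margin around the guide (voxels).
#' @return logical array of the segmented target.
#' @export
segment_reference_mask <- function(z_ref, guide, dilate_vox = 3) {
  m <- if (is.list(z_ref)) Mod(z_ref$data) else Mod(z_ref)
  dims <- dim(m)
  idx <- which(guide, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty guide mask")
  ctr <- colMeans(idx)
  rad <- sqrt(max(rowSums(sweep(idx, 2L, ctr)^2))) + dilate_vox
  all_idx <- index_grid(dims) + 1
  region <- array(rowSums(sweep(all_idx, 2L, ctr)^2) <= rad^2, dims)
  thr <- 0.5 * (max(m[region]) + min(m[region]))
  region & (m > thr)
}

#' Per-frame metrics of a reconstruction against the ground truth
#'
#' Computes the relative error, tumor Dice coefficient and tumor
#' center-of-mass error for each requested frame, plus mean and SD
#' summaries.
#'
#' @param result a `recon_result`.
#' @param cine the `ground_truth_cine` the data were simulated from.
#' @param mask reference-frame tumor mask (logical array); when `NULL`
#'   the tumor label of the cine reference is unavailable and only RE is
#'   computed.
#' @param frames frame indices to evaluate (default all).
#' @return An object of class `metric_series`: data frame `per_frame`
#'   with columns `frame, RE, DSC, COME_mm`, and `summary` (mean/SD per
#'   metric).
#' @export
evaluate_recon <- function(result, cine, mask = NULL, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(cine$n_t)
  re <- dsc <- come <- rep(NA_real_, length(frames))
  for (i in seq_along(frames)) {
    t <- frames[i]
    gt <- cine_frame(cine, t)
    rec <- recon_frame(result, t)
    re[i] <- relative_error(rec, gt)
    if (!is.null(mask)) {
      d_rec <- recon_dvf(result, t)
      d_gt <- cine_dvf(cine, t)
      y <- propagate_mask(mask, d_rec)
      ygt <- propagate_mask(mask, d_gt)
      if (any(y) && any(ygt)) {
        dsc[i] <- dice(y, ygt)
        come[i] <- center_of_mass_error(y, ygt, cine$voxel_mm)
      }
    }
  }
  pf <- data.frame(frame = frames, RE = re, DSC = dsc, COME_mm = come)
  sm <- data.frame(
    metric = c("RE", "DSC", "COME_mm"),
    mean = c(mean(re), mean(dsc, na.rm = TRUE), mean(come, na.rm = TRUE)),
    sd = c(sd(re), sd(dsc, na.rm = TRUE), sd(come, na.rm = TRUE)))
  structure(list(per_frame = pf, summary = sm), class = "metric_series")
}

#' Center-of-mass motion trajectory from a reconstruction
#'
#' Propagates a reference-frame mask through the recovered per-frame
#' DVFs and returns the centroid trajectory per Cartesian axis in mm
#' (LR, AP, SI with the package's axis convention).  Frames whose
#' propagated mask is empty are flagged with `NA`.
#'
#' @param result a `recon_result`.
#' @param mask logical array on the reference grid.
#' @param frames frame indices (default all).
#' @return data frame with columns `t_ms, LR_mm, AP_mm, SI_mm`.
#' @export
motion_trace_from_recon <- function(result, mask, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(result$n_t)
  voxel_mm <- normalize_voxel_mm(result$voxel_mm)
  out <- matrix(NA_real_, length(frames), 3L)
  for (i in seq_along(frames)) {
    y <- suppressWarnings(propagate_mask(mask, recon_dvf(result, frames[i])))
    if (any(y)) {
      idx <- which(y, arr.ind = TRUE) - 1
      out[i, ] <- colMeans(idx) * voxel_mm
    }
  }
  t_ms <- if (!is.null(result$timestamps_ms)) result$timestamps_ms[frames]
          else frames
  data.frame(t_ms = t_ms, LR_mm = out[, 1],
             AP_mm = out[, 2], SI_mm = out[, 3])
}

#' Write a metric series as CSV + JSON summary
#' @param metrics a `metric_series`.
#' @param csv_path per-frame CSV path.
#' @param json_path optional JSON summary path.
#' @return `csv_path` invisibly.
#' @export
write_metrics <- function(metrics, csv_path, json_path = NULL) {
  utils::write.csv(metrics$per_frame, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(summary = metrics$summary), json_path,
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
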