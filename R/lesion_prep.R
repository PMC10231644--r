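# Shared lesion preparation: downsampling to the analysis grid, the
# minimum-overlap coverage mask, lesion volumes, and gray-matter ROI
# restriction. Exclusions are recorded, never silent.

#' Downsample a lesion mask to a coarser isotropic grid
#'
#' Block-mean downsampling followed by thresholding at 0.5, with ties
#' (exactly half the block lesioned) counted as lesioned — a majority rule
#' that preserves small lesions. The target voxel size must be an integer
#' multiple of the source size.
#'
#' @param mask a [lesion_mask()]
#' @param target_voxel_mm target isotropic voxel size (mm)
#' @return a [lesion_mask()] on the coarser grid with an updated affine
#' @export
resample_mask <- function(mask, target_voxel_mm = 2) {
  src <- mask$voxel_size_mm
  if (max(abs(src - src[1])) > 1e-6)
    stop("resample_mask requires isotropic source voxels")
  ratio <- target_voxel_mm / src[1]
  if (abs(ratio - round(ratio)) > 1e-6 || ratio < 1)
    stop("target voxel size must be an integer multiple of the source (got ratio ",
         signif(ratio, 4), ")")
  f <- as.integer(round(ratio))
  if (f == 1L) return(mask)
  d <- dim(mask$grid)
  if (any(d %% f != 0))
    stop("grid dimensions ", paste(d, collapse = "x"),
         " not divisible by factor ", f)
  dn <- d %/% f
  blocks <- array(mask$grid, dim = c(f, dn[1], f, dn[2], f, dn[3]))
  means <- apply(blocks, c(2, 4, 6), mean)
  newgrid <- array(as.integer(means >= 0.5), dn)    # ties -> 1
  aff <- mask$affine
  scale <- diag(c(f, f, f, 1))
  # new voxel (0,0,0) center sits at the mean of the f^3 source centers
  shift <- aff[1:3, 1:3] %*% rep((f - 1) / 2, 3)
  newaff <- aff %*% scale
  newaff[1:3, 4] <- aff[1:3, 4] + shift
  lesion_mask(newgrid, newaff, mask$patient_id, allow_empty = TRUE)
}

#' Build the minimum-overlap coverage mask
#'
#' A voxel enters the analysis iff at least `min_overlap` patients have
#' damage there. Patients whose lesion has no voxel inside the coverage
#' mask are flagged excluded.
#'
#' @param masks list of [lesion_mask()] objects with identical geometry
#' @param min_overlap minimum number of overlapping lesions per voxel
#' @return list of class `coverage_mask`: `mask` (3-D binary),
#'   `overlap_count` (3-D counts), `min_overlap`, `n_input_masks`,
#'   `excluded_ids`, `affine`
#' @export
build_coverage_mask <- function(masks, min_overlap = 5L) {
  stopifnot(length(masks) >= min_overlap)
  for (m in masks[-1]) .same_geometry(masks[[1]], m, "lesion masks")
  counts <- Reduce(`+`, lapply(masks, function(m) m$grid))
  cov <- array(as.integer(counts >= min_overlap), dim(counts))
  excluded <- character(0)
  for (m in masks)
    if (sum(m$grid * cov) == 0) excluded <- c(excluded, m$patient_id)
  if (length(excluded))
    .sm_log(length(excluded), " patient(s) with no voxels in coverage mask")
  structure(list(mask = cov, overlap_count = counts,
                 min_overlap = as.integer(min_overlap),
                 n_input_masks = length(masks), excluded_ids = excluded,
                 affine = masks[[1]]$affine),
            class = "coverage_mask")
}

#' Lesion volume in ml
#'
#' @param mask a [lesion_mask()]
#' @return set-voxel count times voxel volume, in ml
#' @export
lesion_volume_ml <- function(mask) {
  sum(mask$grid) * prod(mask$voxel_size_mm) / 1000
}

#' Restrict a lesion to its gray-matter portion
#'
#' ROI = lesion intersected with `gm_prob >= threshold` (inclusive). An
#' empty result marks the patient as having a pure white-matter lesion.
#'
#' @param mask a [lesion_mask()]
#' @param gm_prob gray-matter probability map (`stat_map` or array, values
#'   in 0-1)
#' @param threshold minimum gray-matter probability
#' @return a [lesion_mask()]; attribute `excluded` is TRUE with reason
#'   "pure white matter lesion" if the ROI is empty
#' @export
gray_matter_roi <- function(mask, gm_prob, threshold = 0.10) {
  gm <- if (inherits(gm_prob, "stat_map")) gm_prob$grid else gm_prob
  if (!identical(dim(gm), dim(mask$grid)))
    stop("geometry mismatch between lesion and gm_prob")
  if (any(gm < 0) || any(gm > 1)) stop("gm_prob values must lie in [0,1]")
  roi <- array(as.integer(mask$grid == 1 & gm >= threshold), dim(gm))
  out <- lesion_mask(roi, mask$affine, mask$patient_id, allow_empty = TRUE)
  if (sum(roi) == 0) {
    attr(out, "excluded") <- TRUE
    attr(out, "exclusion_reason") <- "pure white matter lesion"
    .sm_log("patient ", mask$patient_id, " excluded: pure white matter lesion")
  } else {
    attr(out, "excluded") <- FALSE
  }
  out
}
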