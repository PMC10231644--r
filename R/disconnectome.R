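# Structural disconnection maps: for each patient, streamlines of each
# normative tractogram that pass through the lesion are selected and their
# full voxel visitation paths unioned; per-subject binary maps are
# aggregated into a 0-100% map and binarized at the >= 60% cutoff.

.world_to_vox <- function(pts, affine) {
  inv <- solve(affine)
  t(inv %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
}

#' Per-subject lesion disconnection map
#'
#' Selects the streamlines intersecting the lesion and returns the binary
#' union of all voxels those streamlines pass through. Intersection and
#' visitation use exact segment-grid traversal by default, so no voxel is
#' skipped between consecutive polyline points; `mode = "vertex"` restricts
#' both to vertex membership for comparison.
#'
#' @param lesion a [lesion_mask()]
#' @param tract a tractogram (world-mm streamlines)
#' @param mode `"traversal"` (default) or `"vertex"`
#' @return 3-D binary array on the lesion grid
#' @export
subject_disconnection <- function(lesion, tract, mode = c("traversal", "vertex")) {
  mode <- match.arg(mode)
  if (!length(tract$streamlines)) stop("empty tractogram")
  d <- dim(lesion$grid)
  npts <- vapply(tract$streamlines, nrow, 0L)
  pts_vox <- .world_to_vox(do.call(rbind, tract$streamlines), lesion$affine)
  offsets <- c(0L, cumsum(npts))
  vis <- disconnection_map_cpp(pts_vox, as.integer(offsets),
                               as.vector(lesion$grid) != 0, as.integer(d),
                               mode = if (mode == "traversal") 0L else 1L)
  array(as.integer(vis), d)
}

#' Aggregate per-subject disconnection maps into a percentage map
#'
#' @param per_subject_maps list of 3-D binary arrays, identical geometry
#' @param affine shared affine of the maps
#' @return list of class `disconnectome_map`: `percent` ([stat_map()],
#'   0-100), `n_subjects`
#' @export
aggregate_percent <- function(per_subject_maps, affine = diag(4)) {
  stopifnot(length(per_subject_maps) >= 2)
  d <- dim(per_subject_maps[[1]])
  for (m in per_subject_maps[-1])
    if (!identical(dim(m), d)) stop("geometry mismatch among subject maps")
  counts <- Reduce(`+`, per_subject_maps)
  pct <- 100 * counts / length(per_subject_maps)
  structure(list(percent = stat_map(pct, "percent", affine = affine),
                 n_subjects = length(per_subject_maps)),
            class = "disconnectome_map")
}

#' Binarize a disconnectome percentage map at a cutoff
#'
#' Inclusive rule: a voxel survives iff `percent >= cutoff`.
#'
#' @param dmap a `disconnectome_map`
#' @param cutoff_percent cutoff in (0, 100]
#' @return the map with a `binary` [stat_map()] and `cutoff` added
#' @export
binarize_cutoff <- function(dmap, cutoff_percent = 60) {
  stopifnot(cutoff_percent > 0, cutoff_percent <= 100)
  b <- array(as.integer(dmap$percent$grid >= cutoff_percent),
             dim(dmap$percent$grid))
  dmap$binary <- stat_map(b, "overlap_count", affine = dmap$percent$affine)
  dmap$cutoff <- cutoff_percent
  dmap
}

#' Build binarized disconnectome maps for a cohort
#'
#' @param masks list of [lesion_mask()]
#' @param tractograms list of normative tractograms
#' @param config an [analysis_config()] (`disconnection_cutoff_percent`)
#' @return list per patient of `lesion_mask`-like binary disconnection
#'   masks (patient id preserved); patients with an empty binary map keep
#'   an `excluded` attribute with the fiber-tracking failure reason
#' @export
disconnectome_maps <- function(masks, tractograms,
                               config = analysis_config()) {
  lapply(masks, function(m) {
    subj <- lapply(tractograms, function(tr) subject_disconnection(m, tr))
    dm <- binarize_cutoff(aggregate_percent(subj, m$affine),
                          config$disconnection_cutoff_percent)
    out <- lesion_mask(dm$binary$grid, m$affine, m$patient_id,
                       allow_empty = TRUE)
    attr(out, "percent_map") <- dm$percent
    if (sum(out$grid) == 0) {
      attr(out, "excluded") <- TRUE
      attr(out, "exclusion_reason") <-
        "empty disconnectome map (fiber tracking failed for a very small lesion)"
      .sm_log("patient ", m$patient_id, ": empty disconnectome map")
    }
    out
  })
}
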