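# Domain containers: lesion_mask, stat_map, cohort_table, analysis_config.
# Cross-map operations require identical shape + affine; nothing resamples
# implicitly.

#' Construct a lesion mask
#'
#' A binary 3-D voxel indicator of damage for one patient, in a common
#' space. Voxel indices are 0-based; `affine` maps voxel indices to world
#' mm coordinates.
#'
#' @param grid 3-D array; any nonzero value marks a damaged voxel
#' @param affine 4x4 voxel-to-world transform
#' @param patient_id identifier string
#' @param allow_empty permit a mask with no set voxels
#' @return an object of class `lesion_mask`
#' @export
lesion_mask <- function(grid, affine = diag(4), patient_id = "unknown",
                        allow_empty = FALSE) {
  if (length(dim(grid)) != 3) stop("lesion mask grid must be 3-D")
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  vals <- as.vector(grid)
  if (any(!(vals %in% c(0, 1)))) {
    .sm_log("binarizing mask for ", patient_id, ": values outside {0,1}",
            level = "WARN")
  }
  g <- array(as.integer(vals != 0), dim = dim(grid))
  if (!allow_empty && sum(g) == 0)
    .sm_log("mask for ", patient_id, " is empty", level = "WARN")
  structure(list(patient_id = as.character(patient_id), grid = g,
                 affine = affine,
                 voxel_size_mm = sqrt(colSums(affine[1:3, 1:3]^2))),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask %s: %s grid, %d voxels set, %.1f mm voxels>\n",
              x$patient_id, paste(dim(x$grid), collapse = "x"),
              sum(x$grid), x$voxel_size_mm[1]))
  invisible(x)
}

#' Construct a statistic map
#'
#' A voxelwise map (beta, z, t, p, percent or overlap count) with its
#' analysis mask. Values outside the mask are zero by convention.
#'
#' @param grid 3-D numeric array
#' @param kind one of `beta`, `z`, `t`, `p`, `percent`, `overlap_count`, `prob`
#' @param mask 3-D binary analysis mask (defaults to all ones)
#' @param affine 4x4 voxel-to-world transform
#' @return an object of class `stat_map`
#' @export
stat_map <- function(grid, kind = c("beta", "z", "t", "p", "percent",
                                    "overlap_count", "prob"),
                     mask = NULL, affine = diag(4)) {
  kind <- match.arg(kind)
  if (length(dim(grid)) != 3) stop("stat map grid must be 3-D")
  if (is.null(mask)) mask <- array(1L, dim = dim(grid))
  if (!identical(dim(mask), dim(grid))) stop("mask/grid shape mismatch")
  inside <- as.vector(grid)[as.vector(mask) != 0]
  if (kind == "p" && length(inside) && (any(inside <= 0) || any(inside > 1)))
    stop("p-map values must lie in (0, 1]")
  if (kind == "percent" && length(inside) && (any(inside < 0) || any(inside > 100)))
    stop("percent-map values must lie in [0, 100]")
  g <- array(as.numeric(grid), dim = dim(grid))
  g[mask == 0] <- 0
  structure(list(grid = g, mask = array(as.integer(mask != 0), dim(mask)),
                 kind = kind, affine = affine),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map kind=%s: %s grid, %d voxels in mask>\n",
              x$kind, paste(dim(x$grid), collapse = "x"), sum(x$mask)))
  invisible(x)
}

.same_geometry <- function(a, b, what = "inputs") {
  ga <- if (!is.null(a$grid)) a$grid else a
  gb <- if (!is.null(b$grid)) b$grid else b
  if (!identical(dim(ga), dim(gb)))
    stop("geometry mismatch between ", what, ": shapes ",
         paste(dim(ga), collapse = "x"), " vs ", paste(dim(gb), collapse = "x"))
  aa <- a$affine; ab <- b$affine
  if (!is.null(aa) && !is.null(ab) && max(abs(aa - ab)) > 1e-6)
    stop("geometry mismatch between ", what, ": affines differ")
  invisible(TRUE)
}

#' Analysis configuration
#'
#' Collects every tunable threshold of the four pipelines with the
#' published operating points as defaults: SVR voxel threshold p < 0.005
#' one-tailed, LNSM voxel threshold p < 0.001 two-tailed, cluster-level
#' FWE alpha 0.05, 5000 permutations, minimum lesion overlap 5 patients,
#' disconnection cutoff >= 60 percent, gray-matter probability >= 0.10,
#' framewise-displacement censoring at 0.5 mm, band-pass 0.01-0.08 Hz,
#' 5 mm FWHM smoothing, 9 mm diameter circuit sphere, HADS-D cutoffs
#' 10 and 7. SVR hyperparameters (C = 30, gamma = 5, epsilon = 0.1, RBF)
#' follow the lesion-symptom mapping toolbox defaults and are assumptions;
#' a linear kernel is available for validation work.
#'
#' @param ... overrides for any default field
#' @return an object of class `analysis_config`
#' @export
analysis_config <- function(...) {
  cfg <- list(
    svr_voxel_p = 0.005, lnsm_voxel_p = 0.001, cluster_fwe_alpha = 0.05,
    n_permutations = 5000L, min_lesion_overlap = 5L,
    disconnection_cutoff_percent = 60, gm_probability_threshold = 0.10,
    fd_threshold_mm = 0.5, bandpass_hz = c(0.01, 0.08),
    smoothing_fwhm_mm = 5, sphere_diameter_mm = 9,
    hads_cutoffs = c(10L, 7L),
    svr_cost = 30, svr_gamma = 5, svr_epsilon = 0.1, svr_kernel = "rbf",
    cluster_connectivity = 26L, rng_seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$svr_voxel_p > 0, cfg$svr_voxel_p < 1,
            cfg$lnsm_voxel_p > 0, cfg$lnsm_voxel_p < 1,
            cfg$cluster_fwe_alpha > 0, cfg$cluster_fwe_alpha < 1,
            cfg$n_permutations >= 1, cfg$min_lesion_overlap >= 1,
            cfg$disconnection_cutoff_percent > 0,
            cfg$disconnection_cutoff_percent <= 100,
            cfg$gm_probability_threshold >= 0, cfg$gm_probability_threshold <= 1,
            cfg$fd_threshold_mm > 0, length(cfg$bandpass_hz) == 2,
            cfg$bandpass_hz[1] < cfg$bandpass_hz[2],
            cfg$sphere_diameter_mm > 0,
            cfg$svr_kernel %in% c("rbf", "linear"),
            cfg$cluster_connectivity %in% c(6L, 18L, 26L))
  structure(cfg, class = "analysis_config")
}

#' Read a run configuration file
#'
#' Accepts JSON, or a flat `key: value` YAML subset (scalars and
#' comma-separated vectors only).
#'
#' @param path configuration file
#' @return an `analysis_config`
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*?)\\s*$", lines))
    vals <- list()
    for (m in kv) {
      if (length(m) != 3) next
      v <- strsplit(m[3], ",\\s*")[[1]]
      num <- suppressWarnings(as.numeric(v))
      vals[[m[2]]] <- if (all(!is.na(num))) num else v
    }
  }
  do.call(analysis_config, vals)
}

# ---- io_model file operations ----------------------------------------------

#' Read a lesion mask volume
#'
#' Reads a 3-D NIfTI file and binarizes it (any nonzero voxel becomes 1,
#' with a logged warning if the input was not already 0/1).
#'
#' @param path NIfTI file
#' @param patient_id identifier; defaults to the file stem
#' @return a [lesion_mask()]
#' @export
read_mask_volume <- function(path, patient_id = NULL) {
  nii <- read_nifti(path)
  if (length(dim(nii$img)) != 3) stop("non-3-D image: ", path)
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  suppressMessages(lesion_mask(nii$img, nii$affine, patient_id,
                               allow_empty = TRUE)) -> m
  vals <- unique(as.vector(nii$img))
  if (any(!(vals %in% c(0, 1))))
    .sm_log("values outside {0,1} binarized in ", path, level = "WARN")
  m
}

#' Write a statistic map volume
#'
#' Float32 on disk; the map `kind` and the producing configuration seed are
#' stored in the header description so outputs are self-identifying.
#'
#' @param map a [stat_map()]
#' @param path output `.nii`/`.nii.gz`
#' @param config optional `analysis_config` whose seed is embedded
#' @export
write_stat_volume <- function(map, path, config = NULL) {
  stopifnot(inherits(map, "stat_map"))
  desc <- paste0("kind=", map$kind,
                 if (!is.null(config)) paste0(";seed=", config$rng_seed) else "")
  write_nifti(map$grid, map$affine, path, datatype = "float32", descrip = desc)
  invisible(path)
}

#' Read a statistic map volume
#'
#' @param path NIfTI file written by [write_stat_volume()]
#' @param kind override for the map kind if the header lacks one
#' @return a [stat_map()]
#' @export
read_stat_volume <- function(path, kind = NULL) {
  nii <- read_nifti(path)
  if (is.null(kind)) {
    m <- regmatches(nii$descrip, regexec("kind=([a-z_]+)", nii$descrip))[[1]]
    kind <- if (length(m) == 2) m[2] else "z"
  }
  stat_map(nii$img, kind = kind, affine = nii$affine)
}

#' Write a lesion mask volume (uint8)
#'
#' @param mask a [lesion_mask()]
#' @param path output `.nii`/`.nii.gz`
#' @export
write_mask_volume <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  write_nifti(mask$grid, mask$affine, path, datatype = "uint8",
              descrip = paste0("lesion:", mask$patient_id))
  invisible(path)
}
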