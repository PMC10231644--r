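# Lesion network-symptom mapping: normative run preprocessing (smooth ->
# nuisance regression -> band-pass -> motion censoring), lesion-seeded
# Fisher-z connectivity maps averaged over all subjects/runs, and a
# mass-univariate GLM with permutation cluster-level FWE inference.

#' Preprocess one normative resting-state run
#'
#' Order: (1) spatial Gaussian smoothing; (2) multiple regression removing
#' intercept, the 6 motion parameters, mean white-matter signal, mean CSF
#' signal and the global mean; (3) zero-phase Butterworth band-pass;
#' (4) censoring of frames with framewise displacement above threshold.
#'
#' @param run a `normative_run` (from [generate_normative_timeseries()] or
#'   [read_normative_run()])
#' @param config an [analysis_config()] (`smoothing_fwhm_mm`,
#'   `bandpass_hz`, `fd_threshold_mm`)
#' @return list of class `cleaned_run`: `data` (x,y,z,kept-time array),
#'   `kept_frames`, `fd`, `steps` (order log)
#' @export
preprocess_run <- function(run, config = analysis_config()) {
  d <- dim(run$data)
  stopifnot(length(d) == 4, d[4] > 20, nrow(run$motion) == d[4])
  vox_mm <- sqrt(colSums(run$affine[1:3, 1:3]^2))
  sm <- gaussian_smooth(run$data, config$smoothing_fwhm_mm, vox_mm)
  V <- t(matrix(sm, nrow = prod(d[1:3])))              # time x voxels
  wm_idx <- which(as.vector(run$wm_prob) > 0.5)
  csf_idx <- which(as.vector(run$csf_prob) > 0.5)
  glob_idx <- which(as.vector(run$gm_prob + run$wm_prob + run$csf_prob) > 0.1)
  nuis <- cbind(run$motion,
                wm = if (length(wm_idx)) rowMeans(V[, wm_idx, drop = FALSE]) else 0,
                csf = if (length(csf_idx)) rowMeans(V[, csf_idx, drop = FALSE]) else 0,
                global = rowMeans(V[, glob_idx, drop = FALSE]))
  # drop (numerically) constant regressors: zero motion or uniform tissue
  # means would make the design rank-deficient with the intercept
  keep_cols <- apply(nuis, 2, stats::sd) >
    1e-10 * (abs(colMeans(as.matrix(nuis))) + 1)
  V <- residualize(V, nuis[, keep_cols, drop = FALSE])
  bp <- butter_bandpass(config$bandpass_hz[1], config$bandpass_hz[2],
                        1 / run$tr_s, order = 2)
  V <- filtfilt_sm(bp$b, bp$a, V)
  fd <- framewise_displacement(run$motion)
  kept <- which(fd <= config$fd_threshold_mm)
  if (length(kept) < 10)
    stop("run unusable: fewer than 10 frames survive motion censoring")
  if (length(kept) < d[4])
    .sm_log("censored ", d[4] - length(kept), " high-motion frame(s) in ",
            run$subject_id, " ", run$run_id)
  V <- V[kept, , drop = FALSE]
  structure(list(data = array(t(V), dim = c(d[1:3], length(kept))),
                 kept_frames = kept, fd = fd,
                 subject_id = run$subject_id, run_id = run$run_id,
                 affine = run$affine,
                 steps = c("smooth", "nuisance_regression", "bandpass",
                           "censor")),
            class = "cleaned_run")
}

#' First eigenvariate of an ROI's time series
#'
#' The first left singular vector of the (time x ROI-voxel) matrix,
#' scaled to unit variance, with its sign chosen so that its correlation
#' with the ROI-mean series is non-negative.
#'
#' @param cleaned 4-D array (or `cleaned_run`)
#' @param roi a [lesion_mask()] (non-empty within the data grid)
#' @return numeric time series of length equal to the time axis
#' @export
roi_eigenvariate <- function(cleaned, roi) {
  dat <- if (inherits(cleaned, "cleaned_run")) cleaned$data else cleaned
  d <- dim(dat)
  idx <- which(as.vector(roi$grid) == 1)
  if (!length(idx)) stop("empty ROI")
  M <- t(matrix(dat, nrow = prod(d[1:3])))[, idx, drop = FALSE]
  sv <- svd(M, nu = 1, nv = 0)
  u <- sv$u[, 1]
  if (stats::sd(u) > 0) u <- u / stats::sd(u)
  mref <- rowMeans(M)
  if (stats::sd(mref) > 0 && stats::cor(u, mref) < 0) u <- -u
  u
}

#' Seed-to-voxel Fisher-z connectivity map
#'
#' Pearson correlation of every voxel's series with the seed series,
#' clipped to +/-(1 - 1e-7) and Fisher transformed (`atanh`). Voxels with
#' zero variance get z = 0 and are logged.
#'
#' @param cleaned 4-D array (or `cleaned_run`)
#' @param seed numeric seed time series (length = time axis)
#' @param affine affine for the output map
#' @return a [stat_map()] of kind `z`
#' @export
seed_connectivity_map <- function(cleaned, seed, affine = diag(4)) {
  dat <- if (inherits(cleaned, "cleaned_run")) cleaned$data else cleaned
  if (inherits(cleaned, "cleaned_run")) affine <- cleaned$affine
  d <- dim(dat)
  if (length(seed) != d[4]) stop("seed length must equal kept-frame count")
  if (stats::sd(seed) == 0) stop("constant seed series")
  V <- t(matrix(dat, nrow = prod(d[1:3])))
  sds <- apply(V, 2, stats::sd)
  ok <- sds > 0
  r <- numeric(ncol(V))
  sc <- (seed - mean(seed)) / stats::sd(seed)
  r[ok] <- as.numeric(crossprod(scale(V[, ok, drop = FALSE]), sc)) / (d[4] - 1)
  if (any(!ok)) .sm_log(sum(!ok), " zero-variance voxel(s) set to z = 0")
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[!ok] <- 0
  stat_map(array(z, d[1:3]), "z", affine = affine)
}

#' Lesion network map for one patient
#'
#' Averages the lesion-seeded Fisher-z maps over every normative subject
#' and run. The ROI must already be restricted to gray matter upstream.
#'
#' @param patient a [lesion_mask()] (gray-matter portion of the lesion)
#' @param runs list of `cleaned_run` objects (or `normative_run`s, which
#'   are preprocessed on the fly)
#' @param config an [analysis_config()]
#' @return list of class `lesion_network_map`: `zmap` ([stat_map()]),
#'   `n_maps_averaged`, `patient_id`
#' @export
lesion_network_map <- function(patient, runs, config = analysis_config()) {
  if (sum(patient$grid) == 0) stop("patient ROI is empty")
  zsum <- NULL
  nmaps <- 0L
  for (run in runs) {
    cl <- if (inherits(run, "cleaned_run")) run else preprocess_run(run, config)
    seed <- roi_eigenvariate(cl, patient)
    zm <- seed_connectivity_map(cl, seed)
    zsum <- if (is.null(zsum)) zm$grid else zsum + zm$grid
    nmaps <- nmaps + 1L
  }
  structure(list(zmap = stat_map(zsum / nmaps, "z", affine = runs[[1]]$affine),
                 n_maps_averaged = nmaps, patient_id = patient$patient_id),
            class = "lesion_network_map")
}

#' Lesion network maps for many patients at once
#'
#' Batched equivalent of [lesion_network_map()]: each run's time x voxel
#' matrix is formed once, every patient's ROI eigenvariate is extracted
#' from it, and all seed maps are computed in one correlation product.
#' Results match the per-patient path to numerical precision.
#'
#' @param rois list of (gray-matter restricted) [lesion_mask()] ROIs
#' @param cleaned_runs list of `cleaned_run` objects
#' @param vox_idx optional 1-based linear voxel indices restricting the
#'   output maps (e.g. the GLM analysis mask); default all voxels
#' @return patients x voxels matrix of averaged Fisher-z values
#' @export
lesion_network_maps_matrix <- function(rois, cleaned_runs, vox_idx = NULL) {
  pc <- if (inherits(cleaned_runs, "prepared_connectome")) cleaned_runs
        else prepare_connectome(cleaned_runs, vox_idx)
  np <- length(rois)
  roi_idx <- lapply(rois, function(r) which(as.vector(r$grid) == 1))
  if (any(!vapply(roi_idx, length, 0L))) stop("empty ROI")
  acc <- matrix(0, np, length(pc$vox_idx))
  for (run in pc$runs) {
    S <- vapply(roi_idx, function(idx) {
      M <- run$V[, idx, drop = FALSE]
      sv <- svd(M, nu = 1, nv = 0)
      u <- sv$u[, 1]
      if (stats::sd(u) > 0) u <- u / stats::sd(u)
      mref <- rowMeans(M)
      if (stats::sd(mref) > 0 && stats::cor(u, mref) < 0) u <- -u
      u
    }, numeric(nrow(run$V)))
    R <- matrix(0, length(pc$vox_idx), np)
    R[run$ok, ] <- crossprod(run$Vs, scale(S)) / (nrow(run$V) - 1)
    R <- pmin(pmax(R, -(1 - 1e-7)), 1 - 1e-7)
    Z <- atanh(R)
    Z[!run$ok, ] <- 0
    acc <- acc + t(Z)
  }
  acc / length(pc$runs)
}

#' Precompute standardized voxel matrices of cleaned normative runs
#'
#' Caches, per run, the time x voxel matrix and its column-standardized
#' restriction to `vox_idx`, so that network maps for many cohorts reuse
#' the same preparations.
#'
#' @param cleaned_runs list of `cleaned_run` objects
#' @param vox_idx optional 1-based linear voxel indices for output maps
#' @return an object of class `prepared_connectome`
#' @export
prepare_connectome <- function(cleaned_runs, vox_idx = NULL) {
  d <- dim(cleaned_runs[[1]]$data)[1:3]
  if (is.null(vox_idx)) vox_idx <- seq_len(prod(d))
  runs <- lapply(cleaned_runs, function(run) {
    V <- t(matrix(run$data, nrow = prod(dim(run$data)[1:3])))
    Vx <- V[, vox_idx, drop = FALSE]
    sds <- sqrt(colSums(scale(Vx, scale = FALSE)^2) / (nrow(Vx) - 1))
    ok <- sds > 0
    list(V = V, Vs = scale(Vx[, ok, drop = FALSE]), ok = ok)
  })
  structure(list(runs = runs, vox_idx = vox_idx, dims = d,
                 affine = cleaned_runs[[1]]$affine),
            class = "prepared_connectome")
}

#' Mass-univariate GLM over lesion network maps with permutation
#' cluster-level FWE
#'
#' Per voxel, OLS of behavior on map value plus intercept yields a t-map.
#' Voxels are thresholded two-tailed at `lnsm_voxel_p`; cluster sizes are
#' ranked against the permutation (behavior-shuffling) null of the maximum
#' suprathreshold cluster size. The analysis is restricted to voxels with
#' gray-matter probability at or above threshold, an optional region mask,
#' and nonzero variance across patients (zero-variance voxels are logged
#' and dropped).
#'
#' @param maps list of `lesion_network_map` (or an n x voxels matrix)
#' @param behavior per-patient score vector
#' @param config an [analysis_config()]
#' @param gm_prob gray-matter probability map (array or `stat_map`);
#'   `NULL` disables the gray-matter restriction
#' @param region_mask optional binary array restricting the analysis
#' @param dims,affine grid geometry when `maps` is a matrix
#' @return list of class `lnsm_result`: `t_map`, `clusters` (with
#'   `p_fwe`), `n_permutations`, `perm_max_sizes`, `analysis_mask`
#' @export
lnsm_glm_inference <- function(maps, behavior, config = analysis_config(),
                               gm_prob = NULL, region_mask = NULL,
                               dims = NULL, affine = diag(4)) {
  if (is.list(maps)) {
    dims <- dim(maps[[1]]$zmap$grid)
    affine <- maps[[1]]$zmap$affine
    M <- do.call(rbind, lapply(maps, function(m) as.vector(m$zmap$grid)))
  } else {
    M <- maps
    if (is.null(dims)) stop("dims required for matrix input")
  }
  n <- nrow(M)
  stopifnot(n >= 10, length(behavior) == n)
  amask <- rep(TRUE, prod(dims))
  if (!is.null(gm_prob)) {
    gm <- if (inherits(gm_prob, "stat_map")) gm_prob$grid else gm_prob
    amask <- amask & (as.vector(gm) >= config$gm_probability_threshold)
  }
  if (!is.null(region_mask)) amask <- amask & (as.vector(region_mask) != 0)
  sds <- apply(M, 2, stats::sd)
  nz_drop <- amask & (sds == 0)
  if (any(nz_drop)) .sm_log(sum(nz_drop), " zero-variance voxel(s) dropped")
  amask <- amask & (sds > 0)
  vox_idx <- which(amask)
  if (!length(vox_idx)) stop("empty analysis mask")
  Ms <- scale(M[, vox_idx, drop = FALSE])
  P <- as.integer(config$n_permutations)
  df <- n - 2
  tcrit <- stats::qt(1 - config$lnsm_voxel_p / 2, df)
  .with_seed(config$rng_seed, {
    y <- as.numeric(scale(behavior))
    Y <- cbind(y, vapply(seq_len(P), function(i) y[sample.int(n)], numeric(n)))
    R <- crossprod(Ms, Y) / (n - 1)                    # voxels x (P+1)
    R <- pmin(pmax(R, -(1 - 1e-12)), 1 - 1e-12)
    Tm <- R * sqrt(df) / sqrt(1 - R^2)
    thr <- abs(Tm) > tcrit
    maxsz <- perm_max_cluster(thr, as.integer(vox_idx - 1L),
                              as.integer(dims),
                              as.integer(config$cluster_connectivity))
    voxml <- abs(det(affine[1:3, 1:3])) / 1000
    obs_grid <- array(FALSE, dims)
    obs_grid[vox_idx[thr[, 1]]] <- TRUE
    clusters <- label_clusters(obs_grid, config$cluster_connectivity, voxml)
    null_max <- maxsz[-1]
    tvals <- Tm[, 1]
    for (ci in seq_along(clusters)) {
      sz <- clusters[[ci]]$size_vox
      clusters[[ci]]$p_fwe <- (1 + sum(null_max >= sz)) / (P + 1)
      clusters[[ci]]$significant <- clusters[[ci]]$p_fwe < config$cluster_fwe_alpha
      pk <- clusters[[ci]]$voxels[
        which.max(abs(tvals[match(clusters[[ci]]$voxels, vox_idx)]))]
      clusters[[ci]]$peak_voxel <- c(arrayInd(pk, dims)) - 1L
    }
    tg <- array(0, dims); tg[vox_idx] <- tvals
    mg <- array(0L, dims); mg[vox_idx] <- 1L
    structure(list(t_map = stat_map(tg, "t", mg, affine),
                   clusters = clusters, n_permutations = P,
                   perm_max_sizes = null_max, analysis_mask = mg,
                   seed = config$rng_seed),
              class = "lnsm_result")
  })
}

#' Full LNSM analysis from lesions, cohort and normative runs
#'
#' Restricts each lesion to gray matter (excluding pure white-matter
#' lesions), preprocesses every normative run once, computes each
#' patient's lesion network map, and runs the mass-univariate GLM.
#'
#' @param masks list of [lesion_mask()]
#' @param cohort a [cohort_table()]
#' @param runs list of `normative_run` objects
#' @param config an [analysis_config()]
#' @param gm_prob gray-matter probability map shared by lesions and GLM
#' @param region_mask optional restriction mask for the GLM
#' @return an `lnsm_result` plus `network_maps`, `exclusions`, `n_analyzed`
#' @export
lnsm <- function(masks, cohort, runs, config = analysis_config(),
                 gm_prob, region_mask = NULL) {
  ids <- vapply(masks, function(m) m$patient_id, "")
  cohort <- cohort[match(ids, cohort$patient_id), , drop = FALSE]
  keep <- !cohort$excluded
  masks <- masks[keep]
  rois <- lapply(masks, gray_matter_roi, gm_prob = gm_prob,
                 threshold = config$gm_probability_threshold)
  wm_only <- vapply(rois, function(r) isTRUE(attr(r, "excluded")), TRUE)
  for (id in vapply(masks[wm_only], function(m) m$patient_id, "")) {
    cohort$excluded[cohort$patient_id == id] <- TRUE
    cohort$exclusion_reason[cohort$patient_id == id] <- "pure white matter lesion"
  }
  rois <- rois[!wm_only]
  cohort_in <- cohort[match(vapply(rois, function(r) r$patient_id, ""),
                            cohort$patient_id), , drop = FALSE]
  cleaned <- lapply(runs, function(r)
    if (inherits(r, "cleaned_run")) r else preprocess_run(r, config))
  M <- lesion_network_maps_matrix(rois, cleaned)
  res <- lnsm_glm_inference(M, cohort_in$hads_d, config,
                            gm_prob = gm_prob, region_mask = region_mask,
                            dims = dim(cleaned[[1]]$data)[1:3],
                            affine = cleaned[[1]]$affine)
  res$network_maps <- M
  res$network_map_ids <- vapply(rois, function(r) r$patient_id, "")
  res$exclusions <- cohort[cohort$excluded,
                           c("patient_id", "exclusion_reason"), drop = FALSE]
  res$n_input <- length(ids)
  res$n_analyzed <- length(rois)
  res
}

#' @export
print.lnsm_result <- function(x, ...) {
  nsig <- sum(vapply(x$clusters, function(cl) isTRUE(cl$significant), TRUE))
  cat(sprintf("<lnsm_result: %d permutations, %d cluster(s), %d FWE-significant>\n",
              x$n_permutations, length(x$clusters), nsig))
  invisible(x)
}
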