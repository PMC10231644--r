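# Multivariate SVR symptom mapping over binary voxel-feature maps.
# Lesion masks -> SVR-LSM; binarized disconnectome maps -> SVR-SDSM.
# Inference: permutation null of the back-projected beta-map at the voxel
# level (one-tailed, damage -> higher score) and of the maximum
# suprathreshold cluster size at the cluster level (FWE).

#' Ordinary-least-squares residualization
#'
#' Regresses nuisance columns (plus an intercept) out of a vector or out
#' of every column of a matrix.
#'
#' @param values numeric vector, or matrix whose columns are residualized
#' @param nuisance vector/matrix of nuisance covariates (no intercept)
#' @return residuals with the input's shape, orthogonal to the nuisance
#'   columns and the intercept
#' @export
residualize <- function(values, nuisance) {
  X <- cbind(intercept = 1, as.matrix(nuisance))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient nuisance design")
  was_vec <- is.null(dim(values))
  res <- qr.resid(qrX, as.matrix(values))
  if (was_vec) as.numeric(res) else res
}

#' Build the patient x voxel feature matrix
#'
#' Rows are (included) patients, columns the voxels inside the coverage
#' mask, values the binary damage/disconnection indicator.
#'
#' @param masks list of [lesion_mask()] (or `stat_map` with binary grids)
#' @param coverage a `coverage_mask` from [build_coverage_mask()]
#' @return list: `X` (n x v binary matrix), `vox_idx` (1-based linear grid
#'   indices per column), `patient_ids`, `dims`, `affine`
#' @export
feature_matrix <- function(masks, coverage) {
  vox_idx <- which(as.vector(coverage$mask) == 1)
  X <- do.call(rbind, lapply(masks, function(m) {
    g <- if (inherits(m, "lesion_mask")) m$grid else m$grid
    as.numeric(g)[vox_idx]
  }))
  rownames(X) <- vapply(masks, function(m) m$patient_id, "")
  list(X = X, vox_idx = vox_idx, patient_ids = rownames(X),
       dims = dim(coverage$mask), affine = coverage$affine)
}

.svr_kernel <- function(X, kernel, gamma) {
  if (kernel == "linear") return(X %*% t(X))
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * X %*% t(X)
  exp(-gamma * pmax(D2, 0))
}

#' Fit an epsilon-SVR and back-project its beta-map
#'
#' The behavior vector is z-scored, the dual problem is solved on the
#' precomputed kernel, and voxel weights are recovered as
#' `beta_v = sum_i alpha_i x_iv` (dual-coefficient back-projection; exact
#' for the linear kernel, the established approximation for RBF). The
#' reported z-map follows the toolbox sign convention: z < 0 marks
#' damage associated with *higher* symptom scores.
#'
#' @param features output of [feature_matrix()] (possibly residualized `X`)
#' @param behavior numeric score vector (residualized upstream)
#' @param config an [analysis_config()]
#' @return list: `beta` (raw voxel weights, positive = damage raises the
#'   score), `z` (sign-flipped z-scored betas), `alpha`, `fitted`, plus
#'   `beta_map`/`z_map` as [stat_map()]s
#' @export
fit_svr_betamap <- function(features, behavior, config = analysis_config()) {
  X <- features$X
  n <- nrow(X)
  stopifnot(n >= 10, ncol(X) >= 1)
  if (stats::sd(behavior) == 0) stop("degenerate behavior: zero variance")
  y <- as.numeric(scale(behavior))
  K <- .svr_kernel(X, config$svr_kernel, config$svr_gamma)
  A <- esvr_fit_multi(K, matrix(y, ncol = 1), config$svr_cost,
                      config$svr_epsilon)
  alpha <- A[, 1]
  beta <- as.numeric(crossprod(X, alpha))
  zb <- if (stats::sd(beta) > 0) (beta - mean(beta)) / stats::sd(beta) else beta * 0
  mask <- array(0L, features$dims)
  mask[features$vox_idx] <- 1L
  bgrid <- array(0, features$dims); bgrid[features$vox_idx] <- beta
  zgrid <- array(0, features$dims); zgrid[features$vox_idx] <- -zb
  list(beta = beta, z = -zb, alpha = alpha,
       fitted = as.numeric(K %*% alpha),
       beta_map = stat_map(bgrid, "beta", mask, features$affine),
       z_map = stat_map(zgrid, "z", mask, features$affine))
}

#' Connected components of a thresholded binary map
#'
#' @param thresholded 3-D binary array
#' @param connectivity 6, 18 or 26 (face / face+edge / face+edge+corner)
#' @param voxel_volume_ml volume of one voxel in ml, for cluster sizes
#' @return list of clusters: `voxels` (1-based linear indices),
#'   `size_vox`, `size_ml`; ordered by decreasing size
#' @export
label_clusters <- function(thresholded, connectivity = 26L,
                           voxel_volume_ml = NULL) {
  d <- dim(thresholded)
  lab <- label_components_3d(as.integer(as.vector(thresholded) != 0),
                             as.integer(d), as.integer(connectivity))
  sizes <- lab$sizes
  if (!length(sizes)) return(list())
  ord <- order(sizes, decreasing = TRUE)
  out <- lapply(ord, function(ci) {
    vox <- which(lab$labels == ci)
    list(voxels = vox, size_vox = sizes[ci],
         size_ml = if (is.null(voxel_volume_ml)) NA_real_
                   else sizes[ci] * voxel_volume_ml)
  })
  out
}

#' SVR mapping with permutation voxel- and cluster-level inference
#'
#' The observed beta-map and P behavior-permutation beta-maps share one
#' kernel (features are unchanged by permuting behavior). One-tailed voxel
#' p-values (tail: damage raises the score) come from the per-voxel
#' permutation null including the observed map, so the minimum attainable
#' p is 1/(P+1). Clusters of `voxel p < svr_voxel_p` are tested against
#' the permutation null of the maximum cluster size at the same
#' threshold: `p_fwe = (1 + #{perm max >= observed}) / (P + 1)`.
#'
#' @param features output of [feature_matrix()] with residualized `X`
#' @param behavior residualized score vector
#' @param config an [analysis_config()]; `n_permutations`, `svr_voxel_p`,
#'   `cluster_fwe_alpha`, kernel and seed are consumed
#' @param nuisance optional nuisance columns the behavior was residualized
#'   against; when given, every permuted behavior vector is re-residualized
#'   against them (Freedman-Lane) — permuting residuals alone is
#'   anticonservative at these sample sizes
#' @return list of class `svr_result`: `beta_map`, `z_map`, `voxel_p_map`
#'   ([stat_map()]s), `clusters` (with `p_fwe` and `significant`),
#'   `prediction_r`, `prediction_p`, `n_permutations`, `hyperparameters`,
#'   `perm_max_sizes`
#' @export
permutation_cluster_inference <- function(features, behavior,
                                          config = analysis_config(),
                                          nuisance = NULL) {
  P <- as.integer(config$n_permutations)
  if (P < 100) .sm_log("only ", P, " permutations; p-values are coarse",
                       level = "WARN")
  X <- features$X
  n <- nrow(X)
  stopifnot(n >= 10, ncol(X) >= 1)
  if (stats::sd(behavior) == 0) stop("degenerate behavior: zero variance")
  y <- as.numeric(scale(behavior))
  .with_seed(config$rng_seed, {
    K <- .svr_kernel(X, config$svr_kernel, config$svr_gamma)
    Y <- cbind(y, vapply(seq_len(P), function(i) y[sample.int(n)],
                         numeric(n)))
    if (!is.null(nuisance))
      Y[, -1] <- residualize(Y[, -1, drop = FALSE], nuisance)
    A <- esvr_fit_multi(K, Y, config$svr_cost, config$svr_epsilon)
    # the raw dual-coefficient scale tracks fit difficulty (hard-to-fit
    # permuted responses inflate |alpha|), so each fit's alpha vector is
    # unit-normalized before back-projection; the permutation ranking is
    # then scale-free per voxel
    anorm <- sqrt(colSums(A^2))
    anorm[anorm == 0] <- 1
    B <- crossprod(X, sweep(A, 2, anorm, "/"))   # voxels x (P+1) beta maps
    Pm <- tail_p_rows(B)                         # one-tailed: large beta
    thr <- Pm < config$svr_voxel_p
    maxsz <- perm_max_cluster(thr, as.integer(features$vox_idx - 1L),
                              as.integer(features$dims),
                              as.integer(config$cluster_connectivity))
    voxml <- abs(det(features$affine[1:3, 1:3])) / 1000
    obs_grid <- array(FALSE, features$dims)
    obs_grid[features$vox_idx[thr[, 1]]] <- TRUE
    clusters <- label_clusters(obs_grid, config$cluster_connectivity, voxml)
    null_max <- maxsz[-1]
    beta <- B[, 1]
    for (ci in seq_along(clusters)) {
      sz <- clusters[[ci]]$size_vox
      clusters[[ci]]$p_fwe <- (1 + sum(null_max >= sz)) / (P + 1)
      clusters[[ci]]$significant <- clusters[[ci]]$p_fwe < config$cluster_fwe_alpha
      pk <- clusters[[ci]]$voxels[
        which.max(beta[match(clusters[[ci]]$voxels, features$vox_idx)])]
      clusters[[ci]]$peak_voxel <- c(arrayInd(pk, features$dims)) - 1L
    }
    fitted <- K %*% A
    rvec <- vapply(seq_len(P + 1L),
                   function(k) if (stats::sd(fitted[, k]) == 0) NA_real_
                               else stats::cor(fitted[, k], Y[, k]),
                   numeric(1))
    if (is.na(rvec[1])) stop("zero-variance predictions: r undefined")
    pred_p <- (1 + sum(rvec[-1] >= rvec[1], na.rm = TRUE)) / (P + 1)
    zb <- if (stats::sd(beta) > 0) (beta - mean(beta)) / stats::sd(beta) else beta * 0
    mask <- array(0L, features$dims); mask[features$vox_idx] <- 1L
    mk_map <- function(v, kind) {
      g <- array(if (kind == "p") 1 else 0, features$dims)
      g[features$vox_idx] <- v
      if (kind == "p") g[mask == 0] <- 1
      stat_map(g, kind, mask, features$affine)
    }
    structure(list(
      beta_map = mk_map(beta, "beta"), z_map = mk_map(-zb, "z"),
      voxel_p_map = mk_map(Pm[, 1], "p"), clusters = clusters,
      prediction_r = rvec[1], prediction_p = pred_p,
      n_permutations = P, perm_max_sizes = null_max,
      hyperparameters = list(C = config$svr_cost, gamma = config$svr_gamma,
                             epsilon = config$svr_epsilon,
                             kernel = config$svr_kernel),
      vox_idx = features$vox_idx, dims = features$dims,
      affine = features$affine, seed = config$rng_seed),
      class = "svr_result")
  })
}

#' In-sample prediction performance of the SVR model
#'
#' Pearson correlation between fitted and observed scores, ranked against
#' models refit on permuted behavior.
#'
#' @param features output of [feature_matrix()]
#' @param behavior residualized score vector
#' @param config an [analysis_config()]
#' @param nuisance optional Freedman-Lane nuisance columns (see
#'   [permutation_cluster_inference()])
#' @return list `(r, p, null_r)`
#' @export
prediction_performance <- function(features, behavior,
                                   config = analysis_config(),
                                   nuisance = NULL) {
  P <- as.integer(config$n_permutations)
  X <- features$X
  n <- nrow(X)
  if (stats::sd(behavior) == 0) stop("degenerate behavior: zero variance")
  y <- as.numeric(scale(behavior))
  .with_seed(config$rng_seed, {
    K <- .svr_kernel(X, config$svr_kernel, config$svr_gamma)
    Y <- cbind(y, vapply(seq_len(P), function(i) y[sample.int(n)],
                         numeric(n)))
    if (!is.null(nuisance))
      Y[, -1] <- residualize(Y[, -1, drop = FALSE], nuisance)
    A <- esvr_fit_multi(K, Y, config$svr_cost, config$svr_epsilon)
    fitted <- K %*% A
    rvec <- vapply(seq_len(P + 1L),
                   function(k) if (stats::sd(fitted[, k]) == 0) NA_real_
                               else stats::cor(fitted[, k], Y[, k]),
                   numeric(1))
    if (is.na(rvec[1])) stop("zero-variance predictions: r undefined")
    list(r = rvec[1],
         p = (1 + sum(rvec[-1] >= rvec[1], na.rm = TRUE)) / (P + 1),
         null_r = rvec[-1])
  })
}

#' Full SVR-LSM / SVR-SDSM analysis from masks and a cohort
#'
#' Builds the coverage mask, excludes patients without coverage voxels,
#' regresses lesion volume out of both the feature columns and the
#' behavior (optional extra covariates come out of behavior only), and
#' runs [permutation_cluster_inference()].
#'
#' @param masks list of [lesion_mask()] (lesions or binarized
#'   disconnectomes), one per patient, identical geometry
#' @param cohort a [cohort_table()] covering every mask's patient id
#' @param config an [analysis_config()]
#' @param covariates optional character vector of cohort columns regressed
#'   out of behavior (e.g. `c("age","sex","nihss","barthel")`)
#' @param volumes optional per-patient volumes (ml) used for lesion-volume
#'   control; defaults to each mask's own volume
#' @return an `svr_result` with an added `exclusions` data.frame and
#'   `n_analyzed`
#' @export
svr_lsm <- function(masks, cohort, config = analysis_config(),
                    covariates = NULL, volumes = NULL) {
  ids <- vapply(masks, function(m) m$patient_id, "")
  cohort <- cohort[match(ids, cohort$patient_id), , drop = FALSE]
  if (anyNA(cohort$patient_id)) stop("cohort rows missing for some masks")
  if (!is.null(volumes) && length(volumes) != length(masks))
    stop("volumes must align with masks")
  keep <- !cohort$excluded
  masks <- masks[keep]; cohort_in <- cohort[keep, , drop = FALSE]
  if (!is.null(volumes)) volumes <- volumes[keep]
  cov_mask <- build_coverage_mask(masks, config$min_lesion_overlap)
  if (length(cov_mask$excluded_ids)) {
    drop <- cohort_in$patient_id %in% cov_mask$excluded_ids
    cohort$excluded[match(cohort_in$patient_id[drop], cohort$patient_id)] <- TRUE
    cohort$exclusion_reason[match(cohort_in$patient_id[drop],
                                  cohort$patient_id)] <- "no voxels in coverage mask"
    masks <- masks[!drop]; cohort_in <- cohort_in[!drop, , drop = FALSE]
    if (!is.null(volumes)) volumes <- volumes[!drop]
  }
  fm <- feature_matrix(masks, cov_mask)
  if (is.null(volumes)) volumes <- vapply(masks, lesion_volume_ml, 0)
  nuis_beh <- cbind(volume = volumes)
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(cohort_in))
    if (length(miss)) stop("covariates not in cohort: ", paste(miss, collapse = ", "))
    nuis_beh <- cbind(nuis_beh, as.matrix(cohort_in[, covariates, drop = FALSE]))
  }
  behavior <- residualize(cohort_in$hads_d, nuis_beh)
  fm$X <- residualize(fm$X, volumes)
  res <- permutation_cluster_inference(fm, behavior, config,
                                       nuisance = nuis_beh)
  res$exclusions <- cohort[cohort$excluded,
                           c("patient_id", "exclusion_reason"), drop = FALSE]
  res$n_input <- length(ids)
  res$n_analyzed <- nrow(fm$X)
  res$coverage <- cov_mask
  res
}

#' @export
print.svr_result <- function(x, ...) {
  nsig <- sum(vapply(x$clusters, function(cl) isTRUE(cl$significant), TRUE))
  cat(sprintf(paste0("<svr_result: %d permutations, r = %.3f (p = %.4g), ",
                     "%d cluster(s), %d FWE-significant>\n"),
              x$n_permutations, x$prediction_r, x$prediction_p,
              length(x$clusters), nsig))
  invisible(x)
}
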