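# Depression-circuit map and the network damage score: a spherical seed's
# normative connectivity t-map, summed over each patient's lesion voxels,
# residualized against lesion volume, and compared between groups with a
# permutation t-test.

#' Spherical ROI mask
#'
#' Voxels whose centers lie within `diameter_mm / 2` of the world-mm
#' center (center-inclusion voxelization).
#'
#' @param center_world 3-vector, world mm
#' @param diameter_mm sphere diameter (not radius)
#' @param dims grid dimensions
#' @param affine voxel-to-world transform
#' @return a [lesion_mask()]
#' @export
sphere_roi <- function(center_world, diameter_mm, dims, affine) {
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  world <- t(affine %*% rbind(t(idx), 1))[, 1:3]
  d2 <- rowSums((world - matrix(center_world, nrow(world), 3, byrow = TRUE))^2)
  g <- array(as.integer(d2 <= (diameter_mm / 2)^2), dims)
  if (sum(g) == 0) stop("sphere contains no voxel centers")
  lesion_mask(g, affine, patient_id = "sphere_roi")
}

#' Circuit t-map from a spherical seed
#'
#' For each normative subject, that subject's run-level Fisher-z seed maps
#' are averaged; the circuit map is the voxelwise one-sample t across
#' subjects (`mean / (sd / sqrt(n))`), with zero-variance voxels set to 0
#' and logged.
#'
#' @param runs list of `cleaned_run` or `normative_run` objects
#' @param center 3-vector, world mm (peak coordinates of the target circuit)
#' @param diameter_mm sphere diameter in mm
#' @param config an [analysis_config()]
#' @return list of class `circuit_map`: `tmap` ([stat_map()]),
#'   `roi` (the sphere mask), `n_subjects`
#' @export
circuit_tmap <- function(runs, center, diameter_mm = 9,
                         config = analysis_config()) {
  cleaned <- lapply(runs, function(r)
    if (inherits(r, "cleaned_run")) r else preprocess_run(r, config))
  subjects <- unique(vapply(cleaned, function(r) r$subject_id, ""))
  if (length(subjects) < 3) stop("need >= 3 normative subjects")
  d <- dim(cleaned[[1]]$data)[1:3]
  affine <- cleaned[[1]]$affine
  roi <- sphere_roi(center, diameter_mm, d, affine)
  zsubj <- vapply(subjects, function(s) {
    rs <- cleaned[vapply(cleaned, function(r) r$subject_id, "") == s]
    zs <- vapply(rs, function(r) {
      seed <- roi_eigenvariate(r, roi)
      as.vector(seed_connectivity_map(r, seed)$grid)
    }, numeric(prod(d)))
    rowMeans(zs)
  }, numeric(prod(d)))
  m <- rowMeans(zsubj)
  s <- apply(zsubj, 1, stats::sd)
  tv <- numeric(length(m))
  ok <- s > 0
  tv[ok] <- m[ok] / (s[ok] / sqrt(length(subjects)))
  if (any(!ok)) .sm_log(sum(!ok), " zero-variance voxel(s) set to t = 0")
  structure(list(tmap = stat_map(array(tv, d), "t", affine = affine),
                 roi = roi, roi_center_world = center,
                 roi_diameter_mm = diameter_mm,
                 n_subjects = length(subjects)),
            class = "circuit_map")
}

#' Network damage score of one lesion
#'
#' Sum of the circuit-map t-values over the patient's lesion voxels
#' (unthresholded by default; `positive_only` restricts the sum to
#' positive t-values for sensitivity analyses).
#'
#' @param lesion a [lesion_mask()]
#' @param circuit a `circuit_map` (or a `stat_map` of kind t)
#' @param positive_only sum only positive t-values
#' @return scalar score
#' @export
network_damage_score <- function(lesion, circuit, positive_only = FALSE) {
  tmap <- if (inherits(circuit, "circuit_map")) circuit$tmap else circuit
  .same_geometry(lesion, tmap, "lesion and circuit map")
  tv <- tmap$grid[lesion$grid == 1]
  if (positive_only) tv <- tv[tv > 0]
  sum(tv)
}

#' Residualize network damage scores against lesion volume
#'
#' @param scores per-patient raw scores
#' @param lesion_volumes per-patient lesion volumes (ml)
#' @return OLS residuals of score on volume plus intercept
#' @export
residualize_nds <- function(scores, lesion_volumes) {
  stopifnot(length(scores) >= 3, length(scores) == length(lesion_volumes))
  if (stats::sd(lesion_volumes) == 0) stop("constant lesion volumes")
  residualize(scores, lesion_volumes)
}

.pooled_t <- function(x, g1) {
  n1 <- sum(g1); n2 <- length(x) - n1
  m1 <- mean(x[g1]); m2 <- mean(x[!g1])
  sp2 <- (sum((x[g1] - m1)^2) + sum((x[!g1] - m2)^2)) / (n1 + n2 - 2)
  if (sp2 == 0) return(if (m1 == m2) 0 else sign(m1 - m2) * Inf)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Permutation group test on residualized scores
#'
#' Two-sample mode: statistic is the pooled-variance two-sample t; labels
#' are permuted; the two-tailed p is
#' `(1 + #{perm |t| >= |observed|}) / (P + 1)` for Monte-Carlo draws, or
#' the exact proportion over all label assignments when their number is
#' at most `exhaustive_limit` (then used automatically). Continuous mode:
#' statistic is the Pearson correlation with the (permuted) scores.
#'
#' @param residuals per-patient residualized network damage scores
#' @param labels logical/two-level group labels, or numeric scores with
#'   `mode = "continuous"`
#' @param n_perm Monte-Carlo permutations
#' @param seed RNG seed
#' @param mode `"two_sample"` or `"continuous"`
#' @param exhaustive_limit maximum number of assignments enumerated exactly
#' @return list: `statistic`, `p`, `n_permutations`, `exhaustive`
#' @export
permutation_group_test <- function(residuals, labels, n_perm = 1e6L,
                                   seed = 1L,
                                   mode = c("two_sample", "continuous"),
                                   exhaustive_limit = 1e6) {
  mode <- match.arg(mode)
  x <- as.numeric(residuals)
  n <- length(x)
  if (mode == "continuous") {
    y <- as.numeric(labels)
    obs <- stats::cor(x, y)
    p <- .with_seed(seed, {
      perm <- vapply(seq_len(n_perm),
                     function(i) stats::cor(x, y[sample.int(n)]), numeric(1))
      (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
    })
    return(list(statistic = obs, p = p, n_permutations = as.integer(n_perm),
                exhaustive = FALSE, mode = mode))
  }
  g <- if (is.logical(labels)) labels else labels == sort(unique(labels))[1]
  n1 <- sum(g)
  if (n1 == 0 || n1 == n) stop("both groups must be non-empty")
  obs <- .pooled_t(x, g)
  n_assign <- choose(n, n1)
  if (n_assign <= exhaustive_limit) {
    # all assignments of n1 subjects to group 1; t is a monotone function
    # of the group-1 sum, computed from sums for speed
    combs <- utils::combn(n, n1)
    s_tot <- sum(x); ss_tot <- sum(x^2)
    n2 <- n - n1
    s1 <- colSums(matrix(x[combs], nrow = n1))
    m1 <- s1 / n1; m2 <- (s_tot - s1) / n2
    ss_within <- ss_tot - n1 * m1^2 - n2 * m2^2
    sp2 <- pmax(ss_within, 0) / (n - 2)
    tperm <- ifelse(sp2 == 0, ifelse(m1 == m2, 0, Inf * sign(m1 - m2)),
                    (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2)))
    p <- sum(abs(tperm) >= abs(obs) - 1e-12) / n_assign
    return(list(statistic = obs, p = p,
                n_permutations = as.integer(n_assign), exhaustive = TRUE,
                mode = mode))
  }
  p <- .with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      gp <- rep(FALSE, n)
      gp[sample.int(n, n1)] <- TRUE
      if (abs(.pooled_t(x, gp)) >= abs(obs) - 1e-12) cnt <- cnt + 1L
    }
    (1 + cnt) / (n_perm + 1)
  })
  list(statistic = obs, p = p, n_permutations = as.integer(n_perm),
       exhaustive = FALSE, mode = mode)
}

#' Network damage score analysis for a cohort
#'
#' Computes every patient's raw score against the circuit map,
#' residualizes against lesion volume, and runs the permutation group
#' test at a HADS-D cutoff (two-sample) or on the continuous scores.
#'
#' @param masks list of [lesion_mask()]
#' @param cohort a [cohort_table()]
#' @param circuit a `circuit_map`
#' @param cutoff HADS-D cutoff (`> cutoff` = depressed); `NULL` runs the
#'   continuous-correlation variant
#' @param n_perm,seed permutation settings
#' @return list of class `nds_result`: per-patient `scores` data.frame,
#'   `test` (from [permutation_group_test()]), `cutoff`
#' @export
nds_analysis <- function(masks, cohort, circuit, cutoff = 10L,
                         n_perm = 1e4L, seed = 1L) {
  ids <- vapply(masks, function(m) m$patient_id, "")
  cohort <- cohort[match(ids, cohort$patient_id), , drop = FALSE]
  keep <- !cohort$excluded
  masks <- masks[keep]; cohort_in <- cohort[keep, , drop = FALSE]
  raw <- vapply(masks, network_damage_score, numeric(1), circuit = circuit)
  vols <- vapply(masks, lesion_volume_ml, numeric(1))
  resid <- residualize_nds(raw, vols)
  if (is.null(cutoff)) {
    test <- permutation_group_test(resid, cohort_in$hads_d, n_perm, seed,
                                   mode = "continuous")
  } else {
    depressed <- cohort_in$hads_d > cutoff
    test <- permutation_group_test(resid, depressed, n_perm, seed)
  }
  structure(list(
    scores = data.frame(patient_id = cohort_in$patient_id,
                        raw_score = raw, residual_score = resid,
                        lesion_volume_ml = vols, hads_d = cohort_in$hads_d),
    test = test, cutoff = cutoff, seed = seed),
    class = "nds_result")
}

#' @export
print.nds_result <- function(x, ...) {
  cat(sprintf("<nds_result: n = %d, statistic = %.3f, p = %.4g (%s)>\n",
              nrow(x$scores), x$test$statistic, x$test$p,
              if (x$test$exhaustive) "exhaustive" else "Monte-Carlo"))
  invisible(x)
}
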