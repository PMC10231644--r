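# network_damage: circuit t-map, damage score, permutation group test.

test_that("sphere voxelization matches a brute-force distance check", {
  dims <- c(24L, 24L, 24L)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -23
  center <- c(3, -5, 1)
  roi <- sphere_roi(center, 9, dims, aff)
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  world <- t(aff %*% rbind(t(idx), 1))[, 1:3]
  oracle <- as.integer(sqrt(rowSums(sweep(world, 2, center)^2)) <= 4.5)
  expect_identical(as.vector(roi$grid), oracle)
  expect_gt(sum(roi$grid), 0)
  expect_error(sphere_roi(c(1000, 0, 0), 9, dims, aff), "no voxel centers")
})

test_that("one-sample t across subjects follows the closed form", {
  # subject z-values {0.1, 0.2, 0.3} -> t = mean/(sd/sqrt(3)) = 3.464
  z <- c(0.1, 0.2, 0.3)
  expect_equal(mean(z) / (sd(z) / sqrt(3)), 3.4641016, tolerance = 1e-6)
  w <- tiny_runs_cache()
  ctr_world <- as.numeric(w$truth$affine %*% c(8, 8, 8, 1))[1:3]
  cm <- expect_silent_log(circuit_tmap(w$cleaned, ctr_world, 9,
                                       analysis_config()))
  expect_equal(cm$n_subjects, 3L)
  expect_true(all(is.finite(cm$tmap$grid)))
  # oracle on a handful of voxels: recompute subject means directly
  subj <- unique(vapply(w$cleaned, function(r) r$subject_id, ""))
  zmaps <- lapply(subj, function(s) {
    rs <- w$cleaned[vapply(w$cleaned, function(r) r$subject_id, "") == s]
    Reduce(`+`, lapply(rs, function(r)
      seed_connectivity_map(r, roi_eigenvariate(r, cm$roi))$grid)) / length(rs)
  })
  for (vox in list(c(4, 4, 4), c(8, 8, 8), c(12, 10, 6))) {
    zz <- vapply(zmaps, function(m) m[vox[1], vox[2], vox[3]], 0)
    expected <- if (sd(zz) > 0) mean(zz) / (sd(zz) / sqrt(3)) else 0
    expect_equal(cm$tmap$grid[vox[1], vox[2], vox[3]], expected,
                 tolerance = 1e-8)
  }
  expect_error(circuit_tmap(w$cleaned[1:2], ctr_world, 9, analysis_config()),
               ">= 3")
})

test_that("network damage score is an exact lesion-voxel sum", {
  dims <- c(8L, 8L, 8L)
  aff <- diag(4)
  tg <- array(0, dims)
  tg[2, 2, 2] <- 1.5; tg[3, 2, 2] <- -0.5; tg[4, 2, 2] <- 2.0
  circ <- stat_map(tg, "t", affine = aff)
  les <- block_mask(dims, c(2, 2, 2), c(4, 2, 2), affine = aff)
  expect_equal(network_damage_score(les, circ), 3.0)
  expect_equal(network_damage_score(les, circ, positive_only = TRUE), 3.5)
  empty <- expect_silent_log(lesion_mask(array(0L, dims), aff, "e",
                                         allow_empty = TRUE))
  expect_equal(network_damage_score(empty, circ), 0)
  # additive over disjoint lesions
  set.seed(61)
  tmap <- stat_map(array(rnorm(prod(dims)), dims), "t", affine = aff)
  a <- block_mask(dims, c(1, 1, 1), c(3, 3, 3), affine = aff)
  b <- block_mask(dims, c(5, 5, 5), c(7, 7, 7), affine = aff)
  ab <- lesion_mask(array(as.integer(a$grid | b$grid), dims), aff, "ab")
  expect_equal(network_damage_score(ab, tmap),
               network_damage_score(a, tmap) + network_damage_score(b, tmap))
  expect_error(network_damage_score(
    block_mask(c(4L, 4L, 4L), c(1, 1, 1), c(2, 2, 2)), tmap), "mismatch")
})

test_that("NDS residualization matches the least-squares oracle", {
  set.seed(62)
  vols <- runif(8, 1, 40)
  expect_equal(residualize_nds(3 * vols, vols), rep(0, 8), tolerance = 1e-10)
  scores <- rnorm(8)
  X <- cbind(1, vols)
  oracle <- as.numeric(scores - X %*% solve(t(X) %*% X, t(X) %*% scores))
  expect_equal(residualize_nds(scores, vols), oracle, tolerance = 1e-10)
  expect_lt(abs(sum(residualize_nds(scores, vols) * vols)), 1e-8)
  expect_error(residualize_nds(scores, rep(2, 8)), "constant")
})

test_that("permutation group test is exact for the toy instance", {
  res <- permutation_group_test(c(1, 2, 3, 4, 5, 6),
                                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 20L)
  expect_equal(res$p, 0.1)              # 2 of 20 assignments reach |t_obs|
  # identical group values -> p = 1
  same <- permutation_group_test(rep(2, 6),
                                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(same$p, 1)
  expect_error(permutation_group_test(1:4, rep(TRUE, 4)), "non-empty")
  # continuous mode returns a correlation statistic
  set.seed(63)
  rc <- permutation_group_test(rnorm(12), rnorm(12), n_perm = 500,
                               mode = "continuous")
  expect_equal(rc$mode, "continuous")
  expect_true(rc$p >= 1 / 501 && rc$p <= 1)
})

test_that("Monte-Carlo and exhaustive p agree within 3 standard errors", {
  set.seed(64)
  x <- rnorm(10)
  g <- rep(c(TRUE, FALSE), each = 5)
  ex <- permutation_group_test(x, g)             # 252 assignments, exact
  mc <- permutation_group_test(x, g, n_perm = 1e4, seed = 2,
                               exhaustive_limit = 10)
  se <- sqrt(ex$p * (1 - ex$p) / 1e4)
  expect_false(mc$exhaustive)
  expect_lt(abs(mc$p - ex$p), 3 * se + 1e-4)
})

test_that("nds_analysis assembles scores, residuals and the group test", {
  w <- tiny_runs_cache()
  tr <- w$truth
  cc <- expect_silent_log(generate_lesion_cohort(14, tr, seed = 65))
  ctr_world <- as.numeric(tr$affine %*% c(8, 8, 8, 1))[1:3]
  cm <- expect_silent_log(circuit_tmap(w$cleaned, ctr_world, 9,
                                       analysis_config()))
  res <- nds_analysis(cc$masks, cc$cohort, cm, cutoff = 10L, n_perm = 500L,
                      seed = 3L)
  expect_equal(nrow(res$scores), 14)
  expect_lt(abs(sum(res$scores$residual_score *
                    res$scores$lesion_volume_ml)), 1e-6)
  expect_true(res$test$p >= 0 && res$test$p <= 1)
  # continuous variant
  resc <- nds_analysis(cc$masks, cc$cohort, cm, cutoff = NULL,
                       n_perm = 500L, seed = 3L)
  expect_equal(resc$test$mode, "continuous")
})
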