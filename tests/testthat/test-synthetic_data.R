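# synthetic_data: planted effects, determinism, motion, bundles.

test_that("lesion cohorts are reproducible and respect the score model", {
  tr <- tiny_truth()
  cc1 <- expect_silent_log(generate_lesion_cohort(30, tr, seed = 5))
  cc2 <- expect_silent_log(generate_lesion_cohort(30, tr, seed = 5))
  expect_identical(cc1$cohort$hads_d, cc2$cohort$hads_d)
  expect_identical(cc1$masks[[7]]$grid, cc2$masks[[7]]$grid)
  expect_true(all(vapply(cc1$masks, function(m) sum(m$grid) > 0, TRUE)))
  expect_true(all(cc1$cohort$hads_d >= 0 & cc1$cohort$hads_d <= 21))
  # lesions are connected under 6-connectivity
  for (m in cc1$masks[1:5]) {
    cl <- label_clusters(m$grid, connectivity = 6L)
    expect_length(cl, 1L)
  }
})

test_that("null cohorts carry no lesion-score association", {
  tr0 <- tiny_truth(effect_size = 0)
  cc <- expect_silent_log(generate_lesion_cohort(80, tr0, seed = 6))
  r <- cor(cc$cohort$overlap_frac, cc$cohort$hads_d)
  expect_lt(abs(r), 3 / sqrt(80))
})

test_that("planted effect separates high- from zero-coverage patients", {
  tr <- tiny_truth(effect_size = 10, noise_sd = 0.5)
  cc <- expect_silent_log(generate_lesion_cohort(60, tr, seed = 7))
  hi <- cc$cohort$hads_d[cc$cohort$overlap_frac > 0.5]
  lo <- cc$cohort$hads_d[cc$cohort$overlap_frac == 0]
  expect_gt(length(hi), 0)   # this seed produces heavily-overlapping lesions
  expect_gt(mean(hi), mean(lo))
})

test_that("normative series have community structure and exact FD spikes", {
  tr <- tiny_truth()
  # noise -> 0: same-community voxels correlate ~1 within every run;
  # cross-community correlations (independent band-limited signals with
  # few effective dof per run) average to ~0 over runs
  runs <- generate_normative_timeseries(10, 2, 120, truth = tr, seed = 9,
                                        community_weight = 0.999)
  comm <- tr$network_modules
  idx_by_comm <- lapply(1:2, function(k) which(comm == k))
  v <- function(run, i) {
    a <- arrayInd(i, dim(comm))
    run$data[a[1], a[2], a[3], ]
  }
  same <- vapply(runs, function(r)
    cor(v(r, idx_by_comm[[1]][1]), v(r, idx_by_comm[[1]][2])), 0)
  cross <- vapply(runs, function(r)
    cor(v(r, idx_by_comm[[1]][1]), v(r, idx_by_comm[[2]][1])), 0)
  expect_true(all(same > 0.95))
  # ~12 effective dof per band-limited run: per-run r has sd ~0.4, so the
  # mean over 20 runs is tested at 3 standard errors
  expect_lt(abs(mean(cross)), 3 * 0.4 / sqrt(length(cross)))
  expect_identical(dim(runs[[1]]$motion), c(120L, 6L))
  # injected high-motion frames: exactly 3 frames exceed the threshold,
  # recomputed from the motion table itself
  runs2 <- generate_normative_timeseries(1, 1, 60, truth = tr, seed = 9,
                                         n_high_motion_frames = 3L,
                                         high_motion_mm = 1.0)
  fd <- framewise_displacement(runs2[[1]]$motion)
  expect_equal(sum(fd > 0.5), 3L)
})

test_that("tractograms honor spread and intersect as constructed", {
  tr <- tiny_truth(bundle_spread = 0)
  tg <- generate_normative_tractograms(3, tr, streamlines_per_bundle = 5,
                                       seed = 3)
  # spread = 0: every subject's bundle visits the identical voxel path
  vox_path <- function(t) {
    pts <- t$streamlines[[1]]
    inv <- solve(tr$affine)
    pv <- t(inv %*% rbind(t(pts), 1))[, 1:3]
    sort(unique(strokemap:::streamline_voxels(pv, tr$grid_shape)))
  }
  expect_identical(vox_path(tg[[1]]), vox_path(tg[[2]]))
  expect_identical(vox_path(tg[[1]]), vox_path(tg[[3]]))
  # a lesion on bundle 1's midpoint intersects it in every subject
  spec <- tr$bundle_specs[[1]]
  mid_world <- (spec$a + spec$b) / 2
  mid_vox <- round(solve(tr$affine) %*% c(mid_world, 1))[1:3] + 1
  les <- block_mask(tr$grid_shape, mid_vox - 1, mid_vox + 1,
                    affine = tr$affine)
  for (t in tg) {
    dmap <- subject_disconnection(les, t)
    expect_gt(sum(dmap), 0)
  }
  # a lesion disjoint from all bundles yields an empty map
  far <- block_mask(tr$grid_shape, c(1, 1, 1), c(2, 2, 2), affine = tr$affine)
  expect_equal(sum(subject_disconnection(far, tg[[1]])), 0)
})

test_that("tractogram text format round-trips", {
  tr <- tiny_truth()
  tg <- generate_normative_tractograms(1, tr, streamlines_per_bundle = 3,
                                       seed = 8)[[1]]
  p <- file.path(withr::local_tempdir(), "t.txt")
  write_tractogram(tg, p)
  rt <- read_tractogram(p)
  expect_equal(rt$subject_id, tg$subject_id)
  expect_length(rt$streamlines, length(tg$streamlines))
  expect_equal(rt$streamlines[[2]], tg$streamlines[[2]], tolerance = 1e-3)
})
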