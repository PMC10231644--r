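# disconnectome: streamline traversal, aggregation, cutoff semantics.

test_that("subject_disconnection includes the full path of hit streamlines", {
  dims <- c(8L, 8L, 8L)
  aff <- diag(4)
  # streamline through voxels (1,1,1)-(2,1,1)-(3,1,1) in 0-based indices
  tract <- structure(list(subject_id = "s1", streamlines = list(
    cbind(c(1, 2, 3), c(1, 1, 1), c(1, 1, 1)))), class = "tractogram")
  les <- block_mask(dims, c(3, 2, 2), c(3, 2, 2), affine = aff)  # voxel (2,1,1)
  m <- subject_disconnection(les, tract)
  expect_equal(which(m == 1) - 1,
               c(1 + 8 * (1 + 8 * 1), 2 + 8 * (1 + 8 * 1), 3 + 8 * (1 + 8 * 1)))
  # disjoint lesion -> empty
  far <- block_mask(dims, c(7, 7, 7), c(8, 8, 8), affine = aff)
  expect_equal(sum(subject_disconnection(far, tract)), 0)
  expect_error(subject_disconnection(les, structure(
    list(subject_id = "e", streamlines = list()), class = "tractogram")),
    "empty tractogram")
})

test_that("segment traversal fills gaps a vertex test would skip", {
  dims <- c(10L, 10L, 10L)
  aff <- diag(4)
  # consecutive points two voxels apart: intermediate voxel must be set
  tract <- structure(list(subject_id = "s", streamlines = list(
    cbind(c(2, 4), c(2, 2), c(2, 2)))), class = "tractogram")
  les <- block_mask(dims, c(3, 3, 3), c(3, 3, 3), affine = aff)  # voxel (2,2,2)
  mt <- subject_disconnection(les, tract, mode = "traversal")
  expect_equal(mt[4, 3, 3], 1L)                   # voxel (3,2,2), skipped vertex
  mv <- subject_disconnection(les, tract, mode = "vertex")
  expect_equal(mv[4, 3, 3], 0L)
  # traversal agrees with a dense point-resampling oracle on random segments
  set.seed(41)
  for (k in 1:50) {
    pts <- matrix(runif(6, 0, 9), 2, 3)
    got <- sort(strokemap:::streamline_voxels(pts, dims))
    tt <- seq(0, 1, length.out = 5000)
    dense <- unique(round(outer(1 - tt, pts[1, ]) + outer(tt, pts[2, ])))
    oracle <- sort(unique(dense[, 1] + 10 * (dense[, 2] + 10 * dense[, 3])))
    expect_true(all(oracle %in% got))
  }
})

test_that("percent aggregation and inclusive cutoff follow their formulas", {
  dims <- c(4L, 4L, 4L)
  mk <- function(on) { g <- array(0L, dims); if (on) g[2, 2, 2] <- 1L; g }
  maps <- c(lapply(1:6, function(i) mk(TRUE)), lapply(1:4, function(i) mk(FALSE)))
  dm <- aggregate_percent(maps)
  expect_equal(dm$percent$grid[2, 2, 2], 60)
  expect_equal(dm$n_subjects, 10)
  expect_equal(max(aggregate_percent(lapply(1:5, function(i) mk(TRUE)))$percent$grid), 100)
  # >= rule at the cutoff; just below is unset
  expect_equal(binarize_cutoff(dm, 60)$binary$grid[2, 2, 2], 1L)
  expect_equal(binarize_cutoff(dm, 60.1)$binary$grid[2, 2, 2], 0L)
  # raising the cutoff never adds voxels
  sizes <- vapply(c(40, 50, 60, 70, 80),
                  function(ct) sum(binarize_cutoff(dm, ct)$binary$grid), 0)
  expect_true(all(diff(sizes) <= 0))
  expect_error(aggregate_percent(list(mk(TRUE))), ">= 2")
})

test_that("growing a lesion grows its disconnectome", {
  tr <- tiny_truth()
  tg <- generate_normative_tractograms(2, tr, streamlines_per_bundle = 10,
                                       seed = 12)
  spec <- tr$bundle_specs[[1]]
  mid <- round(solve(tr$affine) %*% c((spec$a + spec$b) / 2, 1))[1:3] + 1
  small <- block_mask(tr$grid_shape, mid, mid, affine = tr$affine)
  big <- block_mask(tr$grid_shape, mid - 1, mid + 1, affine = tr$affine)
  for (t in tg) {
    ms <- subject_disconnection(small, t)
    mb <- subject_disconnection(big, t)
    expect_true(all(mb[ms == 1] == 1))
  }
})
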