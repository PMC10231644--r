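# lnsm: preprocessing, eigenvariates, seed maps, GLM inference.

test_that("band-pass keeps in-band and rejects out-of-band sinusoids", {
  tr <- tiny_truth()
  cfg <- analysis_config()
  run <- generate_normative_timeseries(1, 1, 120, truth = tr, seed = 51)[[1]]
  # plant pure sinusoids in two voxels far from tissue-mean influence
  t_s <- (seq_len(120) - 1) * run$tr_s
  amp_at <- function(v, f) {
    k <- round(f * length(v) * run$tr_s) + 1
    abs(fft(v - mean(v)))[k]
  }
  run$motion[] <- 0                       # zero motion: FD = 0, no censoring
  s_in <- sin(2 * pi * 0.04 * t_s)
  s_out <- sin(2 * pi * 0.2 * t_s)
  run$data[2, 2, 2, ] <- 1000 + 100 * s_in
  run$data[14, 14, 14, ] <- 1000 + 100 * s_out
  cl <- preprocess_run(run, cfg)
  expect_equal(length(cl$kept_frames), 120)
  expect_equal(max(cl$fd), 0)
  # smoothing attenuates a bit spatially; compare against the planted
  # amplitude that survives smoothing by measuring pre/post band ratio
  v_in <- cl$data[2, 2, 2, ]
  v_out <- cl$data[14, 14, 14, ]
  expect_gt(amp_at(v_in, 0.04) / amp_at(gaussian_smooth(run$data, 5,
            run$affine[1, 1])[2, 2, 2, ], 0.04), 0.9)
  expect_lt(amp_at(v_out, 0.2) / amp_at(gaussian_smooth(run$data, 5,
            run$affine[1, 1])[14, 14, 14, ], 0.2), 0.1)
  expect_identical(cl$steps, c("smooth", "nuisance_regression", "bandpass",
                               "censor"))
})

test_that("nuisance residuals are orthogonal and censoring errors when empty", {
  tr <- tiny_truth()
  cfg <- analysis_config()
  run <- generate_normative_timeseries(1, 1, 40, truth = tr, seed = 52)[[1]]
  run$motion[, 1] <- run$motion[, 1] + cumsum(rep(1, 40))  # every frame FD > 0.5
  expect_error(suppressMessages(preprocess_run(run, cfg)), "unusable")
})

test_that("roi_eigenvariate matches rank-1 and SVD oracles", {
  set.seed(53)
  d <- c(4L, 4L, 4L); T <- 30L
  dat <- array(rnorm(prod(d) * T), c(d, T))
  aff <- diag(4)
  single <- block_mask(d, c(2, 2, 2), c(2, 2, 2), affine = aff)
  u <- roi_eigenvariate(dat, single)
  expect_equal(abs(cor(u, dat[2, 2, 2, ])), 1, tolerance = 1e-10)
  expect_gte(cor(u, dat[2, 2, 2, ]), 0)          # sign rule
  # identical voxels: eigenvariate is the (scaled) common series
  common <- rnorm(T)
  dat2 <- dat
  for (i in 2:3) for (j in 2:3) dat2[i, j, 2, ] <- common
  roi <- block_mask(d, c(2, 2, 2), c(3, 3, 2), affine = aff)
  u2 <- roi_eigenvariate(dat2, roi)
  expect_equal(cor(u2, common), 1, tolerance = 1e-10)
  expect_equal(sd(u2), 1, tolerance = 1e-10)
  # 3-voxel toy matrix vs direct singular decomposition
  roi3 <- block_mask(d, c(1, 1, 1), c(3, 1, 1), affine = aff)
  M <- t(matrix(dat, nrow = prod(d)))[, which(roi3$grid == 1)]
  sv <- svd(M)
  ue <- sv$u[, 1] / sd(sv$u[, 1])
  if (cor(ue, rowMeans(M)) < 0) ue <- -ue
  expect_equal(roi_eigenvariate(dat, roi3), ue, tolerance = 1e-8)
  expect_error(roi_eigenvariate(dat, expect_silent_log(
    lesion_mask(array(0L, d), aff, "e", allow_empty = TRUE))), "empty ROI")
})

test_that("seed maps apply the Fisher transform with clipping", {
  set.seed(54)
  d <- c(3L, 3L, 3L); T <- 50L
  dat <- array(rnorm(prod(d) * T), c(d, T))
  seed <- dat[1, 1, 1, ]
  dat[3, 3, 3, ] <- 0                            # zero-variance voxel
  # plant r = 0.5 exactly via orthogonalization
  e <- residualize(rnorm(T), seed)
  dat[2, 2, 2, ] <- 0.5 * scale(seed) + sqrt(0.75) * scale(e)
  zm <- expect_silent_log(seed_connectivity_map(dat, seed))
  expect_equal(zm$grid[1, 1, 1], atanh(1 - 1e-7))    # clip rule at r = 1
  expect_equal(zm$grid[2, 2, 2], 0.5493, tolerance = 1e-3)
  expect_equal(zm$grid[3, 3, 3], 0)                  # zero variance -> 0
  expect_error(seed_connectivity_map(dat, rep(1, T)), "constant seed")
  expect_error(seed_connectivity_map(dat, seed[-1]), "kept-frame")
})

test_that("lesion network maps average runs and ignore subject duplication", {
  w <- tiny_runs_cache()
  roi <- gray_matter_roi(block_mask(w$truth$grid_shape, c(12, 8, 8),
                                    c(13, 9, 9), affine = w$truth$affine),
                         w$truth$gm_prob)
  expect_gt(sum(roi$grid), 0)
  cfg <- analysis_config()
  one <- lesion_network_map(roi, w$cleaned[1], cfg)
  expect_equal(one$n_maps_averaged, 1L)
  z1 <- seed_connectivity_map(w$cleaned[[1]],
                              roi_eigenvariate(w$cleaned[[1]], roi))
  expect_equal(one$zmap$grid, z1$grid)               # mean of one
  # two identical runs: idempotent mean
  two <- lesion_network_map(roi, list(w$cleaned[[1]], w$cleaned[[1]]), cfg)
  expect_equal(two$zmap$grid, z1$grid, tolerance = 1e-12)
  # duplicating a subject's runs leaves the average unchanged
  all4 <- lesion_network_map(roi, w$cleaned, cfg)
  dup <- lesion_network_map(roi, c(w$cleaned, w$cleaned), cfg)
  expect_equal(dup$zmap$grid, all4$zmap$grid, tolerance = 1e-12)
})

test_that("network maps carry the lesion's community signature", {
  w <- tiny_runs_cache()
  tr <- w$truth
  comm <- tr$network_modules
  # ROI entirely inside community 1
  idx1 <- which(comm == 1, arr.ind = TRUE)
  ctr <- idx1[which.min(rowSums(sweep(idx1, 2, colMeans(idx1))^2)), ]
  roi <- block_mask(tr$grid_shape, ctr, ctr, affine = tr$affine)
  nm <- lesion_network_map(roi, w$cleaned, analysis_config())
  z <- as.vector(nm$zmap$grid)
  z_same <- mean(z[comm == 1 & as.vector(roi$grid) == 0])
  z_other <- mean(z[comm %in% 2:4])
  expect_gt(z_same, z_other)
})

test_that("voxelwise GLM t matches the normal-equations oracle", {
  set.seed(55)
  n <- 12; v <- 25
  M <- matrix(rnorm(n * v), n, v)
  y <- rnorm(n)
  cfg <- analysis_config(n_permutations = 50L, rng_seed = 9L)
  res <- suppressMessages(
    lnsm_glm_inference(M, y, cfg, dims = c(v, 1L, 1L)))
  tvals <- res$t_map$grid[seq_len(v)]
  oracle <- vapply(seq_len(v), function(j) {
    X <- cbind(1, M[, j])
    bh <- solve(t(X) %*% X, t(X) %*% y)
    se <- sqrt(sum((y - X %*% bh)^2) / (n - 2) * solve(t(X) %*% X)[2, 2])
    bh[2] / se
  }, 0)
  expect_equal(tvals, oracle, tolerance = 1e-8)
})

test_that("GLM restricts to gray matter and region masks", {
  set.seed(56)
  n <- 14
  d <- c(6L, 6L, 6L); v <- prod(d)
  M <- matrix(rnorm(n * v), n, v)
  y <- rnorm(n)
  gm <- array(runif(v), d)
  region <- array(0L, d); region[1:3, , ] <- 1L
  cfg <- analysis_config(n_permutations = 50L, lnsm_voxel_p = 0.3,
                         rng_seed = 10L)
  res <- suppressMessages(
    lnsm_glm_inference(M, y, cfg, gm_prob = gm, region_mask = region,
                       dims = d))
  amask <- as.vector(res$analysis_mask)
  expect_true(all(which(amask == 1) %in%
                  intersect(which(as.vector(gm) >= 0.10),
                            which(as.vector(region) == 1))))
  for (cl in res$clusters)
    expect_true(all(as.vector(region)[cl$voxels] == 1))
})
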