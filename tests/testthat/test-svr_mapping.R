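# svr_mapping: residualization, beta back-projection, clusters, inference.

test_that("residualize matches a normal-equations oracle", {
  set.seed(21)
  # perfect fit -> zero residuals
  vol <- runif(20, 1, 50)
  expect_equal(residualize(2 * vol, vol), rep(0, 20), tolerance = 1e-10)
  # nuisance orthogonal to values -> centered values
  v <- rep(c(-1, 1), 10)
  nuis <- rep(1:2, each = 10)           # orthogonal to v by construction
  expect_equal(residualize(v, nuis), v - mean(v), tolerance = 1e-10)
  # random instance vs explicit solve of the normal equations
  X <- cbind(1, matrix(rnorm(40), 20, 2))
  Y <- matrix(rnorm(60), 20, 3)
  oracle <- Y - X %*% solve(t(X) %*% X, t(X) %*% Y)
  expect_equal(residualize(Y, X[, -1]), oracle, tolerance = 1e-10)
  expect_error(residualize(rnorm(10), cbind(1:10, 2 * (1:10))),
               "rank-deficient")
})

test_that("fit_svr_betamap recovers a planted voxel and ignores duplication", {
  set.seed(22)
  n <- 24; v <- 30
  X <- matrix(rbinom(n * v, 1, 0.3), n, v)
  behavior <- X[, 11] * 5                  # noise-free single informative voxel
  fm <- list(X = X, vox_idx = seq_len(v), dims = c(v, 1L, 1L), affine = diag(4))
  cfg <- analysis_config(svr_kernel = "linear")
  fit <- fit_svr_betamap(fm, behavior, cfg)
  expect_equal(which.max(fit$beta), 11L)
  # reported z-map is sign-flipped: symptom-increasing voxel has minimal z
  expect_equal(which.min(fit$z), 11L)
  # duplicating every patient leaves the beta map unchanged
  fm2 <- fm; fm2$X <- rbind(X, X)
  fit2 <- fit_svr_betamap(fm2, c(behavior, behavior), cfg)
  # duplication invariance is approximate: the epsilon-insensitive loss
  # doubles while the regularizer does not, so solutions agree closely
  # but not exactly
  expect_lt(max(abs(fit2$beta / max(abs(fit2$beta)) -
                    fit$beta / max(abs(fit$beta)))), 0.01)
  expect_error(fit_svr_betamap(fm, rep(1, n), cfg), "zero variance")
})

test_that("the SVR dual solution satisfies its KKT conditions", {
  # independent optimality oracle for min 0.5 a'Ka - y'a + eps||a||_1,
  # |a_i| <= C: at a minimizer, g = Ka - y must satisfy the subgradient
  # conditions of the soft-threshold box problem coordinate-wise
  set.seed(25)
  for (kern in c("linear", "rbf")) {
    n <- 25; v <- 40
    X <- matrix(rbinom(n * v, 1, 0.3), n, v)
    y <- as.numeric(scale(X[, 5] * 2 + rnorm(n)))
    cfg <- analysis_config(svr_kernel = kern)
    K <- strokemap:::.svr_kernel(X, kern, cfg$svr_gamma)
    a <- strokemap:::esvr_fit_multi(K, matrix(y, ncol = 1), cfg$svr_cost,
                                    cfg$svr_epsilon)[, 1]
    g <- as.numeric(K %*% a - y)
    eps <- cfg$svr_epsilon; C <- cfg$svr_cost
    viol <- vapply(seq_len(n), function(i) {
      if (a[i] > 1e-9 && a[i] < C - 1e-6) abs(g[i] + eps)
      else if (a[i] < -1e-9 && a[i] > -C + 1e-6) abs(g[i] - eps)
      else if (abs(a[i]) <= 1e-9) max(0, abs(g[i]) - eps)
      else if (a[i] >= C - 1e-6) max(0, -(g[i] + eps))
      else max(0, g[i] - eps)
    }, 0)
    expect_lt(max(viol), 1e-6)
  }
})

test_that("label_clusters honors connectivity semantics", {
  g <- array(0L, c(10, 10, 10))
  g[2:3, 2:3, 2] <- 1L                     # 4 voxels... size-4 blob
  g[2, 2, 2] <- 1L
  g[7:8, 7:8, 7] <- 1L; g[7, 7, 8] <- 1L   # 5-voxel blob, far away
  cl <- label_clusters(g, 26L, voxel_volume_ml = 0.008)
  expect_equal(sort(vapply(cl, function(c) c$size_vox, 0L)), c(4L, 5L))
  expect_equal(cl[[1]]$size_ml, cl[[1]]$size_vox * 0.008)
  expect_length(label_clusters(array(0L, c(4, 4, 4))), 0)
  # corner contact: one cluster under 26, two under 6
  g2 <- array(0L, c(4, 4, 4))
  g2[1, 1, 1] <- 1L; g2[2, 2, 2] <- 1L
  expect_length(label_clusters(g2, 26L), 1)
  expect_length(label_clusters(g2, 6L), 2)
})

test_that("permutation inference obeys p bounds, containment and reordering", {
  set.seed(23)
  n <- 16; v <- 40
  X <- matrix(rbinom(n * v, 1, 0.4), n, v)
  y <- rnorm(n)
  fm <- list(X = X, vox_idx = seq_len(v), dims = c(v, 1L, 1L), affine = diag(4))
  cfg <- analysis_config(n_permutations = 60L, svr_kernel = "linear",
                         rng_seed = 11L)
  expect_message(res <- permutation_cluster_inference(fm, y, cfg), "coarse")
  P <- cfg$n_permutations
  pm <- res$voxel_p_map$grid[fm$vox_idx]
  expect_true(all(pm >= 1 / (P + 1) - 1e-12 & pm <= 1))
  for (cl in res$clusters) {
    expect_true(cl$p_fwe >= 1 / (P + 1) - 1e-12 && cl$p_fwe <= 1)
    # every cluster voxel survives the voxel threshold
    expect_true(all(res$voxel_p_map$grid[cl$voxels] < cfg$svr_voxel_p))
  }
  # beta map invariant under patient reordering
  ord <- sample(n)
  fmo <- fm; fmo$X <- X[ord, ]
  reso <- suppressMessages(permutation_cluster_inference(fmo, y[ord], cfg))
  expect_equal(reso$beta_map$grid, res$beta_map$grid, tolerance = 1e-6)
  # bitwise reproducible for a fixed seed
  res2 <- suppressMessages(permutation_cluster_inference(fm, y, cfg))
  expect_identical(res2$voxel_p_map$grid, res$voxel_p_map$grid)
  expect_identical(res2$perm_max_sizes, res$perm_max_sizes)
})

test_that("prediction performance equals the correlation oracle", {
  set.seed(24)
  n <- 10; v <- 12
  X <- matrix(rbinom(n * v, 1, 0.5), n, v)
  y <- rnorm(n)
  fm <- list(X = X, vox_idx = seq_len(v), dims = c(v, 1L, 1L), affine = diag(4))
  cfg <- analysis_config(n_permutations = 50L, svr_kernel = "linear",
                         rng_seed = 2L)
  pp <- prediction_performance(fm, y, cfg)
  # independent oracle: refit the dual by generic box-constrained QP on
  # the same objective, then plain Pearson formula
  K <- X %*% t(X)
  ys <- as.numeric(scale(y))
  a <- strokemap:::esvr_fit_multi(K, matrix(ys, ncol = 1), cfg$svr_cost,
                                  cfg$svr_epsilon)[, 1]
  f <- K %*% a
  r_oracle <- sum((f - mean(f)) * (ys - mean(ys))) /
    sqrt(sum((f - mean(f))^2) * sum((ys - mean(ys))^2))
  expect_equal(pp$r, r_oracle, tolerance = 1e-12)
  expect_true(pp$p >= 1 / 51 && pp$p <= 1)
  expect_length(pp$null_r, 50)
})

test_that("svr_lsm wires exclusions and volume control end to end", {
  tr <- tiny_truth(effect_size = 0)
  cc <- expect_silent_log(generate_lesion_cohort(24, tr, seed = 31))
  cfg <- analysis_config(n_permutations = 40L, svr_kernel = "linear",
                         rng_seed = 4L)
  res <- suppressMessages(svr_lsm(cc$masks, cc$cohort, cfg))
  expect_s3_class(res, "svr_result")
  expect_equal(res$n_input, 24)
  expect_equal(res$n_analyzed + nrow(res$exclusions), 24)
  # covariate variant runs and changes the behavior actually fit
  resc <- suppressMessages(svr_lsm(cc$masks, cc$cohort, cfg,
                                   covariates = c("age", "nihss")))
  expect_s3_class(resc, "svr_result")
  expect_error(suppressMessages(svr_lsm(cc$masks, cc$cohort, cfg,
                                        covariates = "bogus")), "covariates")
})
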