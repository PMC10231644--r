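# Synthetic cohort generator: blob lesions with a planted region -> score
# effect, low-rank community-structured normative time series, and
# bundle-shaped streamline sets. All generators are pure functions of
# (parameters, seed).

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.vox_grid_coords <- function(dims) {
  list(x = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dims),
       y = array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]), dims),
       z = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims))
}

#' Ground truth for a synthetic lesion-mapping world
#'
#' Defines the fixed world all generators draw from: an ellipsoidal brain
#' mask on a 24 x 24 x 24 grid of nominal 2 mm voxels, a compact critical
#' region whose damage raises the HADS-D score, a vascular "territory"
#' toward which lesion seeds are biased, radially organized tissue
#' probability maps, a partition of gray matter into functional
#' communities, and three synthetic fiber bundles.
#'
#' Score model defaults follow the cohort the pipelines target: baseline
#' HADS-D 4.4 with residual SD 3.7, plus `effect_size` points per unit
#' fractional damage of the critical region.
#'
#' @param grid_shape 3-vector of grid dimensions
#' @param voxel_mm isotropic voxel size (mm)
#' @param effect_size points of HADS-D per unit damage fraction
#' @param noise_sd residual score standard deviation
#' @param base_score baseline HADS-D
#' @param n_communities number of functional communities in gray matter
#' @param bundle_spread streamline jitter SD in voxels
#' @return an object of class `ground_truth`
#' @export
default_ground_truth <- function(grid_shape = c(24L, 24L, 24L), voxel_mm = 2,
                                 effect_size = 10, noise_sd = 3.7,
                                 base_score = 4.4, n_communities = 4L,
                                 bundle_spread = 0.6) {
  d <- as.integer(grid_shape)
  stopifnot(length(d) == 3, all(d >= 8))
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- -voxel_mm * (d - 1) / 2
  co <- .vox_grid_coords(d)
  ctr <- (d + 1) / 2
  rx <- (co$x - ctr[1]) / (0.92 * d[1] / 2)
  ry <- (co$y - ctr[2]) / (0.92 * d[2] / 2)
  rz <- (co$z - ctr[3]) / (0.92 * d[3] / 2)
  r <- sqrt(rx^2 + ry^2 + rz^2)
  brain <- array(as.integer(r <= 1), d)
  # tissue probabilities organized radially: WM core, GM shell, CSF rim
  wm <- exp(-(r / 0.45)^2)
  gm <- exp(-((r - 0.68) / 0.20)^2)
  csf <- pmax((r - 0.82) / 0.18, 0)      # first arg keeps the array dim
  wm[brain == 0] <- 0; gm[brain == 0] <- 0; csf[brain == 0] <- 0
  csf <- pmin(csf, 1)
  # critical region: compact cube in the right-lateral gray/white boundary
  cx <- round(d[1] * 0.68); cy <- round(d[2] * 0.5); cz <- round(d[3] * 0.5)
  critical <- array(0L, d)
  critical[(cx - 2):(cx + 2), (cy - 2):(cy + 2), (cz - 2):(cz + 2)] <- 1L
  critical <- critical * brain
  # vascular territory: lesion seeds cluster around its center with a
  # Gaussian falloff (single dominant arterial territory, like an MCA
  # stroke cohort), with a small uniform floor for distal lesions
  territory <- array(0L, d)
  territory[max(1, cx - 6):min(d[1], cx + 5),
            max(1, cy - 6):min(d[2], cy + 6),
            max(1, cz - 6):min(d[3], cz + 6)] <- 1L
  territory <- territory * brain
  dist2 <- (co$x - cx)^2 + (co$y - cy)^2 + (co$z - cz)^2
  seed_weight <- (exp(-dist2 / (2 * 4.5^2)) + 0.01) * brain
  # functional communities: quadrants of the x-y plane within gray matter
  gmvox <- gm >= 0.10 & brain == 1
  comm <- array(0L, d)
  qx <- co$x > ctr[1]; qy <- co$y > ctr[2]
  comm[gmvox] <- (1L + as.integer(qx) + 2L * as.integer(qy))[gmvox]
  if (n_communities != 4L)
    comm[gmvox] <- 1L + (comm[gmvox] - 1L) %% as.integer(n_communities)
  # synthetic bundles in world mm: one through the critical region,
  # one contralateral, one oblique
  vox2world <- function(v) as.numeric(affine %*% c(v - 1, 1))[1:3]
  bundles <- list(
    list(a = vox2world(c(cx, 4, cz)), b = vox2world(c(cx, d[2] - 3, cz)),
         spread = bundle_spread),
    list(a = vox2world(c(round(d[1] * 0.32), 4, cz)),
         b = vox2world(c(round(d[1] * 0.32), d[2] - 3, cz)),
         spread = bundle_spread),
    list(a = vox2world(c(5, cy, round(d[3] * 0.35))),
         b = vox2world(c(d[1] - 4, cy, round(d[3] * 0.62))),
         spread = bundle_spread))
  structure(list(grid_shape = d, voxel_mm = voxel_mm, affine = affine,
                 brain_mask = brain, critical_region = critical,
                 territory = territory, seed_weight = seed_weight,
                 gm_prob = gm, wm_prob = wm,
                 csf_prob = csf, network_modules = comm,
                 n_communities = as.integer(n_communities),
                 bundle_specs = bundles, effect_size = effect_size,
                 noise_sd = noise_sd, base_score = base_score),
            class = "ground_truth")
}

.neigh6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

.grow_blob <- function(seed_vox, target_n, allowed, dims) {
  # random-walk dilation: repeatedly add a free 6-neighbor of a random
  # member voxel; connected by construction
  set <- matrix(seed_vox, nrow = 1)
  in_set <- array(FALSE, dims)
  in_set[seed_vox[1], seed_vox[2], seed_vox[3]] <- TRUE
  stalls <- 0
  while (nrow(set) < target_n && stalls < 200) {
    i <- sample.int(nrow(set), 1)
    nb <- set[i, ] + .neigh6[sample.int(6, 1), ]
    if (any(nb < 1) || any(nb > dims)) { stalls <- stalls + 1; next }
    if (!allowed[nb[1], nb[2], nb[3]] || in_set[nb[1], nb[2], nb[3]]) {
      stalls <- stalls + 1; next
    }
    set <- rbind(set, nb)
    in_set[nb[1], nb[2], nb[3]] <- TRUE
    stalls <- 0
  }
  in_set
}

#' Generate a synthetic lesion cohort with a planted effect
#'
#' Lesions are connected random blobs (random-walk dilation from a seed
#' voxel biased toward the vascular territory, log-normal target volume).
#' The HADS-D score of patient i is
#' `round(clip(base + effect_size * overlap_frac_i + N(0, noise_sd), 0, 21))`
#' where `overlap_frac` is the damaged fraction of the critical region.
#'
#' @param n_patients cohort size (>= 2)
#' @param truth a [default_ground_truth()] world
#' @param seed RNG seed; identical seeds give identical cohorts
#' @param mean_lesion_vox,sdlog_lesion log-normal lesion-size parameters
#' @return list with `masks` (list of [lesion_mask()]) and `cohort`
#'   (a [cohort_table()] including age/sex/nihss/barthel covariates and
#'   the true `overlap_frac`)
#' @export
generate_lesion_cohort <- function(n_patients, truth, seed = 1L,
                                   mean_lesion_vox = 110, sdlog_lesion = 0.6) {
  stopifnot(n_patients >= 2)
  d <- truth$grid_shape
  if (truth$effect_size > 0 && sum(truth$critical_region) == 0)
    stop("effect region empty while effect_size > 0")
  if (prod(d) < 20 * mean_lesion_vox)
    stop("degenerate grid: volume not large relative to mean lesion volume")
  .with_seed(seed, {
    w <- as.vector(truth$seed_weight)
    idx_all <- which(w > 0)
    ncrit <- max(1L, sum(truth$critical_region))
    masks <- vector("list", n_patients)
    overlap <- numeric(n_patients)
    vols <- pmin(pmax(round(stats::rlnorm(n_patients, log(mean_lesion_vox),
                                          sdlog_lesion)), 8), 500)
    for (i in seq_len(n_patients)) {
      lin <- sample(idx_all, 1, prob = w[idx_all])
      sv <- c(arrayInd(lin, d))
      g <- .grow_blob(sv, vols[i], truth$brain_mask == 1, d)
      masks[[i]] <- lesion_mask(array(as.integer(g), d), truth$affine,
                                sprintf("sub-%03d", i))
      overlap[i] <- sum(g & truth$critical_region == 1) / ncrit
    }
    score <- truth$base_score + truth$effect_size * overlap +
      stats::rnorm(n_patients, 0, truth$noise_sd)
    score <- as.integer(round(pmin(pmax(score, 0), 21)))
    df <- data.frame(
      patient_id = vapply(masks, function(m) m$patient_id, ""),
      hads_d = score,
      age = round(pmin(pmax(stats::rnorm(n_patients, 68, 12), 25), 90)),
      sex = stats::rbinom(n_patients, 1, 0.45),
      nihss = pmin(stats::rpois(n_patients, 4), 30),
      barthel = 5 * round(pmin(pmax(stats::rnorm(n_patients, 85, 15), 0), 100) / 5),
      overlap_frac = overlap)
    list(masks = masks, cohort = cohort_table(df, cutoff = 10L))
  })
}

#' Generate normative resting-state runs
#'
#' Each voxel's series is a shared band-limited community signal plus
#' voxel noise, so within-community correlation exceeds between-community
#' correlation in expectation. Runs carry synthetic 6-column motion
#' parameters (slow random walk plus optional injected high-motion step
#' frames) and the world's WM/CSF/GM probability maps.
#'
#' @param n_subjects,n_runs,n_timepoints design; `n_timepoints` must be > 20
#' @param tr_s repetition time in seconds
#' @param truth a [default_ground_truth()]
#' @param seed RNG seed
#' @param community_weight fraction of gray-matter voxel variance carried
#'   by the community signal
#' @param n_high_motion_frames frames per run given a 1 step displacement
#' @param high_motion_mm displacement of injected frames (mm)
#' @return list of `normative_run` objects
#' @export
generate_normative_timeseries <- function(n_subjects = 8L, n_runs = 2L,
                                          n_timepoints = 120L, tr_s = 0.72,
                                          truth = default_ground_truth(),
                                          seed = 1L, community_weight = 0.6,
                                          n_high_motion_frames = 0L,
                                          high_motion_mm = 1.0) {
  stopifnot(n_timepoints > 20)
  d <- truth$grid_shape
  fs <- 1 / tr_s
  bp <- butter_bandpass(0.01, 0.08, fs, order = 2)
  nvox <- prod(d)
  comm <- as.vector(truth$network_modules)
  K <- max(comm)
  run_labels <- c("RL", "LR")[(seq_len(n_runs) - 1) %% 2 + 1]
  .with_seed(seed, {
    runs <- list()
    for (s in seq_len(n_subjects)) {
      for (rn in seq_len(n_runs)) {
        sig <- matrix(stats::rnorm(n_timepoints * K), n_timepoints, K)
        sig <- filtfilt_sm(bp$b, bp$a, sig)
        sig <- scale(sig)                      # unit-variance community signals
        noise <- matrix(stats::rnorm(n_timepoints * nvox, 0, 1),
                        n_timepoints, nvox)
        dat <- noise
        ing <- comm > 0
        dat[, ing] <- sqrt(community_weight) * sig[, comm[ing]] +
          sqrt(1 - community_weight) * noise[, ing]
        dat <- 1000 + 10 * dat                 # arbitrary BOLD-like offset
        # slow drift: translations in mm, rotations in rad (x50 mm in FD)
        motion <- apply(cbind(matrix(stats::rnorm(n_timepoints * 3, 0, 0.02),
                                     n_timepoints, 3),
                              matrix(stats::rnorm(n_timepoints * 3, 0, 2e-4),
                                     n_timepoints, 3)), 2, cumsum)
        if (n_high_motion_frames > 0) {
          at <- round(seq(6, n_timepoints - 5,
                          length.out = n_high_motion_frames))
          for (j in seq_along(at))               # sustained step: one FD spike each
            motion[at[j]:n_timepoints, 1] <-
              motion[at[j]:n_timepoints, 1] + high_motion_mm * (-1)^j
        }
        runs[[length(runs) + 1]] <- structure(
          list(subject_id = sprintf("norm-%02d", s), run_id = run_labels[rn],
               data = array(t(dat), dim = c(d, n_timepoints)), tr_s = tr_s,
               motion = motion, gm_prob = truth$gm_prob,
               wm_prob = truth$wm_prob, csf_prob = truth$csf_prob,
               affine = truth$affine),
          class = "normative_run")
      }
    }
    runs
  })
}

#' Generate normative tractograms
#'
#' Each bundle is a set of polylines jittered around its endpoint-to-
#' endpoint path: a Gaussian lateral offset per streamline plus a smooth
#' sinusoidal bend, both scaled by the bundle's `spread` (in voxels).
#' With `spread = 0` every subject produces the identical voxel path.
#'
#' @param n_subjects number of normative subjects
#' @param truth a [default_ground_truth()] (supplies `bundle_specs`)
#' @param streamlines_per_bundle polylines per bundle per subject
#' @param seed RNG seed
#' @return list of tractograms: `list(subject_id, streamlines)` with each
#'   streamline an n x 3 matrix of world-mm points
#' @export
generate_normative_tractograms <- function(n_subjects = 8L,
                                           truth = default_ground_truth(),
                                           streamlines_per_bundle = 40L,
                                           seed = 1L) {
  if (!length(truth$bundle_specs)) stop("bundle_specs is empty")
  vox_mm <- truth$voxel_mm
  d <- truth$grid_shape
  world_lo <- as.numeric(truth$affine %*% c(-0.49, -0.49, -0.49, 1))[1:3]
  world_hi <- as.numeric(truth$affine %*% c(d - 1 + 0.49, 1))[1:3]
  for (b in truth$bundle_specs)
    if (any(b$a < world_lo - 1e-9) || any(b$a > world_hi + 1e-9) ||
        any(b$b < world_lo - 1e-9) || any(b$b > world_hi + 1e-9))
      stop("bundle endpoints outside grid")
  .with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      streamlines <- list()
      for (bi in seq_along(truth$bundle_specs)) {
        spec <- truth$bundle_specs[[bi]]
        len <- sqrt(sum((spec$b - spec$a)^2))
        npts <- max(3L, ceiling(len / (vox_mm / 2)) + 1L)
        tpar <- seq(0, 1, length.out = npts)
        base <- outer(1 - tpar, spec$a) + outer(tpar, spec$b)
        dirv <- (spec$b - spec$a) / len
        perp1 <- if (abs(dirv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        perp1 <- perp1 - sum(perp1 * dirv) * dirv
        perp1 <- perp1 / sqrt(sum(perp1^2))
        perp2 <- c(dirv[2] * perp1[3] - dirv[3] * perp1[2],
                   dirv[3] * perp1[1] - dirv[1] * perp1[3],
                   dirv[1] * perp1[2] - dirv[2] * perp1[1])
        for (k in seq_len(streamlines_per_bundle)) {
          off <- stats::rnorm(2, 0, spec$spread * vox_mm)
          bend <- stats::rnorm(2, 0, 0.4 * spec$spread * vox_mm)
          phase <- stats::runif(1, 0, 2 * pi)
          lat1 <- off[1] + bend[1] * sin(pi * tpar + phase)
          lat2 <- off[2] + bend[2] * sin(pi * tpar + phase)
          pts <- base + outer(lat1, perp1) + outer(lat2, perp2)
          pts <- pmin(pmax(pts, matrix(world_lo, npts, 3, byrow = TRUE)),
                      matrix(world_hi, npts, 3, byrow = TRUE))
          streamlines[[length(streamlines) + 1]] <- pts
        }
      }
      structure(list(subject_id = sprintf("tract-%02d", s),
                     streamlines = streamlines),
                class = "tractogram")
    })
  })
}

#' Write a tractogram in the plain-text point-list format
#'
#' Format: a header line `# strokemap tractogram v1`, a `subject <id>`
#' line, then per streamline a `streamline <n_points>` line followed by
#' `n_points` lines of `x y z` world-mm coordinates.
#'
#' @param tract a tractogram object
#' @param path output text file
#' @export
write_tractogram <- function(tract, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# strokemap tractogram v1",
               paste("subject", tract$subject_id)), con)
  for (s in tract$streamlines) {
    writeLines(paste("streamline", nrow(s)), con)
    writeLines(sprintf("%.4f %.4f %.4f", s[, 1], s[, 2], s[, 3]), con)
  }
  invisible(path)
}

#' Read a tractogram from the plain-text point-list format
#' @param path file written by [write_tractogram()]
#' @return a tractogram object
#' @export
read_tractogram <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  subject_id <- sub("^subject\\s+", "", lines[1])
  i <- 2
  streamlines <- list()
  while (i <= length(lines)) {
    if (!grepl("^streamline\\s", lines[i])) stop("malformed tractogram at line ", i)
    n <- as.integer(sub("^streamline\\s+", "", lines[i]))
    if (n < 2) stop("streamline with < 2 points")
    block <- lines[(i + 1):(i + n)]
    pts <- matrix(as.numeric(unlist(strsplit(block, "\\s+"))), ncol = 3,
                  byrow = TRUE)
    if (any(!is.finite(pts))) stop("non-finite streamline point")
    streamlines[[length(streamlines) + 1]] <- pts
    i <- i + n + 1
  }
  structure(list(subject_id = subject_id, streamlines = streamlines),
            class = "tractogram")
}

#' Materialize a complete synthetic dataset directory
#'
#' Writes the directory layout every pipeline entry point consumes:
#' `masks/` (per-patient lesion NIfTIs), `cohort.csv`, `tissue/`
#' (GM/WM/CSF probability maps), `connectome/` (4-D runs + motion TSVs),
#' `tractograms/` (point-list files), `truth/` (critical region, for
#' evaluation only) and `config.json`.
#'
#' @param dir output directory (created)
#' @param truth a [default_ground_truth()]
#' @param n_patients,n_subjects,n_timepoints design sizes
#' @param seed RNG seed (sub-seeds are derived per generator)
#' @param config an [analysis_config()] echoed into the dataset
#' @return `dir`, invisibly
#' @export
simulate_dataset <- function(dir, truth = default_ground_truth(),
                             n_patients = 60L, n_subjects = 8L,
                             n_timepoints = 120L, seed = 1L,
                             config = analysis_config(rng_seed = seed)) {
  for (sub in c("", "masks", "tissue", "connectome", "tractograms", "truth"))
    dir.create(file.path(dir, sub), showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_lesion_cohort(n_patients, truth, seed = seed)
  for (m in cohort$masks)
    write_mask_volume(m, file.path(dir, "masks", paste0(m$patient_id, ".nii.gz")))
  utils::write.csv(as.data.frame(cohort$cohort)[
    , c("patient_id", "hads_d", "age", "sex", "nihss", "barthel")],
    file.path(dir, "cohort.csv"), row.names = FALSE)
  for (tn in c("gm", "wm", "csf"))
    write_nifti(truth[[paste0(tn, "_prob")]], truth$affine,
                file.path(dir, "tissue", paste0(tn, "_prob.nii.gz")),
                datatype = "float32", descrip = "kind=prob")
  runs <- generate_normative_timeseries(n_subjects, 2L, n_timepoints,
                                        truth = truth, seed = seed + 1000L)
  for (r in runs) {
    stem <- file.path(dir, "connectome", paste0(r$subject_id, "_run-", r$run_id))
    write_nifti(r$data, truth$affine, paste0(stem, "_bold.nii.gz"),
                datatype = "float32")
    utils::write.table(r$motion, paste0(stem, "_motion.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  tracts <- generate_normative_tractograms(n_subjects, truth,
                                           seed = seed + 2000L)
  for (tr in tracts)
    write_tractogram(tr, file.path(dir, "tractograms",
                                   paste0(tr$subject_id, ".txt")))
  write_nifti(truth$critical_region, truth$affine,
              file.path(dir, "truth", "critical_region.nii.gz"),
              datatype = "uint8")
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
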