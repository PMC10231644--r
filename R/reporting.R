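# Atlas-overlap summaries, cluster tables, dataset loading and end-to-end
# pipeline orchestration.

#' Atlas overlap report for a cluster
#'
#' Per atlas label, the percentage of cluster voxels carrying that label,
#' sorted descending, plus the unlabeled remainder. Fractions sum to 100.
#'
#' @param cluster_voxels 1-based linear voxel indices of the cluster
#' @param atlas integer-labeled array or `stat_map` (0 = unlabeled)
#' @param label_names optional data.frame with columns `label`, `name`
#' @return data.frame of class `overlap_report`: `label`, `name`,
#'   `n_voxels`, `percent`
#' @export
atlas_overlap <- function(cluster_voxels, atlas, label_names = NULL) {
  if (!length(cluster_voxels)) stop("empty cluster")
  lab <- if (inherits(atlas, "stat_map")) atlas$grid else atlas
  vals <- as.integer(as.vector(lab)[cluster_voxels])
  tab <- table(vals)
  df <- data.frame(label = as.integer(names(tab)),
                   n_voxels = as.integer(tab))
  df$percent <- 100 * df$n_voxels / length(cluster_voxels)
  df$name <- ifelse(df$label == 0L, "unlabeled",
                    paste0("label_", df$label))
  if (!is.null(label_names)) {
    hit <- match(df$label, label_names$label)
    df$name[!is.na(hit)] <- label_names$name[hit[!is.na(hit)]]
  }
  df <- df[order(df$label == 0L, -df$percent), c("label", "name", "n_voxels",
                                                 "percent")]
  rownames(df) <- NULL
  class(df) <- c("overlap_report", "data.frame")
  df
}

#' Cluster table as a data.frame
#'
#' @param result an `svr_result` or `lnsm_result`
#' @return data.frame: cluster id, size in voxels and ml, p_fwe,
#'   significance flag, peak voxel indices
#' @export
cluster_table <- function(result) {
  cl <- result$clusters
  if (!length(cl))
    return(data.frame(cluster_id = integer(0), size_vox = integer(0),
                      size_ml = numeric(0), p_fwe = numeric(0),
                      significant = logical(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0)))
  data.frame(
    cluster_id = seq_along(cl),
    size_vox = vapply(cl, function(c) c$size_vox, 0L),
    size_ml = vapply(cl, function(c) c$size_ml, 0),
    p_fwe = vapply(cl, function(c) c$p_fwe, 0),
    significant = vapply(cl, function(c) isTRUE(c$significant), TRUE),
    peak_x = vapply(cl, function(c) c$peak_voxel[1], 0L),
    peak_y = vapply(cl, function(c) c$peak_voxel[2], 0L),
    peak_z = vapply(cl, function(c) c$peak_voxel[3], 0L))
}

#' Read a normative run from a dataset directory
#'
#' @param stem path prefix: `<stem>_bold.nii.gz` and `<stem>_motion.tsv`
#'   must exist
#' @param tissue list with `gm`, `wm`, `csf` probability arrays
#' @param tr_s repetition time
#' @return a `normative_run`
#' @export
read_normative_run <- function(stem, tissue, tr_s = 0.72) {
  nii <- read_nifti(paste0(stem, "_bold.nii.gz"))
  motion <- as.matrix(utils::read.table(paste0(stem, "_motion.tsv"), sep = "\t"))
  base <- basename(stem)
  structure(list(
    subject_id = sub("_run-.*$", "", base),
    run_id = sub("^.*_run-", "", base),
    data = nii$img, tr_s = tr_s, motion = motion,
    gm_prob = tissue$gm, wm_prob = tissue$wm, csf_prob = tissue$csf,
    affine = nii$affine), class = "normative_run")
}

#' Load a dataset directory produced by [simulate_dataset()]
#'
#' @param dir dataset root
#' @param cutoff HADS-D cutoff for the cohort table
#' @param load_runs,load_tractograms toggle the heavier components
#' @return list: `masks`, `cohort`, `tissue`, `runs`, `tractograms`,
#'   `affine`, `truth_critical` (if shipped)
#' @export
read_dataset <- function(dir, cutoff = 10L, load_runs = TRUE,
                         load_tractograms = TRUE) {
  cpath <- file.path(dir, "cohort.csv")
  if (!file.exists(cpath)) stop("missing cohort file: ", cpath)
  cohort <- read_cohort_table(cpath, cutoff = cutoff)
  mask_files <- sort(list.files(file.path(dir, "masks"),
                                pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (!length(mask_files)) stop("no lesion masks in ", file.path(dir, "masks"))
  masks <- lapply(mask_files, read_mask_volume)
  tissue <- NULL
  tdir <- file.path(dir, "tissue")
  if (dir.exists(tdir)) {
    tissue <- list(gm = read_nifti(file.path(tdir, "gm_prob.nii.gz"))$img,
                   wm = read_nifti(file.path(tdir, "wm_prob.nii.gz"))$img,
                   csf = read_nifti(file.path(tdir, "csf_prob.nii.gz"))$img)
  }
  runs <- NULL
  cdir <- file.path(dir, "connectome")
  if (load_runs && dir.exists(cdir) && !is.null(tissue)) {
    stems <- sub("_bold\\.nii\\.gz$", "",
                 sort(list.files(cdir, pattern = "_bold\\.nii\\.gz$",
                                 full.names = TRUE)))
    runs <- lapply(stems, read_normative_run, tissue = tissue)
  }
  tracts <- NULL
  trdir <- file.path(dir, "tractograms")
  if (load_tractograms && dir.exists(trdir)) {
    tracts <- lapply(sort(list.files(trdir, pattern = "\\.txt$",
                                     full.names = TRUE)), read_tractogram)
  }
  crit <- NULL
  cf <- file.path(dir, "truth", "critical_region.nii.gz")
  if (file.exists(cf)) crit <- read_nifti(cf)$img
  list(masks = masks, cohort = cohort, tissue = tissue, runs = runs,
       tractograms = tracts, affine = masks[[1]]$affine,
       truth_critical = crit)
}

.mask_centroid_world <- function(grid, affine) {
  idx <- arrayInd(which(as.vector(grid) != 0), dim(grid)) - 1L
  as.numeric(affine %*% c(colMeans(idx), 1))[1:3]
}

#' Run the full pipeline on a dataset directory
#'
#' Executes the requested stages in dependency order with a shared
#' exclusion log and writes a JSON + CSV + NIfTI bundle plus a markdown
#' summary to `out_dir`. Reruns with the same config and seed are
#' numerically identical.
#'
#' @param config an [analysis_config()]
#' @param dataset_dir directory laid out as by [simulate_dataset()]
#' @param which one of `svr-lsm`, `svr-sdsm`, `lnsm`, `nds`, `all`
#' @param out_dir output directory (created)
#' @param covariates optional covariate columns for the SVR stages
#' @param nds_center_world circuit sphere center (world mm); defaults to
#'   the shipped ground-truth critical-region centroid when available
#' @return named list of stage results, invisibly
#' @export
run_pipeline <- function(config, dataset_dir,
                         which = c("all", "svr-lsm", "svr-sdsm", "lnsm", "nds"),
                         out_dir = file.path(dataset_dir, "results"),
                         covariates = NULL, nds_center_world = NULL) {
  which <- match.arg(which)
  stages <- if (which == "all") c("svr-lsm", "svr-sdsm", "lnsm", "nds") else which
  need_runs <- any(stages %in% c("lnsm", "nds"))
  need_tracts <- "svr-sdsm" %in% stages
  ds <- read_dataset(dataset_dir, cutoff = config$hads_cutoffs[1],
                     load_runs = need_runs, load_tractograms = need_tracts)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  exclusions <- list()
  cleaned <- NULL
  summary <- list(config = unclass(config), stages = list())
  for (stage in stages) {
    .sm_log("stage ", stage, " starting")
    if (stage == "svr-lsm") {
      res <- svr_lsm(ds$masks, ds$cohort, config, covariates = covariates)
      write_stat_volume(res$beta_map, file.path(out_dir, "svr_lsm_beta.nii.gz"), config)
      write_stat_volume(res$z_map, file.path(out_dir, "svr_lsm_z.nii.gz"), config)
      write_stat_volume(res$voxel_p_map, file.path(out_dir, "svr_lsm_p.nii.gz"), config)
      utils::write.csv(cluster_table(res),
                       file.path(out_dir, "svr_lsm_clusters.csv"), row.names = FALSE)
      summary$stages[["svr_lsm"]] <- list(
        n_input = res$n_input, n_analyzed = res$n_analyzed,
        prediction_r = res$prediction_r, prediction_p = res$prediction_p,
        n_significant_clusters = sum(cluster_table(res)$significant))
      exclusions[["svr-lsm"]] <- res$exclusions
    } else if (stage == "svr-sdsm") {
      dmaps <- disconnectome_maps(ds$masks, ds$tractograms, config)
      vols <- vapply(ds$masks, lesion_volume_ml, numeric(1))
      res <- svr_lsm(dmaps, ds$cohort, config, covariates = covariates,
                     volumes = vols)
      write_stat_volume(res$z_map, file.path(out_dir, "svr_sdsm_z.nii.gz"), config)
      utils::write.csv(cluster_table(res),
                       file.path(out_dir, "svr_sdsm_clusters.csv"), row.names = FALSE)
      summary$stages[["svr_sdsm"]] <- list(
        n_input = res$n_input, n_analyzed = res$n_analyzed,
        prediction_r = res$prediction_r, prediction_p = res$prediction_p,
        n_significant_clusters = sum(cluster_table(res)$significant))
      exclusions[["svr-sdsm"]] <- res$exclusions
    } else if (stage == "lnsm") {
      if (is.null(cleaned)) cleaned <- lapply(ds$runs, preprocess_run, config = config)
      res <- lnsm(ds$masks, ds$cohort, cleaned, config, gm_prob = ds$tissue$gm)
      write_stat_volume(res$t_map, file.path(out_dir, "lnsm_t.nii.gz"), config)
      utils::write.csv(cluster_table(res),
                       file.path(out_dir, "lnsm_clusters.csv"), row.names = FALSE)
      summary$stages[["lnsm"]] <- list(
        n_input = res$n_input, n_analyzed = res$n_analyzed,
        n_significant_clusters = sum(cluster_table(res)$significant))
      exclusions[["lnsm"]] <- res$exclusions
    } else if (stage == "nds") {
      if (is.null(cleaned)) cleaned <- lapply(ds$runs, preprocess_run, config = config)
      center <- nds_center_world
      if (is.null(center)) {
        if (is.null(ds$truth_critical))
          stop("nds stage needs nds_center_world (no ground truth shipped)")
        center <- .mask_centroid_world(ds$truth_critical, ds$affine)
      }
      circuit <- circuit_tmap(cleaned, center, config$sphere_diameter_mm, config)
      write_stat_volume(circuit$tmap, file.path(out_dir, "circuit_t.nii.gz"), config)
      res <- nds_analysis(ds$masks, ds$cohort, circuit,
                          cutoff = config$hads_cutoffs[1],
                          n_perm = min(config$n_permutations * 10L, 1e6L),
                          seed = config$rng_seed)
      utils::write.csv(res$scores, file.path(out_dir, "nds_scores.csv"),
                       row.names = FALSE)
      summary$stages[["nds"]] <- list(
        n_analyzed = nrow(res$scores), statistic = res$test$statistic,
        p = res$test$p, exhaustive = res$test$exhaustive)
      exclusions[["nds"]] <- data.frame(patient_id = character(0),
                                        exclusion_reason = character(0))
    }
    results[[stage]] <- res
  }
  excl <- do.call(rbind, lapply(names(exclusions), function(s) {
    e <- exclusions[[s]]
    if (nrow(e)) cbind(stage = s, e) else NULL
  }))
  if (is.null(excl))
    excl <- data.frame(stage = character(0), patient_id = character(0),
                       exclusion_reason = character(0))
  utils::write.csv(excl, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# strokemap pipeline report", "",
          sprintf("- seed: %d", config$rng_seed),
          sprintf("- permutations: %d", config$n_permutations),
          sprintf("- voxel thresholds: SVR p < %g (one-tailed), LNSM p < %g (two-tailed)",
                  config$svr_voxel_p, config$lnsm_voxel_p),
          sprintf("- cluster FWE alpha: %g", config$cluster_fwe_alpha),
          "")
  for (s in names(summary$stages)) {
    md <- c(md, sprintf("## %s", s),
            vapply(names(summary$stages[[s]]), function(k)
              sprintf("- %s: %s", k, format(summary$stages[[s]][[k]])), ""),
            "")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `svr-lsm`, `svr-sdsm`, `lnsm`, `nds`, `all`.
#' `simulate` takes `--out DIR [--n-patients N --n-subjects N --seed S]`;
#' the analysis subcommands take `--data DIR [--out DIR --config FILE
#' --perms N --seed S --covariates a,b,c]`.
#'
#' @param args character vector of CLI arguments
#' @return exit code: 0 ok, 1 analysis error, 2 input error
#' @export
strokemap_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: strokemap <simulate|svr-lsm|svr-sdsm|lnsm|nds|all> [options]\n")
    2L
  }
  if (!length(args)) return(usage())
  cmd <- args[1]
  opt <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (i + 1 > length(rest)) return(usage())
    opt[[key]] <- rest[i + 1]
    i <- i + 2
  }
  seed <- as.integer(opt$seed %||% 1L)
  tryCatch({
    if (cmd == "simulate") {
      if (is.null(opt$out)) return(usage())
      simulate_dataset(opt$out,
                       n_patients = as.integer(opt[["n-patients"]] %||% 60L),
                       n_subjects = as.integer(opt[["n-subjects"]] %||% 8L),
                       seed = seed)
      return(0L)
    }
    if (!cmd %in% c("svr-lsm", "svr-sdsm", "lnsm", "nds", "all")) return(usage())
    if (is.null(opt$data) || !dir.exists(opt$data)) {
      message("input error: missing --data directory")
      return(2L)
    }
    config <- if (!is.null(opt$config)) read_config(opt$config) else analysis_config()
    over <- list(rng_seed = seed)
    if (!is.null(opt$perms)) over$n_permutations <- as.integer(opt$perms)
    config[names(over)] <- over
    covars <- if (!is.null(opt$covariates))
      strsplit(opt$covariates, ",")[[1]] else NULL
    run_pipeline(config, opt$data, which = cmd,
                 out_dir = opt$out %||% file.path(opt$data, "results"),
                 covariates = covars)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("missing|cannot read|no lesion masks|unreadable", conditionMessage(e)))
      2L else 1L
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
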