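# Cohort table: one row per patient, HADS-D depression subscale (0-21),
# optional covariates, and explicit exclusion accounting.

#' Build a cohort table
#'
#' @param df data.frame with `patient_id` and `hads_d` columns, optionally
#'   `age`, `sex`, `nihss`, `barthel`
#' @param cutoff HADS-D group cutoff; patients with `hads_d > cutoff` are
#'   labeled `depressed` (strict inequality)
#' @return data.frame of class `cohort_table` with `group_label`,
#'   `excluded`, `exclusion_reason` columns and a `cutoff` attribute
#' @export
cohort_table <- function(df, cutoff = 10L) {
  req <- c("patient_id", "hads_d")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("cohort table missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id in cohort table")
  hd <- df$hads_d
  bad <- !is.na(hd) & (hd < 0 | hd > 21)
  if (any(bad)) stop("hads_d out of 0-21 for: ",
                     paste(df$patient_id[bad], collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$group_label <- ifelse(is.na(hd), NA_character_,
                           ifelse(hd > cutoff, "depressed", "not_depressed"))
  if (is.null(df$excluded)) df$excluded <- FALSE
  if (is.null(df$exclusion_reason)) df$exclusion_reason <- NA_character_
  miss <- is.na(hd)
  df$excluded[miss] <- TRUE
  df$exclusion_reason[miss] <- "missing hads_d"
  attr(df, "cutoff") <- cutoff
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from CSV/TSV
#'
#' @param path file with `patient_id` and `hads_d` columns (comma- or
#'   tab-separated, sniffed from the first line)
#' @param cutoff HADS-D group cutoff (`hads_d > cutoff` means depressed)
#' @return a [cohort_table()]
#' @export
read_cohort_table <- function(path, cutoff = 10L) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  cohort_table(df, cutoff = cutoff)
}

#' Mark a patient excluded
#'
#' Exclusions are recorded, never silent; `reason` is mandatory.
#'
#' @param cohort a [cohort_table()]
#' @param ids patient ids to exclude
#' @param reason free-text reason stored per patient
#' @export
exclude_patients <- function(cohort, ids, reason) {
  stopifnot(nchar(reason) > 0)
  hit <- cohort$patient_id %in% ids
  newly <- hit & !cohort$excluded
  cohort$excluded[newly] <- TRUE
  cohort$exclusion_reason[newly] <- reason
  if (any(newly)) .sm_log("excluded ", sum(newly), " patient(s): ", reason)
  cohort
}

#' Included subset of a cohort
#' @param cohort a [cohort_table()]
#' @return rows not flagged excluded
#' @export
included <- function(cohort) cohort[!cohort$excluded, , drop = FALSE]

#' Write the exclusion report
#' @param cohort a [cohort_table()]
#' @param path CSV output path
#' @export
write_exclusion_report <- function(cohort, path) {
  ex <- cohort[cohort$excluded, c("patient_id", "exclusion_reason"), drop = FALSE]
  utils::write.csv(ex, path, row.names = FALSE)
  invisible(path)
}
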