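# Undetermined Ct values are written to files as the literal string
# "undetermined" (never a numeric placeholder) and held in memory as NA.

ct_to_file <- function(x) ifelse(is.na(x), "undetermined", format(x))
ct_from_file <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(is.na(x) | trimws(x) == "undetermined")
  if (any(bad))
    stop("unparseable Ct value(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read a per-sample Ct table
#'
#' @param path CSV with header `sample_id,run_id,<one column per panel
#'   target>,internal_control_ct` and optionally `rna_conc`; undetermined
#'   Ct values are the string `"undetermined"`.
#' @param panel Panel configuration, see [fgfr_panel()].
#' @return data.frame with Ct columns numeric (`NA` = undetermined).
#' @export
read_ct_table <- function(path, panel = fgfr_panel()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("sample_id", "run_id", panel$target, "internal_control_ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  for (cl in c(panel$target, "internal_control_ct"))
    df[[cl]] <- ct_from_file(df[[cl]])
  if ("rna_conc" %in% names(df)) df$rna_conc <- as.numeric(df$rna_conc)
  df
}

#' Read a run-control table
#'
#' @param path CSV with header `run_id,control_type,target,ct`
#'   (`control_type` is `ptc` or `ntc`; undetermined Ct is
#'   `"undetermined"`).
#' @return data.frame with `ct` numeric (`NA` = undetermined).
#' @export
read_run_controls <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("run_id", "control_type", "target", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$control_type), c("ptc", "ntc"))
  if (length(bad))
    stop(path, ": unknown control_type: ", paste(bad, collapse = ", "))
  df$ct <- ct_from_file(df$ct)
  df
}

#' QC status for every run in a run-control table
#'
#' Applies [validate_run()] to each run.
#'
#' @param run_controls data.frame as returned by [read_run_controls()].
#' @inheritParams validate_run
#' @return Named character vector mapping run_id to
#'   `"valid"`/`"invalid"`.
#' @export
validate_runs <- function(run_controls, panel = fgfr_panel(),
                          ptc_range = c(20, 30), ntc_min = NULL) {
  runs <- unique(run_controls$run_id)
  out <- vapply(runs, function(r) {
    sub <- run_controls[run_controls$run_id == r, ]
    ptc <- sub[sub$control_type == "ptc", ]
    ntc <- sub[sub$control_type == "ntc", ]
    validate_run(stats::setNames(ptc$ct, ptc$target),
                 stats::setNames(ntc$ct, ntc$target),
                 panel = panel, ptc_range = ptc_range,
                 ntc_min = ntc_min)$status
  }, character(1))
  stats::setNames(out, runs)
}

#' Write the input files for a synthetic bridging study
#'
#' Serialises a synthetic cohort (and its mechanistic Ct profiles) into
#' the five delimited inputs of the pipeline plus the generating
#' configuration: `demographics.csv`, `outcomes.csv`, `paired_calls.csv`,
#' `ct_table.csv`, `run_controls.csv`, `config.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @param profiles Optional [generate_ct_profiles()] result; generated
#'   from the cohort when `NULL`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, profiles = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(profiles)) profiles <- generate_ct_profiles(cohort)
  p <- cohort$patients
  panel <- cohort$config$panel
  w <- function(df, f) {
    path <- file.path(dir, f)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
    path
  }
  demo <- data.frame(patient_id = p$patient_id, tested = p$tested,
                     p[, c("age", "sex", "race", "ethnicity", "region",
                           "tumor_area", "viable_cells", "site")],
                     stringsAsFactors = FALSE)
  tst <- p[p$tested, , drop = FALSE]
  paired <- data.frame(sample_id = tst$patient_id,
                       index_call = tst$cdx_call, ref_call = tst$cta_call,
                       ddpcr_call = tst$ddpcr_call, stringsAsFactors = FALSE)
  outc <- data.frame(patient_id = p$patient_id, treated = p$treated,
                     response = ifelse(is.na(p$response), "", p$response),
                     alteration = p$true_alteration,
                     chemo_refractory = p$chemo_refractory,
                     cta_call = p$cta_call,
                     cdx_call = ifelse(is.na(p$cdx_call), "", p$cdx_call),
                     stringsAsFactors = FALSE)
  ctt <- profiles$ct_table
  for (cl in c(panel$target, "internal_control_ct"))
    ctt[[cl]] <- ct_to_file(ctt[[cl]])
  rc <- profiles$run_controls
  rc$ct <- ct_to_file(rc$ct)
  cfgp <- file.path(dir, "config.json")
  cfg <- cohort$config
  cfg$panel <- NULL
  jsonlite::write_json(unclass(cfg), cfgp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(demographics = w(demo, "demographics.csv"),
              outcomes = w(outc, "outcomes.csv"),
              paired_calls = w(paired, "paired_calls.csv"),
              ct_table = w(ctt, "ct_table.csv"),
              run_controls = w(rc, "run_controls.csv"),
              config = cfgp))
}
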