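#' The nine-target FGFR2/3 panel
#'
#' Returns the panel configuration for the qualitative RT-PCR call engine:
#' four FGFR3 point mutations (R248C, S249C, G370C, Y373C) and five fusions
#' (FGFR3-TACC3_V1, FGFR3-TACC3_V3, FGFR3-BAIAP2L1, FGFR2-CASP7,
#' FGFR2-BICC1), each with a Ct cut-off and a multiplex reaction-mix slot.
#'
#' The commercial assay's Ct cut-offs are proprietary and unpublished; the
#' defaults here (33.0 cycles for every target) are synthetic configuration
#' values used by the simulator and the test-suite. The comparison rule is
#' the assay's: a target is positive when Ct is less than or equal to its
#' cut-off.
#'
#' @param ct_cutoff Ct cut-off applied to every target (cycles), or a named
#'   numeric vector giving a per-target cut-off.
#' @return A data.frame with columns `target`, `alteration_class`
#'   (`"point_mutation"` or `"fusion"`), `ct_cutoff`, `reaction_mix`.
#' @examples
#' fgfr_panel()
#' @export
fgfr_panel <- function(ct_cutoff = 33.0) {
  targets <- c("R248C", "S249C", "G370C", "Y373C",
               "TACC3_V1", "TACC3_V3", "BAIAP2L1", "CASP7", "BICC1")
  cls <- c(rep("point_mutation", 4L), rep("fusion", 5L))
  # two mutation mixes, two fusion mixes
  mix <- c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L)
  if (length(ct_cutoff) == 1L && is.null(names(ct_cutoff))) {
    cutoff <- rep(as.numeric(ct_cutoff), length(targets))
  } else {
    if (!all(targets %in% names(ct_cutoff)))
      stop("per-target ct_cutoff must name all nine panel targets")
    cutoff <- as.numeric(ct_cutoff[targets])
  }
  if (any(!is.finite(cutoff)) || any(cutoff <= 0))
    stop("ct_cutoff must be positive and finite")
  data.frame(target = targets, alteration_class = cls,
             ct_cutoff = cutoff, reaction_mix = mix,
             stringsAsFactors = FALSE)
}

#' Pre-analytical RNA sufficiency check
#'
#' A sample whose RNA concentration falls below the minimum input
#' requirement (18 ng/uL for the assay) is not tested and is accounted for
#' as `insufficient`. A concentration exactly at the minimum meets it.
#'
#' @param rna_conc RNA concentration in ng/uL (nonnegative).
#' @param min_conc Minimum required concentration in ng/uL (default 18).
#' @return `"sufficient"` or `"insufficient"`.
#' @examples
#' check_rna_sufficiency(18, 18)   # "sufficient"
#' check_rna_sufficiency(17.9, 18) # "insufficient"
#' @export
check_rna_sufficiency <- function(rna_conc, min_conc = 18) {
  if (!is.numeric(rna_conc) || length(rna_conc) != 1L || is.na(rna_conc) ||
      rna_conc < 0)
    stop("rna_conc must be a single nonnegative number")
  if (!is.numeric(min_conc) || length(min_conc) != 1L || min_conc <= 0)
    stop("min_conc must be a single positive number")
  if (rna_conc < min_conc) "insufficient" else "sufficient"
}

#' Run-control (PTC/NTC) quality check for a PCR run
#'
#' A run is valid when every positive template control (PTC) amplifies
#' inside its acceptance Ct range and every no-template control (NTC) is
#' either undetermined (no amplification) or above its acceptance minimum;
#' an NTC amplifying inside the analytic range indicates contamination.
#'
#' @param ptc_ct Named numeric vector of PTC Ct values, one per panel
#'   target. `NA` means undetermined (a PTC failure).
#' @param ntc_ct Named numeric vector of NTC Ct values, one per panel
#'   target; `NA` means undetermined (the expected outcome).
#' @param panel Panel configuration, see [fgfr_panel()].
#' @param ptc_range Length-2 numeric, the closed acceptance Ct interval for
#'   PTCs (synthetic default `c(20, 30)`), or a named list of per-target
#'   intervals.
#' @param ntc_min Minimum Ct above which NTC amplification is tolerated as
#'   late nonspecific signal (default: the target's cut-off).
#' @return A list with `status` (`"valid"`/`"invalid"`) and `reasons`, a
#'   character vector naming each failing control.
#' @export
validate_run <- function(ptc_ct, ntc_ct, panel = fgfr_panel(),
                         ptc_range = c(20, 30), ntc_min = NULL) {
  targets <- panel$target
  missing_t <- setdiff(targets, union(names(ptc_ct), names(ntc_ct)))
  if (!all(targets %in% names(ptc_ct)) || !all(targets %in% names(ntc_ct)))
    stop("run controls must cover every panel target; missing: ",
         paste(setdiff(targets, intersect(names(ptc_ct), names(ntc_ct))),
               collapse = ", "))
  range_for <- function(tg) {
    if (is.list(ptc_range)) {
      r <- ptc_range[[tg]]
      if (is.null(r)) stop("no PTC acceptance range configured for ", tg)
      r
    } else ptc_range
  }
  reasons <- character(0)
  for (i in seq_along(targets)) {
    tg <- targets[i]
    r <- range_for(tg)
    pc <- ptc_ct[[tg]]
    if (is.na(pc) || pc < r[1] || pc > r[2])
      reasons <- c(reasons, sprintf("PTC %s Ct %s outside [%g, %g]",
                                    tg, ifelse(is.na(pc), "undetermined",
                                               format(pc)), r[1], r[2]))
    nm <- if (is.null(ntc_min)) panel$ct_cutoff[i] else ntc_min
    nc <- ntc_ct[[tg]]
    if (!is.na(nc) && nc <= nm)
      reasons <- c(reasons,
                   sprintf("NTC %s amplified at Ct %g (contamination)", tg, nc))
  }
  list(status = if (length(reasons)) "invalid" else "valid", reasons = reasons)
}

#' Per-target qualitative call from a Ct value
#'
#' A target is positive when its reaction crossed the fluorescence
#' threshold at or before the assay-specific cut-off cycle; the boundary is
#' inclusive. An undetermined Ct (no amplification, `NA`) is negative.
#'
#' @param ct Ct value in cycles, or `NA` for undetermined.
#' @param cutoff Positive Ct cut-off for the target assay.
#' @return `"positive"` or `"negative"`.
#' @examples
#' call_target(33.0, 33.0)  # "positive" (boundary inclusive)
#' call_target(NA, 33.0)    # "negative"
#' @export
call_target <- function(ct, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff <= 0)
    stop("cutoff must be a single positive number")
  if (length(ct) != 1L) stop("ct must be a single value")
  if (is.na(ct)) return("negative")
  if (!is.numeric(ct) || ct <= 0) stop("ct must be a positive number or NA")
  if (ct <= cutoff) "positive" else "negative"
}

#' Sample-level FGFR status from a Ct profile
#'
#' Applies the qualitative decision cascade of the call engine, with QC
#' precedence mirroring the three disjoint accounting categories:
#' pre-analytical sufficiency first (`insufficient` if the RNA concentration
#' is known and below the minimum), then analytical validity (`invalid` if
#' the run failed QC or the sample's internal control Ct is undetermined or
#' outside its acceptance range), and only then the target calls:
#' `fgfr_positive` with the list of positive targets if at least one target
#' Ct is at or below its cut-off, otherwise `fgfr_negative`.
#'
#' @param target_ct Named numeric vector of per-target Ct values (`NA` =
#'   undetermined) covering the whole panel.
#' @param internal_control_ct Internal-control Ct (`NA` = undetermined).
#' @param panel Panel configuration, see [fgfr_panel()].
#' @param run_status `"valid"` or `"invalid"`, from [validate_run()].
#' @param rna_conc RNA concentration in ng/uL, or `NA` if not measured.
#' @param min_conc Minimum RNA input (ng/uL), default 18.
#' @param ic_range Closed acceptance interval for the internal-control Ct
#'   (synthetic default `c(20, 35)`).
#' @param sample_id Optional identifier carried into the result.
#' @return A list of class `sample_call` with `sample_id`, `status` (one of
#'   `fgfr_positive`, `fgfr_negative`, `invalid`, `insufficient`) and
#'   `positive_targets` (character, empty unless `fgfr_positive`).
#' @export
call_sample <- function(target_ct, internal_control_ct, panel = fgfr_panel(),
                        run_status = "valid", rna_conc = NA_real_,
                        min_conc = 18, ic_range = c(20, 35),
                        sample_id = NA_character_) {
  unknown <- setdiff(names(target_ct), panel$target)
  if (length(unknown))
    stop("unknown target(s) in profile: ", paste(unknown, collapse = ", "))
  if (!all(panel$target %in% names(target_ct)))
    stop("profile must cover every panel target; missing: ",
         paste(setdiff(panel$target, names(target_ct)), collapse = ", "))
  if (!run_status %in% c("valid", "invalid"))
    stop("run_status must be 'valid' or 'invalid'")

  res <- function(status, pos = character(0)) {
    structure(list(sample_id = sample_id, status = status,
                   positive_targets = pos), class = "sample_call")
  }
  if (!is.na(rna_conc) &&
      check_rna_sufficiency(rna_conc, min_conc) == "insufficient")
    return(res("insufficient"))
  ic_fail <- is.na(internal_control_ct) ||
    internal_control_ct < ic_range[1] || internal_control_ct > ic_range[2]
  if (run_status == "invalid" || ic_fail)
    return(res("invalid"))
  pos <- panel$target[vapply(seq_len(nrow(panel)), function(i) {
    call_target(unname(target_ct[[panel$target[i]]]),
                panel$ct_cutoff[i]) == "positive"
  }, logical(1))]
  if (length(pos)) res("fgfr_positive", pos) else res("fgfr_negative")
}

#' @export
print.sample_call <- function(x, ...) {
  cat(sprintf("sample %s: %s", x$sample_id, x$status))
  if (length(x$positive_targets))
    cat(" [", paste(x$positive_targets, collapse = "; "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Call every sample in a Ct table
#'
#' Vectorised driver over [call_sample()]: joins each sample's Ct profile to
#' its run's QC status and emits one call per row.
#'
#' @param ct_table data.frame with columns `sample_id`, `run_id`, one Ct
#'   column per panel target, `internal_control_ct`, and optionally
#'   `rna_conc`. Undetermined Ct values are `NA`.
#' @param run_status Named character vector mapping `run_id` to
#'   `"valid"`/`"invalid"`; runs not listed are assumed valid.
#' @inheritParams call_sample
#' @return data.frame `sample_id`, `status`, `positive_targets`
#'   (semicolon-joined).
#' @export
call_samples <- function(ct_table, run_status = character(0),
                         panel = fgfr_panel(), min_conc = 18,
                         ic_range = c(20, 35)) {
  need <- c("sample_id", "run_id", panel$target, "internal_control_ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop("ct_table missing column(s): ", paste(miss, collapse = ", "))
  has_conc <- "rna_conc" %in% names(ct_table)
  out <- lapply(seq_len(nrow(ct_table)), function(i) {
    row <- ct_table[i, ]
    tct <- as.numeric(row[panel$target])
    names(tct) <- panel$target
    rs <- unname(run_status[as.character(row$run_id)])
    if (length(rs) != 1L || is.na(rs)) rs <- "valid"
    call_sample(tct, row$internal_control_ct, panel = panel,
                run_status = rs,
                rna_conc = if (has_conc) row$rna_conc else NA_real_,
                min_conc = min_conc, ic_range = ic_range,
                sample_id = as.character(row$sample_id))
  })
  data.frame(
    sample_id = vapply(out, `[[`, character(1), "sample_id"),
    status = vapply(out, `[[`, character(1), "status"),
    positive_targets = vapply(out, function(x)
      paste(x$positive_targets, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' Validity accounting across sample calls
#'
#' Tallies the disjoint accounting categories (valid result, insufficient,
#' invalid) over a batch of calls, with percentages of the full batch
#' rounded to one decimal for reporting. `fgfr_positive` and `fgfr_negative`
#' both count as valid results.
#'
#' @param status Character vector of per-sample statuses, or a data.frame
#'   with a `status` column (as returned by [call_samples()]).
#' @return data.frame with rows `valid`, `insufficient`, `invalid` and
#'   columns `n`, `percent` (1-decimal); attribute `total` holds the batch
#'   size.
#' @examples
#' tally_validity(rep(c("fgfr_positive", "fgfr_negative", "insufficient",
#'                      "invalid"), c(88, 204, 3, 5)))
#' @export
tally_validity <- function(status) {
  if (is.data.frame(status)) status <- status$status
  if (!length(status)) stop("no sample calls to tally")
  ok <- c("fgfr_positive", "fgfr_negative", "invalid", "insufficient")
  bad <- setdiff(unique(status), ok)
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  n <- length(status)
  cnt <- c(valid = sum(status %in% c("fgfr_positive", "fgfr_negative")),
           insufficient = sum(status == "insufficient"),
           invalid = sum(status == "invalid"))
  out <- data.frame(category = names(cnt), n = as.integer(cnt),
                    percent = round(100 * cnt / n, 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- n
  out
}
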