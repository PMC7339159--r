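#' Run the full bridging analysis
#'
#' Orchestrates every stage of the bridging study on in-memory tables:
#' sample-validity accounting (through the call engine when Ct data are
#' supplied), cohort representativeness, index-vs-reference concordance
#' with Wilson intervals, accuracy against the orthogonal reference with
#' exact intervals and the CI-floor acceptance rule, ORR overall / by
#' alteration / in the chemo-refractory subgroup with the
#' primary-objective rule, and the weighted-ORR imputation scenarios with
#' bootstrap intervals.
#'
#' Pairs where either assay is invalid or insufficient are excluded from
#' the 2x2 tables and surface only in the validity tally; the accuracy
#' section is skipped with a notice when no ddPCR column is present.
#'
#' @param demographics data.frame per [read_demographics()].
#' @param outcomes data.frame per [read_outcomes()].
#' @param paired_calls data.frame per [read_paired_calls()] (optional
#'   column `ddpcr_call` enables the accuracy section).
#' @param ct_table,run_controls Optional mechanistic inputs (see
#'   [read_ct_table()], [read_run_controls()]); when supplied, sample
#'   calls and the validity tally are recomputed through the call engine.
#' @param panel Panel configuration, see [fgfr_panel()].
#' @param seed Integer seed for the weighted-ORR bootstrap.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param ppa_floor,npa_floor Accuracy acceptance floors in percent.
#' @param orr_margin Primary-objective margin in percent (default 25).
#' @param alpha Significance level for representativeness flags.
#' @param f_list Imputation fractions for the weighted-ORR scenarios.
#' @param quiet Suppress stage-boundary log lines.
#' @return Object of class `bridging_report` (a list of sections).
#' @export
run_pipeline <- function(demographics, outcomes, paired_calls,
                         ct_table = NULL, run_controls = NULL,
                         panel = fgfr_panel(), seed, n_boot = 2000,
                         ppa_floor = 85, npa_floor = 90, orr_margin = 25,
                         alpha = 0.05, f_list = c(0, 0.25, 0.5, 0.75, 1),
                         quiet = FALSE) {
  if (missing(seed)) stop("seed is required (weighted-ORR bootstrap)")
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(thresholds = list(ppa_floor = ppa_floor,
                                   npa_floor = npa_floor,
                                   orr_margin = orr_margin, alpha = alpha,
                                   n_boot = n_boot, seed = seed))

  # -- validity -------------------------------------------------------
  if (!is.null(ct_table)) {
    rs <- if (is.null(run_controls)) character(0) else
      validate_runs(run_controls, panel = panel)
    calls <- call_samples(ct_table, run_status = rs, panel = panel)
    report$calls <- calls
    report$validity <- tally_validity(calls)
    say("call engine: %d samples -> %d valid", nrow(calls),
        sum(calls$status %in% c("fgfr_positive", "fgfr_negative")))
  } else {
    st <- ifelse(paired_calls$index_call %in% c("positive", "negative"),
                 ifelse(paired_calls$index_call == "positive",
                        "fgfr_positive", "fgfr_negative"),
                 paired_calls$index_call)
    report$validity <- tally_validity(st)
  }

  # -- representativeness ---------------------------------------------
  report$representativeness <-
    representativeness_report(demographics, alpha = alpha)
  say("representativeness: %d variables, %d flagged",
      nrow(report$representativeness), sum(report$representativeness$flag))

  # -- concordance ----------------------------------------------------
  ok <- paired_calls$index_call %in% c("positive", "negative") &
    paired_calls$ref_call %in% c("positive", "negative")
  pc <- paired_calls[ok, , drop = FALSE]
  report$excluded_pairs <- sum(!ok)
  tab <- build_2x2(pc$index_call, pc$ref_call, sample_id = pc$sample_id,
                   index_name = "CDx", ref_name = "CTA")
  report$concordance <- list(table = tab,
                             estimates = percent_agreement(tab, "wilson"))
  say("concordance: N=%d pairs (%d excluded)", tab$n, sum(!ok))

  # -- accuracy vs orthogonal reference -------------------------------
  has_ddpcr <- "ddpcr_call" %in% names(paired_calls) &&
    any(paired_calls$index_call %in% c("positive", "negative") &
          paired_calls$ddpcr_call %in% c("positive", "negative"))
  if (has_ddpcr) {
    ok2 <- paired_calls$index_call %in% c("positive", "negative") &
      paired_calls$ddpcr_call %in% c("positive", "negative")
    ac <- paired_calls[ok2, , drop = FALSE]
    atab <- build_2x2(ac$index_call, ac$ddpcr_call,
                      sample_id = ac$sample_id,
                      index_name = "CDx", ref_name = "ddPCR")
    aest <- percent_agreement(atab, "clopper_pearson")
    report$accuracy <- list(
      table = atab, estimates = aest,
      decision = accuracy_decision(aest$ppa, aest$npa, ppa_floor,
                                   npa_floor))
    say("accuracy: N=%d pairs, decision %s", atab$n,
        report$accuracy$decision$decision)
  } else {
    say("accuracy: no ddPCR calls supplied; section skipped")
  }

  # -- efficacy -------------------------------------------------------
  conc_pos <- function(df) df$cta_call == "positive" &
    df$cdx_call == "positive"
  overall <- orr(outcomes, subset = conc_pos,
                 subgroup = "concordant_positive")
  chemo <- orr(outcomes,
               subset = function(df) conc_pos(df) & df$chemo_refractory,
               subgroup = "chemo_refractory")
  by_alt <- orr_by_alteration(
    outcomes[as.logical(outcomes$treated) & conc_pos(outcomes), ,
             drop = FALSE], panel = panel)
  treated_ctapos <- as.logical(outcomes$treated) &
    outcomes$cta_call == "positive"
  no_valid_cdx <- sum(treated_ctapos &
                        !outcomes$cdx_call %in% c("positive", "negative"))
  report$efficacy <- list(
    overall = overall, chemo_refractory = chemo, by_alteration = by_alt,
    excluded_no_valid_cdx = no_valid_cdx,
    primary = primary_objective(overall, margin = orr_margin))
  say("efficacy: %d/%d responders, primary objective %s",
      overall$responders, overall$n, report$efficacy$primary$decision)

  # -- weighted ORR ---------------------------------------------------
  orr_ref <- orr(outcomes,
                 subset = function(df) df$cta_call == "positive",
                 subgroup = "cta_positive")
  w <- calibrate_weight(overall$estimate$point, orr_ref$estimate$point)
  conc_out <- outcomes[as.logical(outcomes$treated) & conc_pos(outcomes), ,
                       drop = FALSE]
  report$weighted_orr <- list(
    weight = w, reference = orr_ref,
    scenarios = scenario_table(conc_out, w, f_list = f_list,
                               n_boot = n_boot, seed = seed))
  say("weighted ORR: w=%.4f over %d scenarios", w$w_concordant,
      length(f_list))
  class(report) <- "bridging_report"
  report
}

#' @export
print.bridging_report <- function(x, ...) {
  cat("== Sample validity ==\n")
  print(x$validity, row.names = FALSE)
  cat("\n== Representativeness (alpha =", x$thresholds$alpha, ") ==\n")
  rp <- x$representativeness
  rp$p <- signif(rp$p, 2)
  rp$statistic <- round(rp$statistic, 2)
  print(rp, row.names = FALSE)
  cat("\n== Concordance (CDx vs CTA, Wilson) ==\n")
  print(x$concordance$table)
  print(x$concordance$estimates)
  if (!is.null(x$accuracy)) {
    cat("\n== Accuracy (CDx vs ddPCR, Clopper-Pearson) ==\n")
    print(x$accuracy$table)
    print(x$accuracy$estimates, digits = 2)
    cat("accuracy decision:", x$accuracy$decision$decision, "\n")
  }
  cat("\n== Efficacy ==\n")
  print(x$efficacy$overall)
  print(x$efficacy$chemo_refractory)
  print(format_orr_table(x$efficacy$by_alteration), row.names = FALSE)
  cat(sprintf("primary objective: %s (CI lower %.1f vs margin %g)\n",
              x$efficacy$primary$decision, x$efficacy$primary$ci_low,
              x$efficacy$primary$margin))
  cat("\n== Weighted ORR scenarios ==\n")
  print(x$weighted_orr$weight)
  sc <- x$weighted_orr$scenarios
  sc[-1] <- round(sc[-1], 1)
  print(sc, row.names = FALSE)
  invisible(x)
}

#' Machine-readable summary of a bridging report
#'
#' Flattens the report into a list of plain numbers at full precision —
#' exactly the quantities shown in the printed tables, with no independent
#' recomputation — suitable for JSON serialisation.
#'
#' @param report A [run_pipeline()] result.
#' @param path Optional path; when given the summary is written as JSON.
#' @return The summary list, invisibly when `path` is given.
#' @export
report_summary <- function(report, path = NULL) {
  stopifnot(inherits(report, "bridging_report"))
  est <- function(e) list(numerator = e$numerator,
                          denominator = e$denominator, point = e$point,
                          ci_low = e$ci_low, ci_high = e$ci_high,
                          method = e$method)
  ce <- report$concordance$estimates
  out <- list(
    validity = report$validity,
    representativeness = report$representativeness,
    concordance = list(
      counts = report$concordance$table[c("a", "b", "c", "d", "n")],
      ppa = est(ce$ppa), npa = est(ce$npa), opa = est(ce$opa)),
    efficacy = list(
      overall = est(report$efficacy$overall$estimate),
      chemo_refractory = est(report$efficacy$chemo_refractory$estimate),
      by_alteration = report$efficacy$by_alteration,
      primary_objective = report$efficacy$primary),
    weighted_orr = list(
      w = report$weighted_orr$weight$w_concordant,
      scenarios = report$weighted_orr$scenarios),
    thresholds = report$thresholds)
  if (!is.null(report$accuracy)) {
    ae <- report$accuracy$estimates
    out$accuracy <- list(
      counts = report$accuracy$table[c("a", "b", "c", "d", "n")],
      ppa = est(ae$ppa), npa = est(ae$npa), opa = est(ae$opa),
      decision = report$accuracy$decision$decision)
  }
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(out))
  }
  out
}
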