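#' Objective response rate with confidence interval
#'
#' ORR is the proportion of treated patients whose best response is
#' complete (CR) or partial (PR) response, over *all* treated patients in
#' the subset — non-evaluable (NE) patients stay in the denominator.
#'
#' @param outcomes data.frame of patient outcomes with at least columns
#'   `treated` (logical) and `response` (one of CR, PR, SD, PD, NE).
#' @param subset Optional predicate: a function taking the data.frame and
#'   returning a logical vector, applied after restricting to treated
#'   patients.
#' @param ci_method CI method, `"wilson"` (default) or `"clopper_pearson"`.
#' @param conf_level Two-sided confidence level, default 0.95.
#' @param subgroup Label carried into the result.
#' @return Object of class `orr_estimate`: list with `responders`, `n`,
#'   `estimate` (a [proportion_estimate()]) and `subgroup`.
#' @examples
#' pts <- data.frame(treated = TRUE,
#'                   response = rep(c("PR", "SD"), c(37, 44)))
#' orr(pts)  # 45.7 (35.3; 56.5)
#' @export
orr <- function(outcomes, subset = NULL,
                ci_method = c("wilson", "clopper_pearson"),
                conf_level = 0.95, subgroup = "overall") {
  ci_method <- match.arg(ci_method)
  need <- c("treated", "response")
  miss <- setdiff(need, names(outcomes))
  if (length(miss))
    stop("outcomes missing column(s): ", paste(miss, collapse = ", "))
  df <- outcomes[as.logical(outcomes$treated), , drop = FALSE]
  if (!is.null(subset)) {
    keep <- subset(df)
    if (!is.logical(keep) || length(keep) != nrow(df))
      stop("subset must return one logical per treated patient")
    df <- df[keep, , drop = FALSE]
  }
  if (!nrow(df))
    stop("empty subset for subgroup '", subgroup,
         "': no treated patients match")
  bad <- setdiff(unique(df$response), c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad))
    stop("unknown response value(s): ", paste(bad, collapse = ", "))
  x <- sum(df$response %in% c("CR", "PR"))
  structure(list(responders = x, n = nrow(df),
                 estimate = proportion_estimate(x, nrow(df), ci_method,
                                                conf_level, label = "orr"),
                 subgroup = subgroup),
            class = "orr_estimate")
}

#' @export
print.orr_estimate <- function(x, digits = 1, ...) {
  cat(sprintf("ORR [%s]: ", x$subgroup))
  print(x$estimate, digits = digits)
  invisible(x)
}

#' ORR by FGFR alteration with class aggregates
#'
#' One row per panel target in the concordant-positive treated population,
#' plus aggregates for the point-mutation class, the fusion class and
#' overall. Subgroups with no patients are reported with `n = 0` and no
#' estimate (rendered as a dash).
#'
#' @param outcomes data.frame with columns `treated`, `response`,
#'   `alteration` (a panel target name, or `""`/`NA` for none).
#' @param panel Panel configuration, see [fgfr_panel()].
#' @inheritParams orr
#' @return data.frame with columns `subgroup`, `class`, `n`, `responders`,
#'   `orr`, `ci_low`, `ci_high` (percent, full precision; `NA` where
#'   `n = 0`).
#' @export
orr_by_alteration <- function(outcomes, panel = fgfr_panel(),
                              ci_method = c("wilson", "clopper_pearson"),
                              conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (!"alteration" %in% names(outcomes))
    stop("outcomes missing column: alteration")
  df <- outcomes[as.logical(outcomes$treated), , drop = FALSE]
  known <- c(panel$target, "", NA_character_)
  bad <- setdiff(unique(df$alteration), known)
  if (length(bad))
    stop("alteration(s) not in the panel: ", paste(bad, collapse = ", "))
  one <- function(label, cls, keep) {
    sub <- df[keep, , drop = FALSE]
    n <- nrow(sub)
    if (!n)
      return(data.frame(subgroup = label, class = cls, n = 0L,
                        responders = 0L, orr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, stringsAsFactors = FALSE))
    x <- sum(sub$response %in% c("CR", "PR"))
    est <- proportion_estimate(x, n, ci_method, conf_level)
    data.frame(subgroup = label, class = cls, n = n, responders = x,
               orr = est$point, ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  }
  alt <- ifelse(is.na(df$alteration), "", df$alteration)
  rows <- list(one("overall", "all", rep(TRUE, nrow(df))))
  for (cls in c("point_mutation", "fusion")) {
    tg <- panel$target[panel$alteration_class == cls]
    rows <- c(rows, list(one(cls, cls, alt %in% tg)),
              lapply(tg, function(t) one(t, cls, alt == t)))
  }
  do.call(rbind, rows)
}

#' Primary-objective decision rule on the ORR lower bound
#'
#' The primary efficacy objective is met when the lower bound of the CI
#' for the observed ORR strictly exceeds the margin.
#'
#' @param est An `orr_estimate` (or a [proportion_estimate()]).
#' @param margin Margin in percent, default 25.
#' @return List with `decision` (`"met"`/`"not_met"`), `ci_low`, `margin`.
#' @export
primary_objective <- function(est, margin = 25) {
  pe <- if (inherits(est, "orr_estimate")) est$estimate else est
  stopifnot(inherits(pe, "prop_estimate"))
  list(decision = if (pe$ci_low > margin) "met" else "not_met",
       ci_low = pe$ci_low, margin = margin)
}

#' Read a patient-outcome table
#'
#' @param path CSV with columns `patient_id,treated,response,alteration,
#'   chemo_refractory,cta_call,cdx_call`.
#' @return data.frame with `treated` and `chemo_refractory` coerced to
#'   logical.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(alteration = "character",
                                       response = "character"))
  need <- c("patient_id", "treated", "response", "alteration",
            "chemo_refractory", "cta_call", "cdx_call")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df$treated <- as.logical(df$treated)
  df$chemo_refractory <- as.logical(df$chemo_refractory)
  df
}

#' Format an ORR-by-alteration table for reporting
#'
#' Rounds to 1 decimal and renders zero-denominator subgroups as an
#' em-dash, mirroring the presentation of clinical efficacy tables.
#'
#' @param tab Output of [orr_by_alteration()].
#' @return data.frame of character columns ready for printing.
#' @export
format_orr_table <- function(tab) {
  fmt <- function(i) {
    if (tab$n[i] == 0) return("—")
    sprintf("%.1f (%.1f; %.1f)", tab$orr[i], tab$ci_low[i], tab$ci_high[i])
  }
  data.frame(subgroup = tab$subgroup, n = tab$n, responders = tab$responders,
             orr_ci = vapply(seq_len(nrow(tab)), fmt, character(1)),
             stringsAsFactors = FALSE)
}
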