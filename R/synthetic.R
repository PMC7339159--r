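#' Configuration for the synthetic screened-cohort generator
#'
#' Bundles every parameter of the simulated bridging study. Defaults
#' emulate the study conditions the analysis assumes: a screened population
#' of about 2,000 patients with ~18% assay-detectable FGFR prevalence,
#' paired imperfect assays whose concordance matches the observed agreement
#' table (P(CDx+|CTA+) = 0.872, P(CDx+|CTA-) = 0.030), per-alteration
#' response probabilities taken from the observed subgroup response rates,
#' 1.0% insufficient and 1.7% invalid sample rates, and baseline
#' demographics drawn from the screened-population summaries. Per-target
#' prevalence is split proportionally to the observed subgroup sizes (a
#' 0.5 pseudo-count keeps the two never-observed fusions possible).
#'
#' @param n_screened Screened-population size (default 2000).
#' @param n_tested_pos,n_tested_neg Reference-positive and
#'   reference-negative samples selected into the bridging test set
#'   (defaults 100 and 200).
#' @param prevalence Total assay-detectable alteration prevalence (default
#'   0.18).
#' @param target_weights Named nonnegative weights splitting `prevalence`
#'   across the nine panel targets.
#' @param cta_sensitivity,cta_specificity Reference-assay (CTA) operating
#'   characteristics against true alteration status.
#' @param p_cdx_pos_given_cta_pos,p_cdx_pos_given_cta_neg Concordance
#'   parameters of the index assay conditional on the reference call.
#' @param ddpcr_sensitivity,ddpcr_specificity Orthogonal reference-method
#'   (ddPCR) operating characteristics against true status.
#' @param response_prob Named per-target probabilities of objective
#'   response (CR/PR) under treatment.
#' @param response_default Response probability for treated patients with
#'   no recorded alteration class-specific rate.
#' @param treat_prob Probability a reference-positive patient was treated.
#' @param chemo_refractory_prob Probability a treated patient is
#'   chemo-relapsed/refractory.
#' @param invalid_rate,insufficient_rate Per-tested-sample probabilities of
#'   an analytically invalid or pre-analytically insufficient result.
#' @param demographics Per-variable distributions: list with `age`,
#'   `tumor_area`, `viable_cells` (each `c(mean, sd)`) and `sex`, `race`,
#'   `ethnicity`, `region`, `site` (named frequency vectors).
#' @param ct_model Ct-generation parameters: `pos_offset` and `pos_sd`
#'   (positive-target Ct ~ Normal(cutoff + pos_offset, pos_sd)),
#'   `neg_undetermined_prob`, `neg_offset`, `neg_sd` (negative targets),
#'   `ic_mean`, `ic_sd` (internal control), `ptc_mean`, `ptc_sd`,
#'   `samples_per_run`.
#' @param panel Panel configuration, see [fgfr_panel()].
#' @param seed Integer seed; mandatory.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_screened = 2000L,
                          n_tested_pos = 100L, n_tested_neg = 200L,
                          prevalence = 0.18,
                          target_weights = c(R248C = 13, S249C = 42,
                                             G370C = 3, Y373C = 11,
                                             TACC3_V1 = 14, TACC3_V3 = 5,
                                             BAIAP2L1 = 1, CASP7 = 0.5,
                                             BICC1 = 0.5),
                          cta_sensitivity = 0.97, cta_specificity = 0.99,
                          p_cdx_pos_given_cta_pos = 0.872,
                          p_cdx_pos_given_cta_neg = 0.030,
                          ddpcr_sensitivity = 0.99,
                          ddpcr_specificity = 0.99,
                          response_prob = c(R248C = 0.538, S249C = 0.452,
                                            G370C = 0.333, Y373C = 0.636,
                                            TACC3_V1 = 0.357,
                                            TACC3_V3 = 0.20,
                                            BAIAP2L1 = 0.0, CASP7 = 0.457,
                                            BICC1 = 0.457),
                          response_default = 0.457,
                          treat_prob = 0.99,
                          chemo_refractory_prob = 87 / 99,
                          invalid_rate = 0.017, insufficient_rate = 0.010,
                          demographics = list(
                            age = c(66.6, 9.87),
                            tumor_area = c(61.9, 30.37),
                            viable_cells = c(64.9, 25.18),
                            sex = c(Male = 0.762, Female = 0.238),
                            race = c(White = 0.657, Black = 0.010,
                                     Asian = 0.141, Other = 0.192),
                            ethnicity = c("Hispanic/Latino" = 0.016,
                                          "Not Hispanic/Latino" = 0.771,
                                          "Unknown" = 0.213),
                            region = c("North America" = 0.158,
                                       "Asia" = 0.156, "Europe" = 0.686),
                            site = c(Primary = 0.845, Metastatic = 0.154,
                                     Unknown = 0.001)),
                          ct_model = list(pos_offset = -5, pos_sd = 1,
                                          neg_undetermined_prob = 0.98,
                                          neg_offset = 4, neg_sd = 1,
                                          ic_mean = 27.5, ic_sd = 1.5,
                                          ptc_mean = 25, ptc_sd = 1,
                                          samples_per_run = 30L),
                          panel = fgfr_panel(),
                          seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed))
    stop("an integer seed is mandatory")
  probs <- c(prevalence, cta_sensitivity, cta_specificity,
             p_cdx_pos_given_cta_pos, p_cdx_pos_given_cta_neg,
             ddpcr_sensitivity, ddpcr_specificity, response_prob,
             response_default, treat_prob, chemo_refractory_prob,
             invalid_rate, insufficient_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (!all(panel$target %in% names(target_weights)))
    stop("target_weights must name all panel targets")
  if (any(target_weights < 0) || sum(target_weights) <= 0)
    stop("target_weights must be nonnegative with positive sum")
  if (prevalence > 1) stop("prevalence must be at most 1")
  cfg <- list(n_screened = as.integer(n_screened),
              n_tested_pos = as.integer(n_tested_pos),
              n_tested_neg = as.integer(n_tested_neg),
              prevalence = prevalence,
              target_prevalence = prevalence * target_weights[panel$target] /
                sum(target_weights[panel$target]),
              cta_sensitivity = cta_sensitivity,
              cta_specificity = cta_specificity,
              p_cdx_pos_given_cta_pos = p_cdx_pos_given_cta_pos,
              p_cdx_pos_given_cta_neg = p_cdx_pos_given_cta_neg,
              ddpcr_sensitivity = ddpcr_sensitivity,
              ddpcr_specificity = ddpcr_specificity,
              response_prob = response_prob,
              response_default = response_default,
              treat_prob = treat_prob,
              chemo_refractory_prob = chemo_refractory_prob,
              invalid_rate = invalid_rate,
              insufficient_rate = insufficient_rate,
              demographics = demographics, ct_model = ct_model,
              panel = panel, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic screened cohort
#'
#' Draws a full screened population: true per-patient alteration status,
#' baseline demographics, reference (CTA) and index (CDx) calls, an
#' orthogonal ddPCR call, sample validity status for the tested subset,
#' treatment flags and best responses. The index call is generated
#' conditionally on the reference call (the statistical fast path); Ct
#' profiles that reproduce the same calls mechanically are generated
#' separately by [generate_ct_profiles()].
#'
#' Patients who are reference-negative are never treated and carry no
#' response — the trial enrolled on the reference assay, which is exactly
#' why discordant-positive outcomes must be imputed downstream.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `patients` (one
#'   row per screened patient) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_screened
  with_seed(cfg$seed, {
    targets <- cfg$panel$target
    p_alt <- cfg$target_prevalence
    alt <- sample(c(targets, ""), n, replace = TRUE,
                  prob = c(p_alt, 1 - sum(p_alt)))
    has_alt <- alt != ""

    dem <- cfg$demographics
    draw_cat <- function(freq) sample(names(freq), n, TRUE, prob = freq)
    demo <- data.frame(
      age = round(stats::rnorm(n, dem$age[1], dem$age[2]), 1),
      sex = draw_cat(dem$sex), race = draw_cat(dem$race),
      ethnicity = draw_cat(dem$ethnicity), region = draw_cat(dem$region),
      tumor_area = pmin(100, pmax(0, round(
        stats::rnorm(n, dem$tumor_area[1], dem$tumor_area[2]), 1))),
      viable_cells = pmin(100, pmax(0, round(
        stats::rnorm(n, dem$viable_cells[1], dem$viable_cells[2]), 1))),
      site = draw_cat(dem$site), stringsAsFactors = FALSE)

    cta_pos <- ifelse(has_alt,
                      stats::runif(n) < cfg$cta_sensitivity,
                      stats::runif(n) < 1 - cfg$cta_specificity)
    cdx_pos <- ifelse(cta_pos,
                      stats::runif(n) < cfg$p_cdx_pos_given_cta_pos,
                      stats::runif(n) < cfg$p_cdx_pos_given_cta_neg)
    ddpcr_pos <- ifelse(has_alt,
                        stats::runif(n) < cfg$ddpcr_sensitivity,
                        stats::runif(n) < 1 - cfg$ddpcr_specificity)

    treated <- cta_pos & stats::runif(n) < cfg$treat_prob
    chemo_ref <- treated & stats::runif(n) < cfg$chemo_refractory_prob
    p_resp <- ifelse(has_alt,
                     unname(cfg$response_prob[alt]), cfg$response_default)
    p_resp[is.na(p_resp)] <- cfg$response_default
    responder <- treated & stats::runif(n) < p_resp
    response <- rep(NA_character_, n)
    response[treated] <- ifelse(
      responder[treated],
      sample(c("CR", "PR"), sum(treated), TRUE, prob = c(0.2, 0.8)),
      sample(c("SD", "PD", "NE"), sum(treated), TRUE,
             prob = c(0.3, 0.6, 0.1)))[seq_len(sum(treated))]

    # bridging test set: sampled reference-positive and -negative patients
    idx_pos <- which(cta_pos); idx_neg <- which(!cta_pos)
    tested_idx <- c(
      sample(idx_pos, min(cfg$n_tested_pos, length(idx_pos))),
      sample(idx_neg, min(cfg$n_tested_neg, length(idx_neg))))
    tested <- seq_len(n) %in% tested_idx

    # sample validity applies only to tested samples
    u <- stats::runif(n)
    status <- rep(NA_character_, n)
    status[tested] <- "valid"
    status[tested & u < cfg$insufficient_rate] <- "insufficient"
    status[tested & u >= cfg$insufficient_rate &
             u < cfg$insufficient_rate + cfg$invalid_rate] <- "invalid"

    cdx_call <- rep(NA_character_, n)
    cdx_call[tested] <- ifelse(
      status[tested] == "valid",
      ifelse(cdx_pos[tested], "positive", "negative"), status[tested])

    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)), demo,
      true_alteration = alt,
      cta_call = ifelse(cta_pos, "positive", "negative"),
      cdx_latent = ifelse(cdx_pos, "positive", "negative"),
      ddpcr_call = ifelse(ddpcr_pos, "positive", "negative"),
      tested = tested, sample_status = status, cdx_call = cdx_call,
      treated = treated, chemo_refractory = chemo_ref,
      response = response, stringsAsFactors = FALSE)
    structure(list(patients = patients, config = cfg),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$patients
  cat(sprintf(paste0("synthetic cohort: %d screened, %d tested ",
                     "(%d CTA+), %d treated\n"),
              nrow(p), sum(p$tested),
              sum(p$tested & p$cta_call == "positive"), sum(p$treated)))
  invisible(x)
}

#' Generate mechanistic Ct profiles and run controls for a cohort
#'
#' Produces, for every tested sample, a per-target Ct profile whose
#' qualitative interpretation through the call engine reproduces the
#' cohort's index-assay calls: latent-positive targets draw Ct from
#' Normal(cutoff + pos_offset, pos_sd) (default 5 cycles below cut-off),
#' latent-negative targets are undetermined or draw from an above-cut-off
#' distribution, invalid samples get an undetermined internal control, and
#' insufficient samples get a below-minimum RNA concentration. One set of
#' passing run controls (PTC in range, NTC undetermined) is emitted per
#' run.
#'
#' @param cohort A [generate_cohort()] result.
#' @param seed Integer seed; defaults to the cohort seed + 1.
#' @return List with `ct_table` (one row per tested sample),
#'   `run_controls` (long format: `run_id,control_type,target,ct`) and
#'   `run_status` (named vector, all `"valid"`).
#' @export
generate_ct_profiles <- function(cohort, seed = cohort$config$seed + 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$config
  cm <- cfg$ct_model
  panel <- cfg$panel
  p <- cohort$patients[cohort$patients$tested, , drop = FALSE]
  n <- nrow(p)
  with_seed(seed, {
    run_id <- sprintf("R%03d", ceiling(seq_len(n) / cm$samples_per_run))
    ct <- matrix(NA_real_, n, nrow(panel),
                 dimnames = list(NULL, panel$target))
    for (j in seq_len(nrow(panel))) {
      cutoff <- panel$ct_cutoff[j]
      pos_here <- p$cdx_latent == "positive" &
        p$true_alteration == panel$target[j]
      neg_amp <- !pos_here & stats::runif(n) >= cm$neg_undetermined_prob
      ct[pos_here, j] <- stats::rnorm(sum(pos_here),
                                      cutoff + cm$pos_offset, cm$pos_sd)
      ct[neg_amp, j] <- stats::rnorm(sum(neg_amp),
                                     cutoff + cm$neg_offset, cm$neg_sd)
    }
    # latent positives without a true alteration amplify one pseudo-target
    orphan <- p$cdx_latent == "positive" & p$true_alteration == ""
    for (i in which(orphan)) {
      j <- 1 + (i %% nrow(panel))
      ct[i, j] <- stats::rnorm(1, panel$ct_cutoff[j] + cm$pos_offset,
                               cm$pos_sd)
    }
    ic <- stats::rnorm(n, cm$ic_mean, cm$ic_sd)
    ic[p$sample_status == "invalid"] <- NA_real_
    rna <- stats::runif(n, 25, 60)
    rna[p$sample_status == "insufficient"] <- stats::runif(
      sum(p$sample_status == "insufficient"), 2, 17.5)
    ct_table <- data.frame(sample_id = p$patient_id, run_id = run_id,
                           as.data.frame(ct), internal_control_ct = ic,
                           rna_conc = round(rna, 1),
                           stringsAsFactors = FALSE)
    runs <- unique(run_id)
    rc <- do.call(rbind, lapply(runs, function(r) {
      data.frame(run_id = r,
                 control_type = rep(c("ptc", "ntc"),
                                    each = nrow(panel)),
                 target = rep(panel$target, 2),
                 ct = c(stats::rnorm(nrow(panel), cm$ptc_mean, cm$ptc_sd),
                        rep(NA_real_, nrow(panel))),
                 stringsAsFactors = FALSE)
    }))
    rs <- stats::setNames(rep("valid", length(runs)), runs)
    list(ct_table = ct_table, run_controls = rc, run_status = rs)
  })
}
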