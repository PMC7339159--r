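#' Weight scheme for the weighted-ORR sensitivity analysis
#'
#' The weighted overall ORR combines the observed ORR in concordant-positive
#' patients (CDx+/CTA+) with a hypothetical ORR for discordant-positive
#' patients (CDx+/CTA-), who were never treated: weighted = w * ORR_cc +
#' (1 - w) * ORR_hyp. `w` is the probability mass placed on the concordant
#' stratum.
#'
#' @param w_concordant Weight in (0, 1] for the concordant stratum.
#' @param source How the weight was obtained: `"calibrated"`,
#'   `"prevalence_model"` or `"explicit"`.
#' @return Object of class `weight_scheme`.
#' @export
weight_scheme <- function(w_concordant,
                          source = c("explicit", "calibrated",
                                     "prevalence_model")) {
  source <- match.arg(source)
  if (!is.numeric(w_concordant) || length(w_concordant) != 1L ||
      is.na(w_concordant) || w_concordant <= 0 || w_concordant > 1)
    stop("w_concordant must be a single number in (0, 1]")
  structure(list(w_concordant = w_concordant, source = source),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("concordant-stratum weight w = %.4f (%s)\n",
              x$w_concordant, x$source))
  invisible(x)
}

#' Calibrate the concordant weight to a reference ORR
#'
#' Chooses `w` so that the zero-imputation scenario (hypothetical discordant
#' ORR = 0) reproduces a reference ORR: `w = orr_reference / orr_concordant`.
#' The natural anchor is the ORR observed among all reference-assay-positive
#' treated patients, so that diluting the concordant stratum down to the
#' full treated population is consistent with the observed data.
#'
#' @param orr_concordant Observed ORR in concordant-positive patients
#'   (percent, in (0, 100]).
#' @param orr_reference Anchor ORR for the f = 0 scenario (percent,
#'   0 <= orr_reference <= orr_concordant).
#' @return A [weight_scheme()] with source `"calibrated"`.
#' @examples
#' calibrate_weight(100 * 37 / 81, 100 * 40 / 99)  # w ~ 0.8845
#' @export
calibrate_weight <- function(orr_concordant, orr_reference) {
  if (!is.numeric(orr_concordant) || orr_concordant <= 0 ||
      orr_concordant > 100)
    stop("orr_concordant must be in (0, 100]")
  if (!is.numeric(orr_reference) || orr_reference < 0)
    stop("orr_reference must be nonnegative")
  if (orr_reference > orr_concordant)
    stop("orr_reference exceeds orr_concordant: calibrated weight would ",
         "exceed 1")
  weight_scheme(orr_reference / orr_concordant, "calibrated")
}

#' Prevalence-model weight for the concordant stratum
#'
#' Alternative interpretation of the weighting: the expected share of
#' CDx-positive patients in the screened population who are also
#' reference-assay positive, `w = p*PPA / (p*PPA + (1-p)*(1-NPA))` where
#' `p` is the alteration prevalence.
#'
#' @param prevalence Assay-positive prevalence in the screened population,
#'   in (0, 1).
#' @param ppa Positive percent agreement as a probability in (0, 1).
#' @param one_minus_npa False-positive rate of the index test against the
#'   reference, in (0, 1).
#' @return A [weight_scheme()] with source `"prevalence_model"`.
#' @examples
#' prevalence_weight(0.21, 0.8723, 0.0303)  # w ~ 0.884
#' @export
prevalence_weight <- function(prevalence, ppa, one_minus_npa) {
  for (v in list(prevalence, ppa, one_minus_npa))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      stop("prevalence, ppa and one_minus_npa must all lie in (0, 1)")
  den <- prevalence * ppa + (1 - prevalence) * one_minus_npa
  if (den <= 0) stop("degenerate denominator in prevalence weight")
  weight_scheme(prevalence * ppa / den, "prevalence_model")
}

#' Weighted overall ORR for one imputation scenario
#'
#' With the hypothetical discordant ORR set to a fraction `f` of the
#' observed concordant ORR, the weighted overall ORR is
#' `orr_cc * (w + (1 - w) * f)` — affine and nondecreasing in `f`.
#'
#' @param orr_cc Observed concordant-positive ORR in percent.
#' @param f Imputation fraction in `[0, 1]`.
#' @param w A [weight_scheme()] or a bare weight in (0, 1].
#' @return Weighted overall ORR in percent (full precision).
#' @export
weighted_orr_point <- function(orr_cc, f, w) {
  if (inherits(w, "weight_scheme")) w <- w$w_concordant
  if (!is.numeric(w) || w <= 0 || w > 1) stop("weight must be in (0, 1]")
  if (!is.numeric(f) || any(f < 0) || any(f > 1))
    stop("f must lie in [0, 1]")
  if (!is.numeric(orr_cc) || any(orr_cc < 0) || any(orr_cc > 100))
    stop("orr_cc must be a percentage in [0, 100]")
  orr_cc * (w + (1 - w) * f)
}

#' Percentile-bootstrap CI for the weighted ORR
#'
#' Resamples the concordant-positive patients with replacement, recomputes
#' their ORR on each resample, applies [weighted_orr_point()] with the same
#' weight and fraction, and takes the percentile interval of the resulting
#' weighted statistics. The hypothetical discordant ORR is deterministic
#' given `f` (it is defined as a fraction of the resampled concordant ORR),
#' so all bootstrap uncertainty comes from the concordant stratum.
#'
#' @param outcomes data.frame of concordant-positive patient outcomes
#'   (columns `treated`, `response`).
#' @param w A [weight_scheme()] or bare weight.
#' @param f Imputation fraction in `[0, 1]`.
#' @param n_boot Number of bootstrap resamples (>= 200; default 2000).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param conf_level Two-sided confidence level, default 0.95.
#' @return Numeric length-2 `c(ci_low, ci_high)` in percent.
#' @export
bootstrap_weighted_ci <- function(outcomes, w, f, n_boot = 2000, seed,
                                  conf_level = 0.95) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer seed is required")
  if (!is.numeric(n_boot) || n_boot < 200)
    stop("n_boot must be at least 200")
  df <- outcomes[as.logical(outcomes$treated), , drop = FALSE]
  if (!nrow(df)) stop("no treated concordant-positive patients")
  resp <- df$response %in% c("CR", "PR")
  n <- length(resp)
  stat <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    orr_star <- 100 * colMeans(matrix(resp[idx], nrow = n))
    weighted_orr_point(orr_star, f, w)
  })
  alpha <- 1 - conf_level
  unname(stats::quantile(stat, c(alpha / 2, 1 - alpha / 2)))
}

#' Weighted-ORR scenario table
#'
#' One row per imputation fraction: the hypothetical discordant ORR
#' (`f * ORR_cc`), the weighted overall ORR, and its percentile-bootstrap
#' CI. The `f = 1` scenario equals the observed concordant ORR; the
#' `f = 0` scenario equals `w * ORR_cc` (the calibration anchor when `w`
#' comes from [calibrate_weight()]).
#'
#' @param outcomes data.frame of concordant-positive patient outcomes.
#' @param w A [weight_scheme()] or bare weight.
#' @param f_list Imputation fractions in `[0, 1]`; default
#'   `c(0, 0.25, 0.5, 0.75, 1)`.
#' @param n_boot Bootstrap resamples per scenario (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Two-sided confidence level, default 0.95.
#' @return data.frame with columns `fraction`, `hypothetical_orr`,
#'   `weighted_orr`, `ci_low`, `ci_high` (percent, full precision);
#'   attributes `orr_cc`, `w`, `n_boot`, `seed`.
#' @export
scenario_table <- function(outcomes, w, f_list = c(0, 0.25, 0.5, 0.75, 1),
                           n_boot = 2000, seed, conf_level = 0.95) {
  if (any(f_list < 0 | f_list > 1)) stop("f_list must lie within [0, 1]")
  est <- orr(outcomes, subgroup = "concordant_positive")
  orr_cc <- est$estimate$point
  rows <- lapply(seq_along(f_list), function(i) {
    f <- f_list[i]
    ci <- bootstrap_weighted_ci(outcomes, w, f, n_boot = n_boot,
                                seed = seed + i - 1L,
                                conf_level = conf_level)
    data.frame(fraction = f,
               hypothetical_orr = f * orr_cc,
               weighted_orr = weighted_orr_point(orr_cc, f, w),
               ci_low = ci[1], ci_high = ci[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "orr_cc") <- orr_cc
  attr(out, "w") <- if (inherits(w, "weight_scheme")) w$w_concordant else w
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  out
}
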