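# Independent oracles and fixture builders used across the suite.

# Clopper-Pearson bounds by direct bisection on the binomial tail
# probabilities (independent of the qbeta route in the package).
cp_bisect <- function(x, n, conf_level = 0.95, tol = 1e-9) {
  alpha <- 1 - conf_level
  bisect <- function(f, lo, hi) {
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  low <- if (x == 0) 0 else
    bisect(function(p) (1 - pbinom(x - 1, n, p)) - alpha / 2, 0, x / n)
  high <- if (x == n) 1 else
    bisect(function(p) alpha / 2 - pbinom(x, n, p), x / n, 1)
  100 * c(low, high)
}

# Brute-force qualitative decision function: the full precedence cascade
# written as one nested conditional, used to cross-check call_sample()
# by exhaustive enumeration.
oracle_status <- function(run_valid, rna, ic_ok, n_pos) {
  if (!is.na(rna) && rna < 18) return("insufficient")
  if (!run_valid || !ic_ok) return("invalid")
  if (n_pos > 0) "fgfr_positive" else "fgfr_negative"
}

# A Ct profile with exactly n_pos positive targets, everything else
# undetermined.
profile_with <- function(n_pos, panel = fgfr_panel()) {
  ct <- rep(NA_real_, nrow(panel))
  names(ct) <- panel$target
  if (n_pos > 0) ct[seq_len(n_pos)] <- panel$ct_cutoff[seq_len(n_pos)] - 2
  ct
}

# Paired calls realising given 2x2 counts (a=idx+/ref+, b=idx+/ref-,
# c=idx-/ref+, d=idx-/ref-).
pairs_from_counts <- function(a, b, c, d) {
  data.frame(
    index_call = rep(c("positive", "positive", "negative", "negative"),
                     c(a, b, c, d)),
    ref_call = rep(c("positive", "negative", "positive", "negative"),
                   c(a, b, c, d)),
    stringsAsFactors = FALSE)
}

# Treated patient outcomes with x responders of n, constant covariates.
outcomes_xn <- function(x, n, alteration = "S249C", chemo = TRUE,
                        cta = "positive", cdx = "positive") {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    treated = TRUE,
    response = rep(c("PR", "SD"), c(x, n - x)),
    alteration = alteration, chemo_refractory = chemo,
    cta_call = cta, cdx_call = cdx, stringsAsFactors = FALSE)
}

# The treated CTA+ study population consistent with the printed totals:
# 81 concordant-positive patients with 37 responders (69 of them
# chemo-refractory with 32 responders), plus 18 CTA+ patients without a
# valid CDx-positive result carrying the remaining 3 responders (40/99
# overall among CTA+).
bridging_outcomes <- function() {
  cc_chemo <- outcomes_xn(32, 69, chemo = TRUE)
  cc_other <- outcomes_xn(5, 12, chemo = FALSE)
  disc <- outcomes_xn(3, 18, chemo = TRUE, cdx = "invalid")
  out <- rbind(cc_chemo, cc_other, disc)
  out$patient_id <- sprintf("P%03d", seq_len(nrow(out)))
  out
}
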