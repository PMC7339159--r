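---
title: "Statistical methods of the FGFR CDx bridging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of the FGFR CDx bridging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgfrbridge)
```

## The problem

A companion diagnostic (CDx) is approved on the claim that it selects the
same benefiting patient population as the clinical trial assay (CTA) that
enrolled the pivotal trial. A bridging study makes that claim quantitative:
archived samples from the trial's screened population are re-tested with
the CDx, agreement between the paired calls is estimated with confidence
intervals, accuracy is checked against an orthogonal reference method
(droplet digital PCR), and the clinical efficacy endpoint — objective
response rate (ORR) — is re-estimated in the CDx-selected population under
a pre-specified decision rule. `fgfrbridge` implements that entire
pipeline for a qualitative multiplex RT-PCR panel of nine FGFR2/3
alterations (four FGFR3 point mutations: R248C, S249C, G370C, Y373C; five
fusions: FGFR3-TACC3_V1, FGFR3-TACC3_V3, FGFR3-BAIAP2L1, FGFR2-CASP7,
FGFR2-BICC1) in urothelial carcinoma, plus a synthetic-cohort generator so
every stage runs and is tested with no external data.

## The qualitative call engine

A sample's FGFR status is decided by a cascade with strict precedence,
mirroring the three disjoint accounting categories of a bridging report
(valid result / insufficient / invalid):

1. **Pre-analytical sufficiency.** If the RNA concentration is known and
   below the minimum input (default 18 ng/uL, boundary inclusive — exactly
   the minimum is sufficient), the sample is `insufficient` and nothing
   downstream is evaluated.
2. **Analytical validity.** If the PCR run failed its controls, or the
   sample's internal-control Ct is undetermined or outside its acceptance
   interval, the sample is `invalid`. A run fails when any positive
   template control falls outside its acceptance Ct range or any
   no-template control amplifies at or below the analytic range
   (contamination); late nonspecific NTC signal above the cut-off is
   tolerated.
3. **Target calls.** A target is positive when its Ct is *less than or
   equal to* its cut-off (the boundary is inclusive); an undetermined Ct is
   negative. The sample is `fgfr_positive` with all positive targets
   listed if at least one target calls positive, else `fgfr_negative`.

The commercial assay's per-target Ct cut-offs are proprietary and have
never been published; only the comparison rule is public. The package
therefore treats cut-offs as configuration with a synthetic default of
33.0 cycles for every target, and the internal-control acceptance interval
defaults to the synthetic [20, 35]. These constants shape only the
simulator and the tests, never a published number. Undetermined Ct values
are written to files as the literal string `"undetermined"` and held in
memory as `NA`, so they can never be confused with a numeric threshold
comparison.

## Agreement statistics and interval choices

Concordance between CDx and CTA is summarised by positive, negative and
overall percent agreement over the oriented 2x2 table (reference on
columns): PPA = a/(a+c), NPA = d/(b+d), OPA = (a+d)/N. Pairs where either
assay is invalid or insufficient are excluded from the table (the study N
drops from 300 to 292) and surface only in the validity tally.

Two binomial interval methods are first-class:

- the **Wilson score interval**, the closed-form inversion of the normal
  score test, and
- the **Clopper–Pearson "exact" interval**, the inversion of the binomial
  tail probabilities computed via beta quantiles.

The study protocol language says "exact" throughout, but the printed
concordance and efficacy intervals are reproduced digit-for-digit by the
Wilson interval (82/94 → 79.0–92.5; 37/81 → 35.3–56.5), while the accuracy
study's intervals are reproduced by Clopper–Pearson (103/104 →
94.76–99.98). We verified this numerically before freezing defaults:
`percent_agreement()` defaults to Wilson, the accuracy analysis uses
Clopper–Pearson, and either can be requested anywhere. The discrepancy
between wording and arithmetic is inherent to the source material and is
left visible rather than resolved. (One further outlier: the ORR of 40/99
among all reference-positive treated patients prints with a Wald interval,
30.7–50.1; the package intentionally offers only Wilson and
Clopper–Pearson, so that interval is not reproduced.)

Decision rules are CI-based: the accuracy study passes when the lower
limit of the exact interval is at least 85% for PPA **and** at least 90%
for NPA (inclusive floors); the primary efficacy objective is met when the
lower bound of the ORR interval strictly exceeds 25%.

Internally every estimate is carried at full precision; rounding to the
presentation precision (1 decimal for agreement/efficacy tables, 2
decimals for the accuracy table) happens only in formatting and
serialisation.

## ORR and the weighted-ORR imputation analysis

ORR is the share of treated patients with complete or partial response,
over *all* treated patients — non-evaluable patients stay in the
denominator. Subgroup tables report each alteration, the point-mutation
and fusion class aggregates, and the overall row; in the package's data
model each patient carries a single primary alteration, so per-target
counts partition the cohort exactly. (Published per-row counts need not be
disjoint when patients harbour multiple alterations, so aggregates in
external tables can differ from the sum of their rows; the package's
invariant applies to its own data model.) Zero-denominator subgroups are
rendered as a dash, not 0.0.

Discordant-positive patients (CDx+/CTA−) were never treated — the trial
enrolled on the CTA — so their ORR is unobservable and the overall
CDx-positive ORR must be a **weighted average** of an observed and a
hypothetical stratum:

$$\mathrm{ORR}_w(f) = w\,\mathrm{ORR}_{cc} + (1-w)\,f\,\mathrm{ORR}_{cc}
 = \mathrm{ORR}_{cc}\,(w + (1-w)f), \qquad f \in \{0, .25, .5, .75, 1\}$$

where ORR~cc~ is the observed concordant-positive ORR and the hypothetical
discordant ORR is a stated fraction *f* of it. The weights themselves were
never published. The package's default is **calibration**: choose *w* so
the *f* = 0 scenario equals the ORR observed among all reference-positive
treated patients (40/99), giving *w* = (40/99)/(37/81) ≈ 0.8845 — this
reproduces every published scenario point (40.4, 41.7, 43.0, 44.4, 45.7).
An alternative **prevalence model**, *w* = p·PPA / (p·PPA + (1−p)(1−NPA)),
is provided as an interpretation, not ground truth; at p = 0.21 with the
observed agreement it yields 0.884, numerically consistent with the
calibrated weight. One scenario label in the published table reads "20% ×
observed" while its own hypothetical value equals 25% of the observed ORR
and the body text says 25%; the package uses *f* = 0.25.

Uncertainty comes from a **percentile bootstrap** (B = 2000 by default,
seed mandatory): concordant patients are resampled with replacement,
ORR~cc~ recomputed, and the weighted point re-evaluated — the hypothetical
stratum is deterministic given *f*, so all bootstrap variation comes from
the concordant stratum. The original bootstrap details (resampling scheme,
B, interval type) are unstated in the source material, so the bootstrap
intervals are checked only as properties: seeded bit-reproducibility, and
at *f* = 1 agreement with the Wilson interval of 37/81 within about 2
percentage points. BCa correction was considered and rejected: with a
simple proportion and n = 81 the percentile and BCa intervals differ by
less than the reporting precision.

## Representativeness testing

Tested and not-tested patients are compared variable by variable:
two-group *t*-tests for continuous baseline measures and Pearson
chi-square for categorical ones, flagged at alpha = 0.05. Two choices were
open and were settled by arithmetic on the published summary table:

- **Pooled vs Welch *t*.** The pooled-variance statistic (df =
  n₁ + n₂ − 2) reproduces the printed p-values from the rounded printed
  summaries (age 0.66, tumor area 0.95, viable cells 0.01); pooled is the
  default and Welch is available by flag. Because the test is computed
  from (n, mean, sd) triples it is exact: it equals the test on any raw
  dataset with those moments, which the suite verifies by constructing
  two-point samples.
- **Continuity correction.** The uncorrected chi-square reproduces the
  printed categorical p-values (region 0.16, race 0.11, ethnicity 0.02,
  sex 0.82, site 0.07); no correction is applied. Categories with zero
  count in one group are retained (site "Unknown" 0 vs 1); categories
  absent from both groups have expected count zero and are rejected.

## The synthetic cohort generator

`cohort_config()` freezes the simulated study conditions; the defaults are
the package's statement of what a realistic screened population looks
like:

| parameter | default | basis |
|---|---|---|
| screened population | 2,000 | same order as a large phase-2 screening program |
| tested subset | 100 reference-positive + 200 reference-negative | the bridging design |
| total alteration prevalence | 0.18 | mUC literature (~15%) and the weight calibration (~21%) |
| per-target split | proportional to observed subgroup sizes | S249C most common; 0.5 pseudo-count keeps never-observed fusions possible |
| P(CDx+\|CTA+), P(CDx+\|CTA−) | 0.872, 0.030 | the observed agreement table |
| invalid / insufficient rates | 0.017 / 0.010 | the observed sample accounting |
| response probabilities | per-target observed ORRs; 0.457 where unobserved | the efficacy table |
| treated fraction of CTA+ | 0.99 | 99 of 100 reference-positive patients treated |
| chemo-refractory share | 87/99 | the treated population |
| demographics | Normal/categorical per the screened-population summaries | the baseline table |

Two generation paths exist by design. The *statistical* path draws calls
directly from the conditional probabilities above and is what the
parameter-recovery tests use. The *mechanistic* path
(`generate_ct_profiles()`) expresses the same latent calls as Ct values —
positive targets draw from Normal(cutoff − 5, 1), negative targets are
undetermined with probability 0.98 or draw from Normal(cutoff + 4, 1),
invalid samples get an undetermined internal control, insufficient samples
a below-minimum RNA concentration — and is the only path that exercises
the call engine end to end (the tail probability of a miscall is
Φ(−5) ≈ 3·10⁻⁷ per target, so engine output reproduces the latent calls).
Reference-negative patients are never treated and carry no response,
which is precisely why the weighted-ORR imputation exists downstream.

What the generator does **not** emulate: tumor heterogeneity, RNA
degradation, batch effects, or correlated errors between the CDx and the
orthogonal ddPCR method. The last one matters: the simulator draws ddPCR
near truth and the CDx conditionally on the CTA, so simulated CDx-vs-ddPCR
agreement sits near the CDx's truth-sensitivity (~0.85) and the accuracy
floors can fail on synthetic data, whereas the real accuracy study found
CDx and ddPCR in near-perfect agreement (the CTA was the outlier). Passing
tests on synthetic cohorts therefore demonstrate correctness of the
estimators and decision rules, not the clinical performance of any assay.

## Numerical and degenerate-input choices

- Proportion CIs: x = 0 pins the exact lower bound at 0, x = n the upper
  at 100; the Wilson interval is clipped to [0, 100] against floating-point
  spill. Wilson bounds agree with `prop.test(correct = FALSE)` to 1e-8 and
  Clopper–Pearson with both `binom.test()` and a bisection oracle on the
  binomial tails to 1e-6.
- PPA is undefined (an error, not NaN) when no reference-positive pairs
  exist; likewise NPA with no reference-negative pairs. An ORR subset with
  no treated patients errors with the subgroup name.
- A non-binary call inside a 2x2 is an error naming the offending sample;
  exclusion of invalid pairs is an explicit upstream step, never silent.
- The *t*-test rejects two constant groups with equal means (the statistic
  is 0/0); chi-square rejects any zero expected cell.
- Bootstrap seeds are mandatory arguments — there is no silent global-RNG
  path; scenario rows use consecutive derived seeds so that adding a
  fraction never changes the other rows' intervals.
- Problem sizes used by the test-suite: exhaustive call-engine decision
  table (2 x 3 x 4 x 10 states), all Clopper–Pearson pairs to n = 50
  against the bisection oracle, 2,000-replicate coverage runs at p ∈
  {0.5, 0.9, 0.97}, n ∈ {50, 200}, and a 20,000-patient recovery cohort —
  sizes at which binomial standard errors make the checks sharp.

## A worked example

```{r example}
coh <- generate_cohort(cohort_config(seed = 42))
prof <- generate_ct_profiles(coh)
dir <- tempfile()
files <- write_cohort(coh, dir, prof)

report <- run_pipeline(
  demographics = read_demographics(files[["demographics"]]),
  outcomes     = read_outcomes(files[["outcomes"]]),
  paired_calls = read_paired_calls(files[["paired_calls"]]),
  ct_table     = read_ct_table(files[["ct_table"]]),
  run_controls = read_run_controls(files[["run_controls"]]),
  seed = 7, n_boot = 500, quiet = TRUE)
report
```

## Limitations

The package analyses calls, counts and outcomes; it does not process
fluorescence curves, model multiplex chemistry (blocking oligonucleotides
exist only as an error-rate abstraction), or handle time-to-event
endpoints. The weighted-ORR weights are reconstructions — calibrated or
model-based — because the originals were never published; both are
documented as such and the calibrated default is anchored to a printed,
reproducible number.
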