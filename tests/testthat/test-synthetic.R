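test_that("cohort generation is reproducible and validates its config", {
  cfg <- cohort_config(n_screened = 500, seed = 5)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  c3 <- generate_cohort(cohort_config(n_screened = 500, seed = 6))
  expect_false(identical(c1$patients, c3$patients))
  expect_error(cohort_config(prevalence = 1.5, seed = 1), "\\[0, 1\\]")
  expect_error(cohort_config(seed = 1, target_weights = c(R248C = 1)),
               "all panel targets")
  expect_error(cohort_config(n_screened = 10), "seed")
})

test_that("perfect assays give perfect agreement on the generated cohort", {
  cfg <- cohort_config(n_screened = 800, cta_sensitivity = 1,
                       cta_specificity = 1, p_cdx_pos_given_cta_pos = 1,
                       p_cdx_pos_given_cta_neg = 0, invalid_rate = 0,
                       insufficient_rate = 0, seed = 12)
  coh <- generate_cohort(cfg)
  tst <- coh$patients[coh$patients$tested, ]
  tab <- build_2x2(tst$cdx_call, tst$cta_call)
  est <- percent_agreement(tab)
  expect_equal(c(est$ppa$point, est$npa$point, est$opa$point),
               c(100, 100, 100))
})

test_that("marginal frequencies recover the configured parameters at
           n = 20000", {
  cfg <- cohort_config(n_screened = 20000, n_tested_pos = 20000,
                       n_tested_neg = 20000, invalid_rate = 0,
                       insufficient_rate = 0,
                       response_prob = setNames(rep(0.457, 9),
                                                fgfr_panel()$target),
                       response_default = 0.457, seed = 88)
  coh <- generate_cohort(cfg)
  p <- coh$patients
  se2 <- function(ph, n) 2 * sqrt(ph * (1 - ph) / n)

  cta_pos <- p$cta_call == "positive"
  ppa_hat <- mean(p$cdx_latent[cta_pos] == "positive")
  expect_lt(abs(ppa_hat - 0.872), se2(0.872, sum(cta_pos)) + 0.001)
  npa_hat <- mean(p$cdx_latent[!cta_pos] == "negative")
  expect_lt(abs(npa_hat - 0.970), se2(0.970, sum(!cta_pos)) + 0.001)

  treated <- p$treated
  orr_hat <- mean(p$response[treated] %in% c("CR", "PR"))
  expect_lt(abs(orr_hat - 0.457), se2(0.457, sum(treated)) + 0.001)

  prev_hat <- mean(p$true_alteration != "")
  expect_lt(abs(prev_hat - 0.18), se2(0.18, nrow(p)) + 0.001)
})

test_that("reference-negative patients are never treated and carry no
           response", {
  coh <- generate_cohort(cohort_config(n_screened = 1000, seed = 3))
  p <- coh$patients
  expect_false(any(p$treated & p$cta_call == "negative"))
  expect_true(all(is.na(p$response[!p$treated])))
  expect_false(any(is.na(p$response[p$treated])))
})

test_that("validity rates average to the configured accounting across
           seeds", {
  rates <- vapply(1:8, function(s) {
    coh <- generate_cohort(cohort_config(n_screened = 1200, seed = s))
    st <- coh$patients$sample_status
    mean(st[!is.na(st)] == "valid")
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.973), 0.01)

  clean <- generate_cohort(cohort_config(n_screened = 1200,
                                         invalid_rate = 0,
                                         insufficient_rate = 0, seed = 2))
  st <- clean$patients$sample_status
  expect_true(all(st[!is.na(st)] == "valid"))
})

test_that("mechanistic Ct profiles reproduce the cohort's calls through
           the call engine and round-trip through files", {
  coh <- generate_cohort(cohort_config(seed = 42))
  prof <- generate_ct_profiles(coh)
  # positive-target Ct mass below cut-off: Normal(cutoff - 5, 1) tail
  expect_gt(pnorm(5), 0.99)

  dir <- withr::local_tempdir()
  files <- write_cohort(coh, dir, prof)
  ctt <- read_ct_table(files[["ct_table"]])
  rc <- read_run_controls(files[["run_controls"]])
  expect_equal(nrow(ctt), sum(coh$patients$tested))

  rs <- validate_runs(rc)
  expect_true(all(rs == "valid"))
  calls <- call_samples(ctt, run_status = rs)
  tst <- coh$patients[coh$patients$tested, ]
  m <- merge(calls, tst[, c("patient_id", "cdx_call")],
             by.x = "sample_id", by.y = "patient_id")
  map <- c(fgfr_positive = "positive", fgfr_negative = "negative",
           invalid = "invalid", insufficient = "insufficient")
  expect_equal(unname(map[m$status]), m$cdx_call)
})

test_that("degenerate configurations stay structurally valid", {
  none <- generate_cohort(cohort_config(n_screened = 300, prevalence = 0,
                                        cta_sensitivity = 1,
                                        cta_specificity = 1, seed = 4))
  expect_true(all(none$patients$cta_call == "negative"))
  expect_false(any(none$patients$treated))

  all_alt <- generate_cohort(cohort_config(n_screened = 300,
                                           prevalence = 1, seed = 4))
  expect_true(all(all_alt$patients$true_alteration != ""))

  broke <- generate_cohort(cohort_config(n_screened = 300,
                                         invalid_rate = 1,
                                         insufficient_rate = 0, seed = 4))
  st <- broke$patients$sample_status
  expect_true(all(st[!is.na(st)] == "invalid"))
  expect_error(tally_validity(character(0)))
})

test_that("written cohort files are byte-identical given the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    coh <- generate_cohort(cohort_config(n_screened = 400, seed = 77))
    write_cohort(coh, d, generate_ct_profiles(coh))
  }
  for (f in c("demographics.csv", "outcomes.csv", "paired_calls.csv",
              "ct_table.csv", "run_controls.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
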