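test_that("panel configuration has four point mutations and five fusions", {
  p <- fgfr_panel()
  expect_equal(sum(p$alteration_class == "point_mutation"), 4)
  expect_equal(sum(p$alteration_class == "fusion"), 5)
  expect_true(all(p$ct_cutoff > 0))
  expect_error(fgfr_panel(-1), "positive")
  expect_error(fgfr_panel(c(R248C = 33)), "all nine")
})

test_that("RNA sufficiency threshold is inclusive at the minimum", {
  expect_equal(check_rna_sufficiency(18, 18), "sufficient")
  expect_equal(check_rna_sufficiency(0, 18), "insufficient")
  expect_equal(check_rna_sufficiency(17.9, 18), "insufficient")
  expect_error(check_rna_sufficiency(-1, 18), "nonnegative")
})

test_that("target call boundary is inclusive and undetermined is negative", {
  expect_equal(call_target(33.0, 33.0), "positive")
  expect_equal(call_target(NA, 33.0), "negative")
  expect_equal(call_target(33.01, 33.0), "negative")
  expect_equal(call_target(1e-6, 33.0), "positive")
  expect_error(call_target(30, -1), "positive")
})

test_that("run validation checks PTCs in range and NTCs for contamination", {
  p <- fgfr_panel()
  ptc <- setNames(rep(25, 9), p$target)
  ntc <- setNames(rep(NA_real_, 9), p$target)
  expect_equal(validate_run(ptc, ntc, p)$status, "valid")

  bad_ptc <- ptc; bad_ptc["S249C"] <- 31.5
  r <- validate_run(bad_ptc, ntc, p)
  expect_equal(r$status, "invalid")
  expect_match(r$reasons, "S249C", all = FALSE)

  # NTC amplifying inside the analytic range is contamination
  bad_ntc <- ntc; bad_ntc["BICC1"] <- 28
  r2 <- validate_run(ptc, bad_ntc, p)
  expect_equal(r2$status, "invalid")
  expect_match(r2$reasons, "contamination", all = FALSE)
  # late NTC signal above the cut-off is tolerated
  late <- ntc; late["BICC1"] <- 38
  expect_equal(validate_run(ptc, late, p)$status, "valid")

  expect_error(validate_run(ptc[-1], ntc, p), "every panel target")
})

test_that("sample decision cascade matches the brute-force oracle on the
           full decision table", {
  panel <- fgfr_panel()
  rna_levels <- list(NA_real_, 10, 40)
  ic_levels <- list(pass = 27, low = 15, high = 40, und = NA_real_)
  for (run_valid in c(TRUE, FALSE))
    for (rna in rna_levels)
      for (ic_name in names(ic_levels))
        for (n_pos in 0:9) {
          got <- call_sample(profile_with(n_pos, panel),
                             ic_levels[[ic_name]], panel,
                             run_status = if (run_valid) "valid" else
                               "invalid",
                             rna_conc = rna)
          want <- oracle_status(run_valid, rna, ic_name == "pass", n_pos)
          expect_equal(got$status, want,
                       info = sprintf("run=%s rna=%s ic=%s npos=%d",
                                      run_valid, rna, ic_name, n_pos))
          expect_equal(length(got$positive_targets),
                       if (want == "fgfr_positive") n_pos else 0L)
        }
})

test_that("lowering a single target Ct never flips positive to negative", {
  panel <- fgfr_panel()
  set.seed(11)
  for (i in 1:50) {
    ct <- setNames(runif(9, 25, 40), panel$target)
    ct[runif(9) < 0.4] <- NA
    before <- call_sample(ct, 27, panel)$status
    j <- sample(9, 1)
    ct2 <- ct
    ct2[j] <- if (is.na(ct[j])) 30 else max(ct[j] - runif(1, 0, 10), 0.5)
    after <- call_sample(ct2, 27, panel)$status
    expect_false(before == "fgfr_positive" && after == "fgfr_negative")
  }
})

test_that("validity tally reproduces the 292/3/5 accounting and sums to 100", {
  st <- rep(c("fgfr_positive", "fgfr_negative", "insufficient", "invalid"),
            c(88, 204, 3, 5))
  t1 <- tally_validity(st)
  expect_equal(t1$percent[t1$category == "valid"], 97.3)
  expect_equal(t1$percent[t1$category == "insufficient"], 1.0)
  expect_equal(t1$percent[t1$category == "invalid"], 1.7)
  expect_equal(sum(t1$n), 300)
  expect_lt(abs(sum(t1$percent) - 100), 0.3)

  t2 <- tally_validity(rep("fgfr_negative", 10))
  expect_equal(t2$percent[t2$category == "valid"], 100.0)
  t3 <- tally_validity(rep(c("fgfr_negative", "invalid"), c(4, 4)))
  expect_equal(t3$percent[t3$category == "valid"], 50.0)
  expect_error(tally_validity(character(0)), "no sample calls")
  expect_error(tally_validity("oops"), "unknown status")
})

test_that("batch calling joins run status and reports semicolon lists", {
  panel <- fgfr_panel()
  ct <- as.data.frame(as.list(setNames(c(30, 31, rep(NA, 7)),
                                       panel$target)))
  tab <- data.frame(sample_id = c("s1", "s2"),
                    run_id = c("r1", "r2"), rbind(ct, ct),
                    internal_control_ct = c(27, 27), rna_conc = c(40, 40))
  calls <- call_samples(tab, run_status = c(r2 = "invalid"), panel = panel)
  expect_equal(calls$status, c("fgfr_positive", "invalid"))
  expect_equal(calls$positive_targets[1], "R248C;S249C")
  expect_equal(calls$positive_targets[2], "")
})
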