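test_that("Wilson interval reproduces the published agreement intervals", {
  expect_equal(round(wilson_ci(82, 94), 1), c(79.0, 92.5))
  expect_equal(round(wilson_ci(37, 81), 1), c(35.3, 56.5))
  expect_equal(wilson_ci(0, 10)[1], 0)
  # independent cross-check: score test inversion in stats::prop.test
  for (xn in list(c(82, 94), c(37, 81), c(5, 20), c(1, 7))) {
    ref <- 100 * suppressWarnings(
      prop.test(xn[1], xn[2], correct = FALSE))$conf.int
    expect_equal(wilson_ci(xn[1], xn[2]), as.numeric(ref), tolerance = 1e-8)
  }
})

test_that("Wilson interval is complement-symmetric", {
  for (n in c(7, 50, 292)) for (x in c(0, 1, floor(n / 3), n)) {
    ci <- wilson_ci(x, n)
    co <- wilson_ci(n - x, n)
    expect_equal(ci, 100 - rev(co), tolerance = 1e-9)
  }
})

test_that("Clopper-Pearson reproduces the published exact intervals and
           pins degenerate bounds", {
  expect_equal(round(clopper_pearson_ci(103, 104), 2), c(94.76, 99.98))
  expect_equal(clopper_pearson_ci(10, 10)[2], 100)
  expect_equal(clopper_pearson_ci(0, 10)[1], 0)
  ci <- clopper_pearson_ci(5, 20)
  expect_true(ci[1] < 25 && ci[2] > 25)
  wi <- wilson_ci(5, 20)
  expect_true(ci[2] - ci[1] >= wi[2] - wi[1])  # exact is conservative
  # independent cross-check against stats::binom.test
  for (xn in list(c(103, 104), c(5, 20), c(0, 15), c(7, 7))) {
    ref <- 100 * binom.test(xn[1], xn[2])$conf.int
    expect_equal(clopper_pearson_ci(xn[1], xn[2]), as.numeric(ref),
                 tolerance = 1e-8)
  }
})

test_that("Clopper-Pearson equals bisection on binomial tails for all
           x, n <= 50", {
  for (n in 1:50) for (x in 0:n) {
    expect_equal(clopper_pearson_ci(x, n), cp_bisect(x, n),
                 tolerance = 1e-6, info = sprintf("x=%d n=%d", x, n))
  }
})

test_that("CI bounds are monotone nondecreasing in x for fixed n", {
  for (n in c(10, 81)) {
    for (f in list(wilson_ci, clopper_pearson_ci)) {
      b <- t(vapply(0:n, function(x) f(x, n), numeric(2)))
      expect_true(all(diff(b[, 1]) >= -1e-9))
      expect_true(all(diff(b[, 2]) >= -1e-9))
    }
  }
})

test_that("both interval methods achieve near-nominal coverage", {
  set.seed(97)
  for (p in c(0.5, 0.9, 0.97)) for (n in c(50, 200)) {
    x <- rbinom(2000, n, p)
    for (m in c("wilson", "clopper_pearson")) {
      ci <- vapply(x, function(xi) switch(m,
        wilson = wilson_ci(xi, n),
        clopper_pearson = clopper_pearson_ci(xi, n)), numeric(2))
      cover <- mean(ci[1, ] <= 100 * p & 100 * p <= ci[2, ])
      expect_gte(cover, 0.95 - 0.02)
      if (m == "clopper_pearson") expect_gte(cover, 0.95)
    }
  }
})

test_that("2x2 construction fixes orientation and rejects non-binary calls", {
  p <- pairs_from_counts(82, 6, 12, 192)
  tab <- build_2x2(p$index_call, p$ref_call,
                   index_name = "CDx", ref_name = "CTA")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(82, 6, 12, 192))
  expect_equal(tab$n, 292)

  expect_error(build_2x2(character(0), character(0)), "no paired calls")
  allpos <- build_2x2(rep("positive", 5), rep("positive", 5))
  expect_equal(c(allpos$a, allpos$b, allpos$c, allpos$d), c(5, 0, 0, 0))
  expect_error(
    build_2x2(c("positive", "invalid"), c("positive", "negative"),
              sample_id = c("s1", "s2")),
    "s2")
  expect_error(agreement_table(1, -1, 0, 0), "nonnegative")
  expect_error(agreement_table(0, 0, 0, 0), "empty")
})

test_that("percent agreement reproduces the published concordance and
           accuracy tables", {
  t2 <- percent_agreement(agreement_table(82, 6, 12, 192), "wilson")
  expect_equal(round(t2$ppa$point, 1), 87.2)
  expect_equal(round(c(t2$ppa$ci_low, t2$ppa$ci_high), 1), c(79.0, 92.5))
  expect_equal(round(t2$npa$point, 1), 97.0)
  expect_equal(round(c(t2$npa$ci_low, t2$npa$ci_high), 1), c(93.5, 98.6))
  expect_equal(round(t2$opa$point, 1), 93.8)
  expect_equal(round(c(t2$opa$ci_low, t2$opa$ci_high), 1), c(90.5, 96.1))

  t3 <- percent_agreement(agreement_table(103, 5, 1, 197),
                          "clopper_pearson")
  expect_equal(round(t3$ppa$point, 2), 99.04)
  expect_equal(round(t3$npa$point, 2), 97.52)
  expect_equal(round(t3$opa$point, 2), 98.04)
  expect_equal(round(c(t3$npa$ci_low, t3$npa$ci_high), 2), c(94.32, 99.19))
  expect_equal(round(c(t3$opa$ci_low, t3$opa$ci_high), 2), c(95.78, 99.28))

  perfect <- percent_agreement(agreement_table(10, 0, 0, 10))
  expect_equal(c(perfect$ppa$point, perfect$npa$point, perfect$opa$point),
               c(100, 100, 100))
  expect_error(percent_agreement(agreement_table(0, 3, 0, 7)), "PPA")
  expect_error(percent_agreement(agreement_table(3, 0, 7, 0)), "NPA")
})

test_that("OPA identity holds exactly: OPA*N = PPA*(a+c) + NPA*(b+d)", {
  set.seed(5)
  for (i in 1:25) {
    cnt <- rmultinom(1, sample(20:400, 1), c(0.3, 0.05, 0.05, 0.6))[, 1] + 1
    e <- percent_agreement(agreement_table(cnt[1], cnt[2], cnt[3], cnt[4]))
    n <- sum(cnt)
    expect_equal(e$opa$point * n,
                 e$ppa$point * (cnt[1] + cnt[3]) +
                   e$npa$point * (cnt[2] + cnt[4]),
                 tolerance = 1e-9)
  }
})

test_that("accuracy decision applies inclusive CI-floor rules", {
  t3 <- percent_agreement(agreement_table(103, 5, 1, 197),
                          "clopper_pearson")
  d <- accuracy_decision(t3$ppa, t3$npa, 85, 90)
  expect_equal(d$decision, "pass")
  expect_true(all(d$detail$met))

  mk <- function(lo) {
    e <- proportion_estimate(1, 2)
    e$ci_low <- lo
    e
  }
  expect_equal(accuracy_decision(mk(84.9), mk(95), 85, 90)$decision, "fail")
  expect_equal(accuracy_decision(mk(85.0), mk(90.0), 85, 90)$decision,
               "pass")
})
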