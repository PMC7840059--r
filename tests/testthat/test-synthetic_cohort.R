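test_that("attainable scores and decompositions are consistent", {
  tb <- toy_table()
  att <- attainable_scores(tb)
  # toy table: age {0,5,8} + surgery {1,6} + comorbidity subset sums {0,2,4,6}
  expect_false(0 %in% att)  # no zero-point surgery exists
  expect_identical(max(att), max_attainable_score(tb))
  decomp <- score_decompositions(tb)
  for (i in seq_len(nrow(decomp))) {
    hand <- tb$age_bands$points[decomp$band[i]] +
      tb$surgeries$points[decomp$surgery[i]] +
      sum(tb$comorbidities$points[decomp$comorbidities[[i]]])
    expect_identical(as.integer(hand), decomp$score[i])
  }
  # default synthetic table attains every integer score up to its bound
  dtb <- default_point_table()
  expect_identical(attainable_scores(dtb), 0:max_attainable_score(dtb))
})

test_that("codes_for_score round-trips through the scoring engine", {
  dtb <- default_point_table()
  zero <- codes_for_score(0, dtb)
  expect_identical(zero$icd, character(0))
  case0 <- make_case(age = zero$age, icd = zero$icd, ops = zero$ops)
  expect_identical(score_case(case0, dtb)$score, 0L)

  maxs <- max_attainable_score(dtb)
  top <- codes_for_score(maxs, dtb)
  expect_identical(length(top$icd), nrow(dtb$comorbidities))  # all comorbidities
  expect_identical(score_case(make_case(age = top$age, icd = top$icd,
                                        ops = top$ops), dtb)$score, maxs)

  for (target in attainable_scores(toy_table())) {
    parts <- codes_for_score(target, toy_table())
    case <- make_case(age = parts$age, icd = parts$icd, ops = parts$ops)
    expect_identical(score_case(case, toy_table())$score, as.integer(target))
  }

  expect_error(codes_for_score(0, toy_table()),
               class = "gpospom_unattainable_score_error", regexp = "nearest")
})

test_that("fixture generation hits every stratum count exactly", {
  spec <- fixture_spec(n_total = 300, n_without_index = 60, n_minor = 40,
                       n_incomplete = 10, n_deaths_among_included = 9, seed = 101)
  reg <- generate_fixture(spec)
  expect_identical(nrow(reg), 300L)
  tb <- default_point_table()
  out <- apply_eligibility(reg, tb)
  expect_identical(out$report$n_no_index_procedure, 60L)
  expect_identical(out$report$n_under_18, 40L)
  expect_identical(out$report$n_incomplete, 10L)
  expect_identical(out$report$n_included, 190L)
  scored <- score_cases(out$included, tb)
  expect_identical(sum(scored$died), 9L)

  none <- generate_fixture(fixture_spec(n_total = 5, n_without_index = 0,
                                        n_minor = 0, n_incomplete = 0,
                                        n_deaths_among_included = 0, seed = 1))
  expect_identical(apply_eligibility(none, tb)$report$n_included, 5L)

  expect_error(fixture_spec(n_total = 10, n_without_index = 20, n_minor = 0,
                            n_incomplete = 0), class = "gpospom_spec_error")
  expect_error(fixture_spec(n_total = 10, n_without_index = 0, n_minor = 0,
                            n_incomplete = 0, n_deaths_among_included = 11),
               class = "gpospom_spec_error")
})

test_that("generation is deterministic given the seed, down to the CSV bytes", {
  spec <- fixture_spec(n_total = 150, n_without_index = 30, n_minor = 20,
                       n_incomplete = 6, n_deaths_among_included = 3, seed = 103)
  a <- generate_fixture(spec)
  b <- generate_fixture(spec)
  expect_identical(a, b)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_cases(a, pa); write_cases(b, pb)
  expect_identical(readLines(pa), readLines(pb))

  ca <- generate_statistical(cohort_spec(n = 500, seed = 107))
  cb <- generate_statistical(cohort_spec(n = 500, seed = 107))
  expect_identical(ca, cb)
})

test_that("statistical cohorts score back to their intended values exactly", {
  coh <- generate_statistical(cohort_spec(n = 2000, seed = 109))
  tb <- default_point_table()
  out <- apply_eligibility(coh, tb)
  expect_identical(out$report$n_included, 2000L)
  scored <- score_cases(out$included, tb)
  expect_identical(scored$score, as.integer(attr(coh, "intended_scores")))
})

test_that("a zero-variance spec collapses onto one attainable score", {
  coh <- generate_statistical(cohort_spec(n = 50, score_mean = 18,
                                          score_sd = 0, seed = 113))
  scored <- score_cases(coh, default_point_table())
  expect_true(all(scored$score == 18L))
})

test_that("empirical moments match the exact truncated-discretized pmf", {
  tb <- default_point_table()
  pmf <- score_distribution_pmf(tb)
  expect_equal(sum(pmf$prob), 1)
  exact_mean <- sum(pmf$score * pmf$prob)
  exact_sd <- sqrt(sum(pmf$prob * (pmf$score - exact_mean)^2))
  # truncation at zero lifts the mean above the 18.18 location parameter
  expect_gt(exact_mean, 18.18)

  n <- 20000
  coh <- generate_statistical(cohort_spec(n = n, seed = 127))
  scores <- attr(coh, "intended_scores")
  mc_sigma <- exact_sd / sqrt(n)
  expect_lt(abs(mean(scores) - exact_mean), 3 * mc_sigma)
})

test_that("a flat outcome link yields flat per-score mortality", {
  flat <- risk_map("logistic", intercept = qlogis(0.05), slope = 0)
  coh <- generate_statistical(cohort_spec(n = 20000, seed = 131), link = flat)
  scored <- score_cases(coh, default_point_table(), map = flat)
  ps <- per_score_mortality(scored)
  big <- ps[ps$n >= 200, ]
  # every well-filled score bin within 3 binomial sigmas of 5%
  sigma <- sqrt(0.05 * 0.95 / big$n)
  expect_true(all(abs(big$deaths / big$n - 0.05) < 3 * sigma + 1e-12))
})

test_that("scores outside the attainable range are rejected by the spec", {
  tb <- toy_table()
  expect_error(
    generate_statistical(cohort_spec(n = 10, score_mean = 1000, score_sd = 0,
                                     seed = 1), table = tb),
    class = "gpospom_spec_error"
  )
})
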