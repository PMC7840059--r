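test_that("age points come from the unique containing band", {
  tb <- toy_table()
  expect_identical(age_points(c(18L, 59L), tb), c(0L, 0L))
  expect_identical(age_points(60L, tb), 5L)
  expect_identical(age_points(c(80L, 99L), tb), c(8L, 8L))
  expect_error(age_points(17L, tb), class = "gpospom_precondition_error")

  set.seed(51)
  for (rep in 1:5) {
    rt <- random_toy_table()
    ages <- sample(18:99, 40, replace = TRUE)
    oracle <- vapply(ages, age_points_oracle, integer(1), table = rt)
    expect_identical(age_points(ages, rt), oracle)
  }
})

test_that("each comorbidity group scores at most once per case", {
  tb <- toy_table()
  expect_identical(comorbidity_points(make_case(icd = character(0)), tb)$points, 0L)
  res <- comorbidity_points(make_case(icd = c("I50.1", "I50.9")), tb)
  expect_identical(res$points, 4L)  # heart failure counted once
  expect_identical(res$matched[[1]], "heart_failure")
})

test_that("comorbidity matching equals the brute-force double-loop oracle", {
  set.seed(53)
  for (rep in 1:4) {
    rt <- random_toy_table()
    cases <- random_cases(25, rt)
    res <- comorbidity_points(cases, rt)
    for (i in seq_len(nrow(cases))) {
      oracle <- comorbidity_oracle(cases$icd_codes[[i]], rt)
      expect_identical(res$points[i], oracle$points)
      expect_identical(sort(res$matched[[i]]), sort(oracle$matched))
    }
  }
})

test_that("index-surgery selection follows chronology, then points, then name", {
  tb <- toy_table()
  one <- select_surgery(make_case(ops = "5-530"), tb)
  expect_identical(one$surgery_group, "hernia_repair")

  # chronology beats points: the earlier, cheaper hernia repair wins
  chrono <- make_case(ops = c("5-530", "5-511"),
                      ops_dates = c("2016-01-01", "2016-01-02"))
  expect_identical(select_surgery(chrono, tb)$surgery_group, "hernia_repair")

  # same date: the higher-scoring cholecystectomy wins
  tied <- make_case(ops = c("5-530", "5-511"),
                    ops_dates = c("2016-01-01", "2016-01-01"))
  expect_identical(select_surgery(tied, tb)$surgery_group, "cholecystectomy")
  expect_identical(select_surgery(tied, tb)$surgery_points, 6L)

  # all dates missing: treated as simultaneous, max points wins
  undated <- make_case(ops = c("5-530", "5-511"))
  expect_identical(select_surgery(undated, tb)$surgery_group, "cholecystectomy")

  # same date and points: lexicographic group name breaks the tie
  tb2 <- toy_table()
  tb2$surgeries$points <- c(6L, 6L)
  expect_identical(select_surgery(undated, tb2)$surgery_group, "cholecystectomy")

  expect_error(select_surgery(make_case(ops = "8-980"), tb),
               class = "gpospom_precondition_error")
})

test_that("an undated procedure ties with the earliest dated one", {
  tb <- toy_table()
  mixed <- make_case(ops = c("5-530", "5-511"),
                     ops_dates = c("2016-01-01", NA))
  expect_identical(select_surgery(mixed, tb)$surgery_group, "cholecystectomy")
})

test_that("score_case sums the three components on the toy table", {
  tb <- toy_table()
  zeroish <- score_case(make_case(age = 18, icd = character(0), ops = "5-530"), tb)
  expect_identical(zeroish$score, 1L)  # 0 age + 0 comorbidity + 1 surgery
  fifteen <- score_case(make_case(age = 60, icd = "I50.1", ops = "5-511"), tb)
  expect_identical(fifteen$score, 15L)  # 5 + 4 + 6, hand sum
  expect_identical(fifteen$age_points, 5L)
  expect_identical(fifteen$comorbidity_points, 4L)
  expect_identical(fifteen$surgery_points, 6L)
})

test_that("scores equal the composition of component oracles on random cases", {
  set.seed(59)
  for (rep in 1:4) {
    rt <- random_toy_table()
    cases <- random_cases(60, rt)
    elig <- apply_eligibility(cases, rt)$included
    if (nrow(elig) == 0) next
    scored <- score_cases(elig, rt)
    for (i in seq_len(nrow(elig))) {
      oracle <- age_points_oracle(elig$age[i], rt) +
        comorbidity_oracle(elig$icd_codes[[i]], rt)$points +
        scored$surgery_points[i]
      expect_identical(scored$score[i], as.integer(oracle))
    }
    # additivity and boundedness
    expect_identical(scored$score, scored$age_points + scored$comorbidity_points +
                       scored$surgery_points)
    expect_true(all(scored$score >= 0 & scored$score <= max_attainable_score(rt)))
  }
})

test_that("duplicated codes never change the score; new matches never lower it", {
  set.seed(61)
  tb <- toy_table()
  cases <- random_cases(80, tb)
  elig <- apply_eligibility(cases, tb)$included
  base <- score_cases(elig, tb)

  doubled <- elig
  doubled$icd_codes <- lapply(doubled$icd_codes, function(x) c(x, x))
  expect_identical(score_cases(doubled, tb)$score, base$score)

  added <- elig
  added$icd_codes <- lapply(added$icd_codes, function(x) c(x, "J44.9"))
  expect_true(all(score_cases(added, tb)$score >= base$score))
})

test_that("point decomposition totals, shares and degenerate cohorts", {
  zero <- decompose_points(fake_scored(0L, FALSE))
  expect_identical(zero$total_points, 0)
  expect_identical(unname(zero$shares), c(0, 0, 0))

  # two cases: one only age points, one only surgery points
  two <- fake_scored(c(3L, 3L), c(FALSE, FALSE))
  two$age_points <- c(3L, 0L); two$surgery_points <- c(0L, 3L)
  two$comorbidity_points <- c(0L, 0L)
  d <- decompose_points(two)
  expect_equal(unname(d$shares), c(0, 50, 50))
  expect_equal(d$total_points, 6)

  # shares always sum to 100 within rounding on random cohorts
  set.seed(63)
  tb <- toy_table()
  scored <- score_cases(apply_eligibility(random_cases(100, tb), tb)$included, tb)
  d2 <- decompose_points(scored)
  expect_lt(abs(sum(d2$shares) - 100), 0.02)
  expect_equal(d2$comorbidity_points_total + d2$age_points_total +
                 d2$surgery_points_total, d2$total_points)
})

test_that("cohort mean score equals total points over n", {
  set.seed(67)
  tb <- toy_table()
  scored <- score_cases(apply_eligibility(random_cases(150, tb), tb)$included, tb)
  d <- decompose_points(scored)
  expect_equal(mean(scored$score), d$total_points / nrow(scored))
})
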