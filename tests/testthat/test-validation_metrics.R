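test_that("c-statistic handles perfect separation, all ties, and hand-counted ties", {
  expect_equal(c_statistic(c(1, 2, 3), c(FALSE, FALSE, TRUE)), 1.0)
  expect_equal(c_statistic(c(2, 2, 2, 2), c(FALSE, TRUE, FALSE, TRUE)), 0.5)
  # brute force over the 4 death-survivor pairs: (3 + 0.5) / 4
  expect_equal(c_statistic(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE)), 0.875)
  expect_error(c_statistic(1:3, c(TRUE, TRUE, TRUE)),
               class = "gpospom_undefined_statistic_error")
})

test_that("c-statistic equals the pairwise oracle and pROC on random cohorts", {
  set.seed(71)
  for (rep in 1:30) {
    n <- sample(5:150, 1)
    scores <- sample(0:30, n, replace = TRUE)
    outcomes <- runif(n) < 0.3
    if (!any(outcomes) || all(outcomes)) next
    expect_equal(c_statistic(scores, outcomes), auc_pairwise(scores, outcomes))
  }
  skip_if_not_installed("pROC")
  scores <- sample(0:40, 500, replace = TRUE)
  outcomes <- runif(500) < plogis(-4 + 0.1 * scores)
  expect_equal(c_statistic(scores, outcomes),
               as.numeric(pROC::auc(pROC::roc(outcomes, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("c-statistic is invariant to monotone transforms; complement flips it", {
  set.seed(73)
  scores <- sample(0:25, 80, replace = TRUE)
  outcomes <- runif(80) < 0.25
  outcomes[1] <- TRUE; outcomes[2] <- FALSE
  a <- c_statistic(scores, outcomes)
  expect_equal(c_statistic(scores^3 + 2, outcomes), a)  # strictly increasing on >=0
  expect_equal(c_statistic(scores, !outcomes), 1 - a)
})

test_that("the ROC curve is a proper monotone curve whose area is the c-statistic", {
  set.seed(79)
  scores <- sample(0:20, 200, replace = TRUE)
  outcomes <- runif(200) < plogis(-3 + 0.15 * scores)
  outcomes[1] <- TRUE; outcomes[2] <- FALSE
  roc <- roc_curve(scores, outcomes)
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(attr(roc, "auc"), c_statistic(scores, outcomes))
})

test_that("Brier score: perfect forecasts, hand value, prevalence identity", {
  expect_equal(brier(c(0, 1, 1), c(FALSE, TRUE, TRUE)), 0)
  expect_equal(brier(c(0.2, 0.8), c(FALSE, TRUE)), 0.04)  # (0.04 + 0.04) / 2
  # constant forecast at the exact prevalence scores p(1 - p)
  outcomes <- rep(c(TRUE, FALSE), c(3, 7))
  expect_equal(brier(rep(0.3, 10), outcomes), 0.3 * 0.7)
  expect_error(brier(numeric(0), logical(0)),
               class = "gpospom_undefined_statistic_error")
  expect_error(brier(1.2, TRUE), class = "gpospom_validation_error")
})

test_that("Wald interval reproduces printed bounds, clips, and is symmetric", {
  expect_identical(unname(proportion_ci(0, 50)), c(0, 0, 0))
  ci <- proportion_ci(4053, 199780)
  expect_equal(unname(ci), c(2.03, 1.97, 2.09))
  ci50 <- proportion_ci(5000, 10000)
  expect_equal(ci50[["estimate"]] - ci50[["lower"]],
               ci50[["upper"]] - ci50[["estimate"]])
  expect_error(proportion_ci(1, 0), class = "gpospom_undefined_statistic_error")
})

test_that("Wald interval width scales as 1 over sqrt(n)", {
  p <- 0.02
  width <- vapply(c(1e3, 1e4, 1e5), function(n) {
    z <- qnorm(0.975)
    2 * z * sqrt(p * (1 - p) / n) * 100  # unrounded width in percent
  }, numeric(1))
  expect_equal(width[1] / width[2], sqrt(10), tolerance = 1e-10)
  expect_equal(width[2] / width[3], sqrt(10), tolerance = 1e-10)
  # and the reported (rounded) intervals shrink accordingly
  w <- vapply(c(1e3, 1e4, 1e5), function(n) {
    ci <- proportion_ci(round(p * n), n)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("per-score mortality equals a brute-force group-by", {
  expect_identical(nrow(per_score_mortality(fake_scored(integer(0), logical(0)))), 0L)
  two <- per_score_mortality(fake_scored(c(10L, 10L), c(TRUE, FALSE)))
  expect_equal(two$mortality_pct, 50)

  set.seed(83)
  scored <- fake_scored(sample(0:15, 300, replace = TRUE), runif(300) < 0.2)
  got <- per_score_mortality(scored)
  for (s in unique(scored$score)) {
    idx <- scored$score == s
    expect_identical(got$n[got$score == s], sum(idx))
    expect_identical(got$deaths[got$score == s], as.integer(sum(scored$died[idx])))
  }
  expect_identical(sum(got$n), 300L)
  expect_identical(got$score, sort(unique(scored$score)))
})

test_that("calibration fit recovers perfect, flat and hand-computed lines", {
  map <- risk_map("logistic", intercept = -4, slope = 0.2)
  scores <- c(0L, 10L, 20L, 30L)
  p <- predicted_risk(scores, map)
  n <- rep(1000L, 4)
  perfect <- tibble::tibble(score = scores, n = n,
                            deaths = as.integer(round(p * n)))
  perfect$mortality_pct <- 100 * perfect$deaths / perfect$n
  fit <- calibration_fit(perfect, map)
  expect_equal(fit$slope, 1, tolerance = 0.02)      # rounding of deaths only
  expect_equal(fit$intercept, 0, tolerance = 1e-3)

  flat <- perfect
  flat$deaths <- rep(50L, 4)
  ffit <- calibration_fit(flat, map)
  expect_equal(ffit$slope, 0)
  expect_equal(ffit$intercept, 0.05)

  hand <- tibble::tibble(score = c(1L, 2L, 3L, 4L, 5L), n = rep(100L, 5),
                         deaths = c(1L, 3L, 2L, 6L, 9L))
  hfit <- calibration_fit(hand, map)
  oracle <- ols_oracle(predicted_risk(hand$score, map), hand$deaths / hand$n)
  expect_equal(hfit$slope, oracle[["slope"]])
  expect_equal(hfit$intercept, oracle[["intercept"]])

  expect_error(calibration_fit(hand[1, ], map), class = "gpospom_undefined_fit_error")
})

test_that("weighted calibration matches lm with case-count weights", {
  map <- default_risk_map()
  set.seed(89)
  ps <- tibble::tibble(score = 0:20, n = sample(10:5000, 21))
  ps$deaths <- rbinom(21, ps$n, predicted_risk(ps$score, map))
  ps$mortality_pct <- 100 * ps$deaths / ps$n
  wfit <- calibration_fit(ps, map, weighted = TRUE)
  ref <- lm(I(deaths / n) ~ predicted_risk(score, map), data = ps, weights = ps$n)
  expect_equal(wfit$slope, unname(coef(ref)[2]))
})

test_that("cohort summary reproduces counts, strata and degenerate cohorts", {
  one <- summarize_cohort(fake_scored(7L, FALSE))
  expect_equal(one$score[["mean"]], 7)
  expect_true(is.na(one$score[["sd"]]))
  expect_equal(one$mortality_pct, 0)

  set.seed(97)
  n <- 400L
  scored <- fake_scored(sample(0:20, n, TRUE), runif(n) < 0.1,
                        sex = sample(c("female", "male", "other"), n, TRUE,
                                     prob = c(0.49, 0.49, 0.02)),
                        age = sample(18:95, n, TRUE))
  s <- summarize_cohort(scored)
  expect_identical(s$n, n)
  expect_identical(s$deaths, sum(scored$died))
  expect_equal(s$score[["sd"]], sd(scored$score))  # sample SD, n-1
  expect_identical(s$sex_stratum_shortfall, sum(scored$sex == "other"))
  fem <- s$sex_strata[s$sex_strata$sex == "female", ]
  expect_identical(fem$n, sum(scored$sex == "female"))
  expect_error(summarize_cohort(fake_scored(integer(0), logical(0))),
               class = "gpospom_undefined_statistic_error")
})
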