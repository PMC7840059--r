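#' Concordance statistic (area under the ROC curve)
#'
#' The probability that a randomly chosen death scores higher than a randomly
#' chosen survivor, with ties counted as one half. Computed via the midrank
#' (Mann-Whitney) formula, which equals the pairwise definition
#' `(concordant + 0.5 * tied) / (deaths * survivors)` exactly, including ties.
#'
#' @param scores Numeric predictor (higher = higher predicted risk).
#' @param outcomes Logical (or 0/1) event indicator.
#' @return The c-statistic in `[0, 1]`.
#' @export
c_statistic <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  stopifnot(length(scores) == length(outcomes))
  n1 <- sum(outcomes)
  n0 <- sum(!outcomes)
  if (n1 == 0L || n0 == 0L) {
    abort_gpospom("c-statistic undefined: need at least one death and one survivor",
                  "gpospom_undefined_statistic_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve for an integer score
#'
#' Thresholds at every distinct score value, sweeping from the highest
#' ("predict death only for the very highest scores") down, and returns the
#' (FPR, TPR) polyline from (0,0) to (1,1). The trapezoidal area under this
#' curve equals the tie-corrected pairwise c-statistic.
#'
#' @inheritParams c_statistic
#' @return A tibble of class `pospom_roc` with columns `threshold`, `fpr`,
#'   `tpr` and attribute `auc`.
#' @export
roc_curve <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  n1 <- sum(outcomes)
  n0 <- sum(!outcomes)
  if (n1 == 0L || n0 == 0L) {
    abort_gpospom("ROC undefined: need at least one death and one survivor",
                  "gpospom_undefined_statistic_error")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(outcomes & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!outcomes & scores >= t) / n0, numeric(1))
  curve <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1) {
    curve <- rbind(curve, tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(curve, class = c("pospom_roc", class(curve)), auc = auc)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; 0 is perfect prediction, and the uninformative constant forecast
#' at prevalence p scores exactly p(1-p).
#'
#' @param predicted Probabilities in `[0, 1]`.
#' @param outcomes Logical (or 0/1) event indicator of the same length.
#' @return The Brier score in `[0, 1]`.
#' @export
brier <- function(predicted, outcomes) {
  outcomes <- as.logical(outcomes)
  if (length(predicted) == 0L) {
    abort_gpospom("Brier score undefined on empty input",
                  "gpospom_undefined_statistic_error")
  }
  stopifnot(length(predicted) == length(outcomes))
  if (any(predicted < 0 | predicted > 1, na.rm = TRUE)) {
    abort_gpospom("predicted probabilities must lie in [0,1]",
                  "gpospom_validation_error")
  }
  mean((predicted - as.numeric(outcomes))^2)
}

#' Wald confidence interval for a binomial proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`, reported as
#' percentages rounded half up to 2 decimals and clipped to `[0, 100]`. This
#' is the interval conventionally printed for in-hospital mortality in large
#' registries, where n is in the hundreds of thousands and the normal
#' approximation is exact for practical purposes.
#'
#' @param k Number of events (deaths).
#' @param n Number of trials (cases), `n > 0`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric: `estimate`, `lower`, `upper`, all in percent.
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  if (n <= 0 || k < 0 || k > n) {
    abort_gpospom("proportion CI undefined: need 0 <= k <= n, n > 0",
                  "gpospom_undefined_statistic_error")
  }
  p <- k / n
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(estimate = round_half_up(100 * p, 2),
    lower = max(0, round_half_up(100 * (p - half), 2)),
    upper = min(100, round_half_up(100 * (p + half), 2)))
}

#' Observed mortality at each score value
#'
#' Groups a scored cohort by exact integer score and reports, per score value
#' present, the case count, death count, and observed in-hospital mortality
#' percentage. Score values with no cases are omitted.
#'
#' @param scored Scored-case tibble with `score` and `died`.
#' @return A tibble with columns `score`, `n`, `deaths`, `mortality_pct`,
#'   ordered by score.
#' @export
per_score_mortality <- function(scored) {
  if (nrow(scored) == 0L) {
    return(tibble::tibble(score = integer(0), n = integer(0),
                          deaths = integer(0), mortality_pct = numeric(0)))
  }
  scored |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(n = dplyr::n(), deaths = sum(.data$died), .groups = "drop") |>
    dplyr::mutate(mortality_pct = round_half_up(100 * .data$deaths / .data$n, 2)) |>
    dplyr::arrange(.data$score)
}

#' Calibration of predicted against observed mortality
#'
#' Builds one calibration point per score value — predicted probability from
#' the risk map against observed mortality proportion — and fits an ordinary
#' least-squares line through those points. Perfect calibration is the
#' identity line: slope 1, intercept 0. The default fit is unweighted (one
#' dot per score value, as calibration plots are drawn); `weighted = TRUE`
#' weights each point by its case count instead.
#'
#' @param per_score Per-score mortality tibble from [per_score_mortality()].
#' @param map A `pospom_risk_map`.
#' @param weighted Weight points by case count? Default `FALSE`.
#' @return A list of class `calibration_fit` with `points` (tibble: `score`,
#'   `n`, `predicted`, `observed` as proportions), `slope`, `intercept`.
#' @export
calibration_fit <- function(per_score, map, weighted = FALSE) {
  if (nrow(per_score) < 2L) {
    abort_gpospom("calibration fit undefined: need at least 2 score values",
                  "gpospom_undefined_fit_error")
  }
  points <- tibble::tibble(
    score = per_score$score,
    n = per_score$n,
    predicted = predicted_risk(per_score$score, map),
    observed = per_score$deaths / per_score$n
  )
  if (length(unique(points$predicted)) < 2L) {
    abort_gpospom("calibration fit undefined: need at least 2 distinct predicted values",
                  "gpospom_undefined_fit_error")
  }
  fit <- if (weighted) {
    lm(observed ~ predicted, data = points, weights = points$n)
  } else {
    lm(observed ~ predicted, data = points)
  }
  structure(list(points = points,
                 slope = unname(coef(fit)[["predicted"]]),
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 weighted = weighted),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %d points, slope %.3f, intercept %.4f%s\n",
              nrow(x$points), x$slope, x$intercept,
              if (x$weighted) " (case-weighted)" else ""))
  invisible(x)
}

#' Cohort summary statistics
#'
#' The headline descriptive block of a validation study: case and death
#' counts, in-hospital mortality with its Wald confidence interval, mean/SD
#' (sample SD, n-1 denominator) and median of score and age, and the same
#' statistics per sex stratum. Stratum counts that fail to sum to the cohort
#' total (e.g. because of unknown sex) are reported in
#' `sex_stratum_shortfall`, never silently repaired.
#'
#' @param scored Scored-case tibble.
#' @param ci_level Confidence level for the mortality CI.
#' @return A list of class `cohort_summary`.
#' @export
summarize_cohort <- function(scored, ci_level = 0.95) {
  n <- nrow(scored)
  if (n == 0L) {
    abort_gpospom("cohort summary undefined on empty cohort",
                  "gpospom_undefined_statistic_error")
  }
  deaths <- sum(scored$died)
  ci <- proportion_ci(deaths, n, ci_level)
  num_block <- function(x) {
    c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else NA_real_,
      median = median(as.numeric(x)))
  }
  strata <- scored |>
    dplyr::filter(.data$sex %in% c("female", "male")) |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct = NA_real_,
      deaths = sum(.data$died),
      mortality_pct = round_half_up(100 * sum(.data$died) / dplyr::n(), 2),
      mean_score = mean(.data$score),
      sd_score = sd(.data$score),
      mean_age = mean(.data$age),
      sd_age = sd(.data$age),
      median_age = median(as.numeric(.data$age)),
      .groups = "drop"
    )
  strata$pct <- round_half_up(100 * strata$n / n, 2)
  structure(list(
    n = n,
    deaths = deaths,
    mortality_pct = ci[["estimate"]],
    mortality_ci = c(lower = ci[["lower"]], upper = ci[["upper"]]),
    ci_level = ci_level,
    score = num_block(scored$score),
    age = num_block(scored$age),
    max_score = max(scored$score),
    sex_strata = strata,
    sex_stratum_shortfall = n - sum(strata$n)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  cases: %s, deaths: %s, mortality %.2f%% (%d%% CI %.2f-%.2f%%)\n",
              format(x$n, big.mark = ","), format(x$deaths, big.mark = ","),
              x$mortality_pct, round(100 * x$ci_level),
              x$mortality_ci[["lower"]], x$mortality_ci[["upper"]]))
  cat(sprintf("  score: mean %.2f (SD %.2f), median %g, max %g\n",
              x$score[["mean"]], x$score[["sd"]], x$score[["median"]], x$max_score))
  cat(sprintf("  age:   mean %.2f (SD %.2f), median %g\n",
              x$age[["mean"]], x$age[["sd"]], x$age[["median"]]))
  if (x$sex_stratum_shortfall != 0) {
    cat(sprintf("  note: sex strata fall %d case(s) short of the total\n",
                x$sex_stratum_shortfall))
  }
  invisible(x)
}

#' Assemble a full validation report
#'
#' Bundles every statistic of the validation battery — cohort summary,
#' attrition, point decomposition, c-statistic, Brier score, calibration fit
#' and per-score mortality — into one object that serializes to JSON via
#' [write_validation_report()].
#'
#' @param scored Scored-case tibble with predicted risks (supply `map` to
#'   [score_cases()], or pass `map` here to fill them in).
#' @param map A `pospom_risk_map` (required if `scored$predicted_risk` is NA).
#' @param attrition Optional `attrition_report`.
#' @return A list of class `validation_report`.
#' @export
validation_report <- function(scored, map, attrition = NULL) {
  if (all(is.na(scored$predicted_risk))) {
    scored$predicted_risk <- predicted_risk(scored$score, map)
  }
  per_score <- per_score_mortality(scored)
  auc <- tryCatch(c_statistic(scored$score, scored$died),
                  gpospom_undefined_statistic_error = function(e) NA_real_)
  structure(list(
    summary = summarize_cohort(scored),
    attrition = attrition,
    decomposition = decompose_points(scored),
    auc = auc,
    brier = brier(scored$predicted_risk, scored$died),
    calibration = calibration_fit(per_score, map),
    per_score_mortality = per_score
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  c-statistic: %s\n",
              if (is.na(x$auc)) "undefined (single-class outcome)" else sprintf("%.3f", x$auc)))
  cat(sprintf("  Brier score: %.4f\n", x$brier))
  cat(sprintf("  calibration: slope %.3f, intercept %.4f\n",
              x$calibration$slope, x$calibration$intercept))
  print(x$summary)
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' Writes every block of the report with stable key order and full numeric
#' precision (rounded headline percentages appear alongside the exact
#' underlying counts so they can always be recomputed).
#'
#' @param report A `validation_report`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  s <- report$summary
  obj <- list(
    summary = list(
      n = s$n, deaths = s$deaths,
      mortality_pct = s$mortality_pct,
      mortality_ci = as.list(s$mortality_ci),
      ci_level = s$ci_level,
      score = as.list(s$score), age = as.list(s$age), max_score = s$max_score,
      sex_strata = s$sex_strata,
      sex_stratum_shortfall = s$sex_stratum_shortfall
    ),
    attrition = if (is.null(report$attrition)) NULL else unclass(report$attrition),
    decomposition = list(
      total_points = report$decomposition$total_points,
      comorbidity_points_total = report$decomposition$comorbidity_points_total,
      age_points_total = report$decomposition$age_points_total,
      surgery_points_total = report$decomposition$surgery_points_total,
      shares = as.list(report$decomposition$shares)
    ),
    auc = report$auc,
    brier = report$brier,
    calibration = list(
      slope = report$calibration$slope,
      intercept = report$calibration$intercept,
      weighted = report$calibration$weighted,
      points = report$calibration$points
    ),
    per_score_mortality = report$per_score_mortality
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "rows")
  invisible(path)
}
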