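#' Load a pipeline run configuration
#'
#' A single YAML (or JSON) file drives a whole run: input paths, dialect
#' overrides, death codes, minimum age, CI level and the seed. Missing keys
#' fall back to package defaults.
#'
#' @param path Path to the config file, or a named list (returned as-is with
#'   defaults filled in).
#' @return A list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) read_config(path) else path
  defaults <- list(
    registry = NULL, point_table = NULL, risk_map = NULL, scored = NULL,
    out_dir = ".", list_sep = "|", death_codes = "07", min_age = 18,
    ci_level = 0.95, seed = NULL, figures = TRUE
  )
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  structure(cfg, class = "run_config")
}

resolve_table <- function(x) {
  if (inherits(x, "pospom_table")) x
  else if (is.null(x)) default_point_table()
  else load_point_table(x)
}

resolve_map <- function(x) {
  if (inherits(x, "pospom_risk_map")) x
  else if (is.null(x)) default_risk_map()
  else load_risk_map(x)
}

#' Run the scoring pipeline
#'
#' read registry -> eligibility cascade -> score -> write. Writes
#' `scored_cases.csv` and `attrition.json` into the output directory, logs
#' the attrition at message level, and never mutates its inputs.
#'
#' @param config A `run_config`, config-file path, or named list with at
#'   least `registry` (registry CSV path or case tibble); `point_table` and
#'   `risk_map` may be paths or objects and default to the synthetic table
#'   and the default logistic link.
#' @return Invisibly, a list with `scored` (tibble), `report`
#'   (`attrition_report`) and the output paths.
#' @export
run_score <- function(config) {
  cfg <- load_run_config(config)
  table <- resolve_table(cfg$point_table)
  map <- resolve_map(cfg$risk_map)
  dialect <- registry_dialect(list_sep = cfg$list_sep, death_codes = cfg$death_codes)
  cases <- if (is.data.frame(cfg$registry)) cfg$registry else read_cases(cfg$registry, dialect)
  elig <- apply_eligibility(cases, table, min_age = cfg$min_age)
  scored <- score_cases(elig$included, table, map = map, death_codes = cfg$death_codes)
  if (nrow(scored) == 0L) warning("no eligible cases after the eligibility cascade")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  scored_path <- file.path(cfg$out_dir, "scored_cases.csv")
  write_scored_cases(scored, scored_path)
  attrition_path <- file.path(cfg$out_dir, "attrition.json")
  jsonlite::write_json(unclass(elig$report), attrition_path,
                       auto_unbox = TRUE, pretty = TRUE)
  message(sprintf(
    "attrition: %d input | %d no index procedure | %d under 18 | %d incomplete | %d included",
    elig$report$n_input, elig$report$n_no_index_procedure, elig$report$n_under_18,
    elig$report$n_incomplete, elig$report$n_included))
  invisible(list(scored = scored, report = elig$report,
                 scored_path = scored_path, attrition_path = attrition_path))
}

#' Run the validation pipeline
#'
#' Produces the full validation report (cohort summary, attrition, point
#' decomposition, c-statistic, Brier score, calibration fit, per-score
#' mortality) as `validation_report.json`, plus ROC, calibration and
#' score-distribution figures in SVG and PNG when `figures` is enabled.
#'
#' @param config As in [run_score()]; when `scored` names a scored-cases CSV
#'   it is used directly, otherwise the scoring pipeline runs first.
#' @return Invisibly, the `validation_report`.
#' @export
run_validate <- function(config) {
  cfg <- load_run_config(config)
  map <- resolve_map(cfg$risk_map)
  attrition <- NULL
  if (!is.null(cfg$scored)) {
    scored <- if (is.data.frame(cfg$scored)) cfg$scored else read_scored_cases(cfg$scored)
  } else {
    run <- run_score(cfg)
    scored <- run$scored
    attrition <- run$report
  }
  report <- validation_report(scored, map, attrition = attrition)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_validation_report(report, file.path(cfg$out_dir, "validation_report.json"))
  message(sprintf("c-statistic %.3f | Brier %.4f | calibration slope %.3f",
                  report$auc, report$brier, report$calibration$slope))
  if (isTRUE(cfg$figures)) {
    emit_figures(scored, report, cfg$out_dir)
  }
  invisible(report)
}

emit_figures <- function(scored, report, out_dir) {
  figs <- list(
    roc = plot_roc(roc_curve(scored$score, scored$died)),
    calibration = plot_calibration(report$calibration),
    score_mortality = plot_score_mortality(report$per_score_mortality)
  )
  for (name in names(figs)) {
    ggplot2::ggsave(file.path(out_dir, paste0(name, ".svg")), figs[[name]],
                    device = grDevices::svg, width = 6, height = 5)
    ggplot2::ggsave(file.path(out_dir, paste0(name, ".png")), figs[[name]],
                    device = grDevices::png, type = "cairo",
                    width = 6, height = 5, dpi = 150, units = "in")
  }
  invisible(figs)
}

#' Plot a ROC curve
#'
#' False-positive rate against true-positive rate with the chance diagonal
#' and the AUC in the subtitle.
#'
#' @param roc A `pospom_roc` from [roc_curve()].
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(tibble::as_tibble(roc), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Receiver operating characteristic",
                  subtitle = sprintf("AUC = %.3f", attr(roc, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' Observed against predicted in-hospital mortality, one dot per score value,
#' with the identity diagonal (perfect calibration) and the least-squares
#' line of best fit.
#'
#' @param fit A `calibration_fit`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(fit) {
  ggplot2::ggplot(fit$points, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(colour = "black", size = 1.6, alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = "Predicted in-hospital mortality",
                  y = "Observed in-hospital mortality",
                  title = "Calibration",
                  subtitle = sprintf("slope %.3f, intercept %.4f",
                                     fit$slope, fit$intercept)) +
    ggplot2::theme_minimal()
}

#' Plot the score distribution with per-score mortality
#'
#' Case counts per score value (bars, left axis) overlaid with the observed
#' in-hospital mortality at each score (line, right axis).
#'
#' @param per_score Per-score mortality tibble from [per_score_mortality()].
#' @return A ggplot object.
#' @export
plot_score_mortality <- function(per_score) {
  max_n <- max(per_score$n)
  max_m <- max(per_score$mortality_pct, 1)
  k <- max_n / max_m
  ggplot2::ggplot(per_score, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n), fill = "#e08214", alpha = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mortality_pct * k), colour = "#b2182b") +
    ggplot2::scale_y_continuous(
      name = "Cases",
      sec.axis = ggplot2::sec_axis(~ . / k, name = "Observed mortality (%)")
    ) +
    ggplot2::labs(x = "Score", title = "Score distribution and observed mortality") +
    ggplot2::theme_minimal()
}

#' Compare two cohorts' score distributions or mortality curves
#'
#' Overlays the study cohort with a reference cohort (for instance the
#' original derivation population), either as the share of cases per score
#' value or as the observed mortality at each score.
#'
#' @param per_score Study-cohort per-score table.
#' @param reference Reference-cohort per-score table (same columns).
#' @param what `"distribution"` (share of cases per score) or `"mortality"`.
#' @param labels Length-2 character vector naming the two cohorts.
#' @return A ggplot object.
#' @export
plot_cohort_comparison <- function(per_score, reference,
                                   what = c("distribution", "mortality"),
                                   labels = c("study", "reference")) {
  what <- match.arg(what)
  both <- dplyr::bind_rows(
    dplyr::mutate(per_score, cohort = labels[1], share = 100 * .data$n / sum(.data$n)),
    dplyr::mutate(reference, cohort = labels[2], share = 100 * .data$n / sum(.data$n))
  )
  y <- if (what == "distribution") "share" else "mortality_pct"
  ylab <- if (what == "distribution") "Share of cases (%)" else "Observed mortality (%)"
  p <- ggplot2::ggplot(both, ggplot2::aes(x = .data$score, y = .data[[y]],
                                          fill = .data$cohort, colour = .data$cohort))
  p <- if (what == "distribution") {
    p + ggplot2::geom_col(position = "identity", alpha = 0.5, colour = NA)
  } else {
    p + ggplot2::geom_line(linewidth = 0.8)
  }
  p + ggplot2::labs(x = "Score", y = ylab) + ggplot2::theme_minimal()
}
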