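#' Registry CSV dialect
#'
#' Describes how a case-level registry CSV (one row per hospital stay,
#' emulating a German paragraph-21 KHEntgG billing extract) is laid out:
#' the separator used inside multi-valued code fields and the set of
#' discharge-reason codes that encode in-hospital death.
#'
#' @param list_sep Separator inside the `icd_codes`, `ops_codes` and
#'   `ops_dates` fields (default `"|"`).
#' @param death_codes Discharge-reason codes meaning in-hospital death
#'   (default `"07"`, the paragraph-21 convention).
#' @return A list of class `registry_dialect`.
#' @export
registry_dialect <- function(list_sep = "|", death_codes = "07") {
  structure(list(list_sep = list_sep, death_codes = as.character(death_codes)),
            class = "registry_dialect")
}

registry_columns <- c("case_id", "age", "sex", "icd_codes", "ops_codes",
                      "ops_dates", "admission_date", "discharge_date",
                      "discharge_reason")

#' Read a case-level registry CSV
#'
#' Expects UTF-8 CSV with columns `case_id, age, sex, icd_codes, ops_codes,
#' ops_dates, admission_date, discharge_date, discharge_reason`; multi-valued
#' fields are split on the dialect's list separator and all ICD/OPS codes are
#' normalized on ingest. Rows are preserved in file order.
#'
#' @param path Path to the CSV file.
#' @param dialect A [registry_dialect()].
#' @return A tibble with one row per case; `icd_codes`, `ops_codes` and
#'   `ops_dates` are list-columns (`ops_dates` holds `Date` vectors aligned
#'   with `ops_codes`, `NA` where no date was recorded).
#' @export
read_cases <- function(path, dialect = registry_dialect()) {
  if (!file.exists(path)) {
    abort_gpospom(sprintf("registry file not found: '%s'", path), "gpospom_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0), fileEncoding = "UTF-8")
  missing_cols <- setdiff(registry_columns, names(raw))
  if (length(missing_cols) > 0L) {
    abort_gpospom(sprintf("registry '%s' is missing mandatory column(s): %s",
                          path, paste(missing_cols, collapse = ", ")),
                  "gpospom_schema_error")
  }
  if (anyDuplicated(raw$case_id)) {
    dups <- unique(raw$case_id[duplicated(raw$case_id)])
    abort_gpospom(sprintf("duplicate case_id(s): %s",
                          paste(head(dups, 10), collapse = ", ")),
                  "gpospom_integrity_error")
  }
  sep <- dialect$list_sep
  blank_na <- function(x) ifelse(nzchar(x), x, NA_character_)
  parse_date <- function(x) as.Date(blank_na(x), format = "%Y-%m-%d")
  n <- nrow(raw)
  icd <- lapply(raw$icd_codes, function(x) normalize_code(split_list_field(x, sep)))
  ops <- lapply(raw$ops_codes, function(x) normalize_code(split_list_field(x, sep)))
  ops_dates <- vector("list", n)
  for (i in seq_len(n)) {
    d <- split_list_field(raw$ops_dates[i], sep)
    k <- length(ops[[i]])
    dates <- as.Date(rep(NA_character_, k))
    if (length(d) > 0L && k > 0L) {
      d <- head(d, k)
      parsed <- as.Date(ifelse(nzchar(d) & d != "NA", d, NA_character_),
                        format = "%Y-%m-%d")
      dates[seq_along(parsed)] <- parsed
    }
    ops_dates[[i]] <- dates
  }
  cases <- tibble::tibble(
    case_id = raw$case_id,
    age = suppressWarnings(as.integer(blank_na(raw$age))),
    sex = blank_na(raw$sex),
    icd_codes = icd,
    ops_codes = ops,
    ops_dates = ops_dates,
    admission_date = parse_date(raw$admission_date),
    discharge_date = parse_date(raw$discharge_date),
    discharge_reason = blank_na(raw$discharge_reason)
  )
  bad_stay <- !is.na(cases$admission_date) & !is.na(cases$discharge_date) &
    cases$discharge_date < cases$admission_date
  if (any(bad_stay)) {
    abort_gpospom(sprintf("discharge before admission for case(s): %s",
                          paste(head(cases$case_id[bad_stay], 10), collapse = ", ")),
                  "gpospom_integrity_error")
  }
  cases
}

#' Write a case-level registry CSV
#'
#' Inverse of [read_cases()]: list-columns are joined with the dialect's list
#' separator, dates are ISO-8601, and `read_cases(write_cases(x))` round-trips
#' every field.
#'
#' @param cases Case tibble as returned by [read_cases()] or the generators.
#' @param path Output path.
#' @param dialect A [registry_dialect()].
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path, dialect = registry_dialect()) {
  sep <- dialect$list_sep
  fmt_date <- function(x) ifelse(is.na(x), "", format(x, "%Y-%m-%d"))
  out <- data.frame(
    case_id = cases$case_id,
    age = ifelse(is.na(cases$age), "", as.character(cases$age)),
    sex = ifelse(is.na(cases$sex), "", cases$sex),
    icd_codes = vapply(cases$icd_codes, join_list_field, character(1), sep = sep),
    ops_codes = vapply(cases$ops_codes, join_list_field, character(1), sep = sep),
    ops_dates = vapply(cases$ops_dates, function(d) join_list_field(fmt_date(d), sep),
                       character(1)),
    admission_date = fmt_date(cases$admission_date),
    discharge_date = fmt_date(cases$discharge_date),
    discharge_reason = ifelse(is.na(cases$discharge_reason), "", cases$discharge_reason),
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive the in-hospital death outcome from the discharge disposition
#'
#' A case died in hospital iff its discharge-reason code is a member of the
#' configured death-code set. A missing discharge reason yields
#' `died = FALSE` together with `incomplete = TRUE`, so the eligibility filter
#' can exclude the case rather than silently treating it as a survivor.
#'
#' @param discharge_reason Character vector of discharge-reason codes.
#' @param death_codes Character vector of codes meaning death (default `"07"`).
#' @return A tibble with logical columns `died` and `incomplete`.
#' @export
derive_outcome <- function(discharge_reason, death_codes = "07") {
  missing <- is.na(discharge_reason) | !nzchar(discharge_reason)
  tibble::tibble(
    died = !missing & discharge_reason %in% death_codes,
    incomplete = missing
  )
}

#' Write scored cases to CSV
#'
#' One row per case with the score and its decomposition; the score column
#' always equals the sum of the three point columns. Probabilities are written
#' with full precision (`format = "%.17g"` equivalent via `as.character`), so
#' a write/read round trip is bit-exact.
#'
#' @param scored Scored-case tibble from [score_cases()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scored_cases <- function(scored, path) {
  cols <- c("case_id", "age", "sex", "score", "age_points", "comorbidity_points",
            "surgery_points", "surgery_group", "predicted_risk", "died")
  out <- scored[, intersect(cols, names(scored))]
  if (!"predicted_risk" %in% names(out)) out$predicted_risk <- NA_real_
  out$predicted_risk <- vapply(out$predicted_risk, function(p) {
    if (is.na(p)) "" else sprintf("%.17g", p)
  }, character(1))
  out$died <- ifelse(out$died, "1", "0")
  utils::write.csv(out[, cols], path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read scored cases back from CSV
#'
#' @param path Path written by [write_scored_cases()].
#' @return A tibble with the scored-case columns typed back (scores integer,
#'   `predicted_risk` numeric, `died` logical).
#' @export
read_scored_cases <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0), fileEncoding = "UTF-8")
  tibble::tibble(
    case_id = raw$case_id,
    age = as.integer(raw$age),
    sex = raw$sex,
    score = as.integer(raw$score),
    age_points = as.integer(raw$age_points),
    comorbidity_points = as.integer(raw$comorbidity_points),
    surgery_points = as.integer(raw$surgery_points),
    surgery_group = raw$surgery_group,
    predicted_risk = suppressWarnings(as.numeric(ifelse(nzchar(raw$predicted_risk),
                                                        raw$predicted_risk, NA))),
    died = raw$died == "1"
  )
}
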