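#' Age points for a case
#'
#' Looks up the unique age band containing each age. Bands are inclusive on
#' both ends; ages above every finite band fall into the open-ended top band,
#' whose existence the table validator guarantees. Vectorized over `age`.
#'
#' @param age Integer age(s) in years, all at least the youngest band's lower
#'   bound (the eligibility filter removes minors beforehand).
#' @param table A validated `pospom_table`.
#' @return Integer point vector.
#' @export
age_points <- function(age, table) {
  ab <- table$age_bands
  idx <- findInterval(age, ab$lower)
  bad <- is.na(age) | idx == 0L | age > ab$upper[pmax(idx, 1L)]
  if (any(bad)) {
    abort_gpospom(sprintf("age(s) outside all bands: %s",
                          paste(head(unique(age[bad]), 10), collapse = ", ")),
                  "gpospom_precondition_error")
  }
  ab$points[idx]
}

#' Comorbidity points for cases
#'
#' Each comorbidity group contributes its points at most once per case, iff
#' any of the case's ICD codes matches any of the group's prefixes. Duplicated
#' or multiply-coded diagnoses within one group therefore never inflate the
#' score.
#'
#' @param cases Case tibble.
#' @param table A validated `pospom_table`.
#' @return A list with `points` (integer vector) and `matched` (list of
#'   character vectors of contributing group names, one per case).
#' @export
comorbidity_points <- function(cases, table) {
  cg <- table$comorbidities
  n <- nrow(cases)
  if (nrow(cg) == 0L || n == 0L) {
    return(list(points = integer(n), matched = rep(list(character(0)), n)))
  }
  hits <- vapply(seq_len(nrow(cg)),
                 function(g) match_codes_by_case(cases$icd_codes, cg$prefixes[[g]]),
                 logical(n))
  hits <- matrix(hits, nrow = n)
  points <- as.integer(hits %*% cg$points)
  matched <- apply(hits, 1L, function(row) cg$name[row], simplify = FALSE)
  list(points = points, matched = matched)
}

#' Select the index surgery for each case
#'
#' Implements the assignment rule for multiply-operated cases: among all
#' procedures matching a surgery group, the chronologically first is assigned;
#' among procedures tied on that earliest date — or when no dates are recorded
#' at all, which is treated as everything being simultaneous — the group
#' scoring the most points wins; a residual tie (same date, same points,
#' different groups) is broken by lexicographic group name so the assignment
#' is deterministic. A procedure with a missing date in a case that also has
#' dated procedures is treated as tied with the earliest dated one.
#'
#' @param cases Case tibble; every case must have at least one index
#'   procedure (see [has_index_procedure()]).
#' @param table A validated `pospom_table`.
#' @return A tibble with columns `surgery_group` and `surgery_points`, one row
#'   per case.
#' @export
select_surgery <- function(cases, table) {
  sg <- table$surgeries
  n <- nrow(cases)
  if (n == 0L) {
    return(tibble::tibble(surgery_group = character(0), surgery_points = integer(0)))
  }
  lens <- lengths(cases$ops_codes)
  codes <- unlist(cases$ops_codes, use.names = FALSE)
  case_of <- rep.int(seq_len(n), lens)
  dates <- as.Date(unlist(lapply(cases$ops_dates, as.numeric)), origin = "1970-01-01")
  # ambiguity is validated away: a full code matches at most one group
  group_of <- rep(NA_integer_, length(codes))
  for (g in seq_len(nrow(sg))) {
    hit <- rep(FALSE, length(codes))
    for (p in sg$prefixes[[g]]) hit <- hit | startsWith(codes, p)
    group_of[is.na(group_of) & hit] <- g
  }
  keep <- !is.na(group_of)
  if (!any(keep) || !all(seq_len(n) %in% case_of[keep])) {
    missing_cases <- setdiff(seq_len(n), case_of[keep])
    abort_gpospom(sprintf("no index procedure for case(s): %s",
                          paste(head(cases$case_id[missing_cases], 10), collapse = ", ")),
                  "gpospom_precondition_error")
  }
  cand <- data.frame(case = case_of[keep], group = group_of[keep],
                     date = dates[keep])
  cand$points <- sg$points[cand$group]
  cand$name <- sg$name[cand$group]
  # earliest recorded date per case (NA when no procedure is dated)
  suppressWarnings(
    d0 <- stats::ave(as.numeric(cand$date), cand$case,
                     FUN = function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  )
  eff <- ifelse(is.na(as.numeric(cand$date)), d0, as.numeric(cand$date))
  tied_first <- is.na(d0) | (!is.na(eff) & eff == d0)
  cand <- cand[tied_first, ]
  ord <- order(cand$case, -cand$points, cand$name)
  cand <- cand[ord, ]
  first <- cand[!duplicated(cand$case), ]
  first <- first[order(first$case), ]
  tibble::tibble(surgery_group = first$name,
                 surgery_points = as.integer(first$points))
}

#' Score a cohort of eligible cases
#'
#' Computes the POSPOM score and its full decomposition for every case:
#' `score = age_points + comorbidity_points + surgery_points`, the matched
#' comorbidity groups, the assigned surgery group, the in-hospital death
#' outcome derived from the discharge disposition, and (when a risk map is
#' supplied) the predicted mortality probability.
#'
#' @param cases Eligible case tibble (run [apply_eligibility()] first).
#' @param table A validated `pospom_table`.
#' @param map Optional `pospom_risk_map` for predicted probabilities.
#' @param death_codes Discharge-reason codes meaning in-hospital death.
#' @return A scored-case tibble with columns `case_id`, `age`, `sex`, `score`,
#'   `age_points`, `comorbidity_points`, `surgery_points`, `surgery_group`,
#'   `matched_comorbidities` (list), `predicted_risk`, `died`.
#' @export
score_cases <- function(cases, table, map = NULL, death_codes = "07") {
  n <- nrow(cases)
  if (n == 0L) {
    return(tibble::tibble(
      case_id = character(0), age = integer(0), sex = character(0),
      score = integer(0), age_points = integer(0), comorbidity_points = integer(0),
      surgery_points = integer(0), surgery_group = character(0),
      matched_comorbidities = list(), predicted_risk = numeric(0), died = logical(0)
    ))
  }
  ap <- age_points(cases$age, table)
  cp <- comorbidity_points(cases, table)
  surg <- select_surgery(cases, table)
  score <- as.integer(ap + cp$points + surg$surgery_points)
  outcome <- derive_outcome(cases$discharge_reason, death_codes)
  tibble::tibble(
    case_id = cases$case_id,
    age = cases$age,
    sex = cases$sex,
    score = score,
    age_points = as.integer(ap),
    comorbidity_points = cp$points,
    surgery_points = surg$surgery_points,
    surgery_group = surg$surgery_group,
    matched_comorbidities = cp$matched,
    predicted_risk = if (is.null(map)) NA_real_ else predicted_risk(score, map),
    died = outcome$died
  )
}

#' Score a single case
#'
#' Convenience wrapper over [score_cases()] for one case record.
#'
#' @param case One-row case tibble.
#' @inheritParams score_cases
#' @return A one-row scored-case tibble.
#' @export
score_case <- function(case, table, map = NULL, death_codes = "07") {
  score_cases(case[1, ], table, map = map, death_codes = death_codes)
}

#' Decompose a cohort's points by component
#'
#' Sums the age, comorbidity and surgery points over all scored cases and
#' expresses each component as a percentage of the grand total (rounded half
#' up to 2 decimals; an all-zero cohort has all shares defined as 0).
#'
#' @param scored Scored-case tibble from [score_cases()].
#' @return A list of class `point_decomposition` with `total_points`, the
#'   three component totals, and `shares` (named percentages).
#' @export
decompose_points <- function(scored) {
  comorbidity <- sum(as.numeric(scored$comorbidity_points))
  age <- sum(as.numeric(scored$age_points))
  surgery <- sum(as.numeric(scored$surgery_points))
  total <- comorbidity + age + surgery
  share <- function(x) if (total == 0) 0 else round_half_up(100 * x / total, 2)
  structure(list(
    total_points = total,
    comorbidity_points_total = comorbidity,
    age_points_total = age,
    surgery_points_total = surgery,
    shares = c(comorbidity = share(comorbidity), age = share(age),
               surgery = share(surgery))
  ), class = "point_decomposition")
}

#' @export
print.point_decomposition <- function(x, ...) {
  cat("<point_decomposition>\n")
  cat(sprintf("  total points: %s\n", format(x$total_points, big.mark = ",")))
  cat(sprintf("  comorbidity:  %s (%.2f%%)\n",
              format(x$comorbidity_points_total, big.mark = ","), x$shares[["comorbidity"]]))
  cat(sprintf("  age:          %s (%.2f%%)\n",
              format(x$age_points_total, big.mark = ","), x$shares[["age"]]))
  cat(sprintf("  surgery:      %s (%.2f%%)\n",
              format(x$surgery_points_total, big.mark = ","), x$shares[["surgery"]]))
  invisible(x)
}
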