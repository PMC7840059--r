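#' Does a case carry an index procedure?
#'
#' A case is index-eligible iff at least one of its OPS codes matches (by
#' normalized prefix) at least one surgery group of the point table. Cases
#' without an index procedure — intensive-care interventions,
#' electroconvulsive therapy, biopsies and other minor interventions — cannot
#' be scored and are the first exclusion of the eligibility cascade.
#'
#' @param cases Case tibble (one or more rows).
#' @param table A validated `pospom_table`.
#' @return Logical vector, one element per case.
#' @export
has_index_procedure <- function(cases, table) {
  prefixes <- unique(unlist(table$surgeries$prefixes))
  match_codes_by_case(cases$ops_codes, prefixes)
}

# vectorized "any code of this case starts with any prefix"
match_codes_by_case <- function(code_list, prefixes) {
  n <- length(code_list)
  if (n == 0L) return(logical(0))
  lens <- lengths(code_list)
  if (sum(lens) == 0L || length(prefixes) == 0L) return(rep(FALSE, n))
  codes <- unlist(code_list, use.names = FALSE)
  case_of <- rep.int(seq_len(n), lens)
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  out <- rep(FALSE, n)
  out[unique(case_of[hit])] <- TRUE
  out
}

#' Is a case record complete enough to score?
#'
#' Complete means: age present and discharge reason present. An empty ICD code
#' list is complete — absence of coded comorbidity is informative (zero
#' comorbidity points), not missing data.
#'
#' @param cases Case tibble.
#' @return Logical vector, one element per case.
#' @export
is_complete <- function(cases) {
  !is.na(cases$age) & !is.na(cases$discharge_reason) & nzchar(cases$discharge_reason)
}

#' Apply the eligibility cascade
#'
#' Reproduces the sequential attrition of a surgical-registry flow chart:
#' cases without an index procedure are removed first, then minors (age below
#' `min_age`), then incomplete records. Each case is counted in exactly one
#' bucket — a case failing several criteria lands in the earliest one — so the
#' four bucket counts always partition the input. A case whose age is missing
#' cannot be asserted to be a minor and falls through to the incomplete bucket.
#'
#' @param cases Case tibble.
#' @param table A validated `pospom_table`.
#' @param min_age Minimum age for inclusion (default 18).
#' @return A list with `included` (case tibble) and `report` (an
#'   `attrition_report` with counts `n_input`, `n_no_index_procedure`,
#'   `n_under_18`, `n_incomplete`, `n_included`).
#' @export
apply_eligibility <- function(cases, table, min_age = 18) {
  n <- nrow(cases)
  no_index <- !has_index_procedure(cases, table)
  minor <- !no_index & !is.na(cases$age) & cases$age < min_age
  incomplete <- !no_index & !minor & !is_complete(cases)
  included <- !no_index & !minor & !incomplete
  report <- attrition_report(
    n_input = n,
    n_no_index_procedure = sum(no_index),
    n_under_18 = sum(minor),
    n_incomplete = sum(incomplete),
    n_included = sum(included)
  )
  list(included = cases[included, ], report = report)
}

#' Construct an attrition report
#'
#' @param n_input,n_no_index_procedure,n_under_18,n_incomplete,n_included
#'   Non-negative counts; the four exclusion/inclusion buckets must sum to
#'   `n_input`.
#' @return A list of class `attrition_report`.
#' @export
attrition_report <- function(n_input, n_no_index_procedure, n_under_18,
                             n_incomplete, n_included) {
  counts <- c(n_input = n_input, n_no_index_procedure = n_no_index_procedure,
              n_under_18 = n_under_18, n_incomplete = n_incomplete,
              n_included = n_included)
  if (any(counts < 0)) {
    abort_gpospom("attrition counts must be non-negative", "gpospom_validation_error")
  }
  if (sum(counts[-1]) != counts[[1]]) {
    abort_gpospom("attrition buckets do not sum to n_input", "gpospom_validation_error")
  }
  structure(as.list(counts), class = "attrition_report")
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("<attrition_report>\n")
  cat(sprintf("  cases identified:        %9d\n", x$n_input))
  cat(sprintf("  - no index procedure:    %9d\n", x$n_no_index_procedure))
  cat(sprintf("  - under 18 years:        %9d\n", x$n_under_18))
  cat(sprintf("  - incomplete record:     %9d\n", x$n_incomplete))
  cat(sprintf("  = included:              %9d\n", x$n_included))
  invisible(x)
}
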