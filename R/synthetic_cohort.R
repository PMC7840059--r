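#' A synthetic default point table
#'
#' A fully synthetic, illustrative score definition with six age bands, 15
#' comorbidity ICD-10 prefix groups and eight OPS surgery groups, shaped like
#' the published score (age, comorbidity and surgery components of comparable
#' magnitude; every integer score from 0 to the maximum attainable). It exists
#' so the simulation and validation pipeline can run end-to-end without the
#' original supplementary point values, which are user-supplied configuration;
#' its point values are NOT the published ones.
#'
#' @return A validated `pospom_table` (version `"synthetic-default-1"`).
#' @export
default_point_table <- function() {
  table <- pospom_table(
    age_bands = data.frame(
      lower = c(18, 46, 56, 66, 76, 86),
      upper = c(45, 55, 65, 75, 85, Inf),
      points = c(0L, 3L, 6L, 9L, 12L, 15L)
    ),
    comorbidities = tibble::tibble(
      name = c("congestive_heart_failure", "ischaemic_heart_disease",
               "cardiac_arrhythmia", "valvular_disease",
               "peripheral_vascular_disease", "cerebrovascular_disease",
               "dementia", "chronic_pulmonary_disease", "chronic_kidney_disease",
               "chronic_liver_disease", "diabetes", "solid_cancer",
               "metastatic_cancer", "hemiplegia", "alcohol_abuse"),
      points = c(4L, 2L, 2L, 3L, 2L, 3L, 2L, 2L, 3L, 3L, 1L, 2L, 4L, 2L, 1L),
      prefixes = list(
        c("I50"), c("I20", "I21", "I25"), c("I47", "I48", "I49"),
        c("I05", "I06", "I07", "I08", "I34", "I35"), c("I70", "I71", "I73"),
        c("I60", "I61", "I62", "I63", "I64", "G45"),
        c("F00", "F01", "F02", "F03", "G30"),
        c("J40", "J41", "J42", "J43", "J44", "J45", "J47"),
        c("N18", "N19"), c("K70", "K72", "K74"),
        c("E10", "E11", "E12", "E13", "E14"),
        c("C18", "C34", "C50", "C61"), c("C77", "C78", "C79", "C80"),
        c("G81", "G82"), c("F10")
      )
    ),
    surgeries = tibble::tibble(
      name = c("cataract_surgery", "inguinal_hernia_repair", "cholecystectomy",
               "joint_replacement", "colorectal_resection", "open_vascular_surgery",
               "cardiac_surgery", "oesophago_pancreatic_surgery"),
      points = c(0L, 2L, 4L, 6L, 8L, 10L, 12L, 14L),
      prefixes = list(
        c("5-144"), c("5-530"), c("5-511"), c("5-820", "5-822"),
        c("5-455", "5-456"), c("5-38"), c("5-35", "5-36"),
        c("5-424", "5-524")
      )
    ),
    version = "synthetic-default-1"
  )
  stopifnot(length(validate_point_table(table)) == 0L)
  table
}

#' Default score-to-probability link
#'
#' A logistic risk map calibrated by ordinary least squares on the logit scale
#' through the reported observed in-hospital mortalities at 10, 20, 30 and 40
#' score points (0.31%, 1.39%, 6.35%, 18.37%) of the German single-centre
#' validation cohort. Used both as the default prediction map and as the
#' outcome link of the statistical cohort generator.
#'
#' @return A logistic `pospom_risk_map`.
#' @export
default_risk_map <- function() {
  anchors <- data.frame(score = c(10, 20, 30, 40),
                        p = c(0.0031, 0.0139, 0.0635, 0.1837))
  fit <- lm(stats::qlogis(p) ~ score, data = anchors)
  risk_map("logistic", intercept = unname(coef(fit)[1]),
           slope = unname(coef(fit)[2]))
}

# subset-sum DP over comorbidity groups: every attainable comorbidity total,
# with one representative subset of group indices per total
comorbidity_sums <- function(table) {
  pts <- table$comorbidities$points
  reach <- list(integer(0))
  names(reach) <- "0"
  for (i in seq_along(pts)) {
    for (s in names(reach)) {
      new_sum <- as.character(as.integer(s) + pts[i])
      if (is.null(reach[[new_sum]])) reach[[new_sum]] <- c(reach[[s]], i)
    }
  }
  reach
}

#' All attainable scores under a point table
#'
#' A score is attainable iff it decomposes as (points of one age band) +
#' (points of one surgery group) + (sum of a subset of comorbidity groups);
#' found by dynamic programming over the component point values. Under toy
#' tables the attainable set can have gaps, which is why the generator
#' discretizes its score distribution onto this set.
#'
#' @param table A validated `pospom_table`.
#' @return Sorted integer vector of attainable scores.
#' @export
attainable_scores <- function(table) {
  sort(score_decompositions(table)$score)
}

#' One deterministic decomposition per attainable score
#'
#' For each attainable score, a representative (age band, surgery group,
#' comorbidity subset) whose points sum to it. Among candidate band/surgery
#' pairs the one leaving the smallest comorbidity remainder is chosen, so
#' generated cases carry as few diagnosis codes as possible.
#'
#' @param table A validated `pospom_table`.
#' @return A tibble with columns `score`, `band` (row index into
#'   `table$age_bands`), `surgery` (row index into `table$surgeries`),
#'   `comorbidities` (list of row indices).
#' @export
score_decompositions <- function(table) {
  csums <- comorbidity_sums(table)
  bands <- table$age_bands
  surg <- table$surgeries
  combos <- expand.grid(band = seq_len(nrow(bands)), surgery = seq_len(nrow(surg)))
  combos$base <- bands$points[combos$band] + surg$points[combos$surgery]
  combos <- combos[order(-combos$base, combos$band, combos$surgery), ]
  max_score <- max_attainable_score(table)
  rows <- vector("list", max_score + 1L)
  for (target in 0:max_score) {
    feasible <- combos[combos$base <= target, , drop = FALSE]
    for (k in seq_len(nrow(feasible))) {
      rest <- as.character(target - feasible$base[k])
      subset <- csums[[rest]]
      if (!is.null(subset) || rest == "0") {
        rows[[target + 1L]] <- tibble::tibble(
          score = target, band = feasible$band[k], surgery = feasible$surgery[k],
          comorbidities = list(subset %||% integer(0))
        )
        break
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Construct a case that scores an exact target
#'
#' Inverse of the scoring engine: picks one decomposition of `target` and
#' returns an age, ICD code list and OPS code list that [score_case()] maps
#' back to exactly `target`. Codes are the first prefix of each chosen group
#' (a prefix is itself a valid matching code).
#'
#' @param target Integer score, attainable under `table`.
#' @param table A validated `pospom_table`.
#' @param sample_age Draw the age uniformly within the chosen band (uses the
#'   current RNG stream)? Default `FALSE` returns the band's lower bound.
#' @return A list with `age`, `icd` (character vector), `ops` (character
#'   vector).
#' @export
codes_for_score <- function(target, table, sample_age = FALSE) {
  decomp <- score_decompositions(table)
  row <- decomp[decomp$score == target, ]
  if (nrow(row) == 0L) {
    att <- decomp$score
    nearest <- att[order(abs(att - target))][1:min(3, length(att))]
    abort_gpospom(sprintf("score %d is not attainable; nearest attainable: %s",
                          target, paste(sort(nearest), collapse = ", ")),
                  "gpospom_unattainable_score_error")
  }
  band <- table$age_bands[row$band, ]
  age <- if (sample_age) sample_age_in_band(1L, row$band, table) else as.integer(band$lower)
  list(
    age = age,
    icd = vapply(table$comorbidities$prefixes[row$comorbidities[[1]]],
                 function(p) p[[1]], character(1)),
    ops = table$surgeries$prefixes[[row$surgery]][[1]]
  )
}

# uniform integer age inside band(s); open-ended bands use a 14-year span
sample_age_in_band <- function(n, band_idx, table) {
  lower <- table$age_bands$lower[band_idx]
  upper <- table$age_bands$upper[band_idx]
  upper <- ifelse(is.finite(upper), upper, lower + 14)
  as.integer(lower + floor(runif(n) * (upper - lower + 1)))
}

#' Specification of an attrition fixture registry
#'
#' Defaults are the flow-chart counts of the German single-centre validation:
#' 357,861 identified cases, of which 115,281 without an index procedure,
#' 41,836 minors, 964 incomplete, and 4,053 in-hospital deaths among the
#' 199,780 included.
#'
#' @param n_total Total cases identified.
#' @param n_without_index Cases with no index procedure.
#' @param n_minor Cases younger than 18.
#' @param n_incomplete Cases with a missing mandatory field.
#' @param n_deaths_among_included Death dispositions among the included.
#' @param seed Integer RNG seed (or `NULL` to use the current stream).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_total = 357861, n_without_index = 115281,
                         n_minor = 41836, n_incomplete = 964,
                         n_deaths_among_included = 4053, seed = NULL) {
  n_included <- n_total - n_without_index - n_minor - n_incomplete
  if (n_included < 0) {
    abort_gpospom("fixture strata exceed n_total", "gpospom_spec_error")
  }
  if (n_deaths_among_included > n_included) {
    abort_gpospom("more deaths than included cases", "gpospom_spec_error")
  }
  structure(list(n_total = n_total, n_without_index = n_without_index,
                 n_minor = n_minor, n_incomplete = n_incomplete,
                 n_included = n_included,
                 n_deaths_among_included = n_deaths_among_included, seed = seed),
            class = "fixture_spec")
}

#' Specification of a statistical cohort
#'
#' The data-generating process the validation battery assumes: integer scores
#' from a discretized truncated normal (defaults: mean 18.18, SD 8.11 — the
#' score distribution reported for the German validation cohort), cases built
#' to score exactly those values, and in-hospital death drawn as
#' Bernoulli(link(score)).
#'
#' @param n Number of cases.
#' @param score_mean,score_sd Normal parameters of the score distribution
#'   before truncation to the attainable range.
#' @param sex_ratio_female Probability a case is female (default 0.4924).
#' @param seed Integer RNG seed (or `NULL`).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, score_mean = 18.18, score_sd = 8.11,
                        sex_ratio_female = 0.4924, seed = NULL) {
  structure(list(n = n, score_mean = score_mean, score_sd = score_sd,
                 sex_ratio_female = sex_ratio_female, seed = seed),
            class = "cohort_spec")
}

#' Exact probability mass of the generator's score distribution
#'
#' The discretized truncated normal assigns each attainable score the normal
#' mass between the midpoints to its attainable neighbours, renormalized to
#' the truncation window. Because the normal is truncated at zero from below,
#' the distribution's exact mean exceeds the `mean` parameter (by about +0.23
#' under the defaults); tests of the generator must therefore compare
#' empirical moments against this pmf, not against the raw parameter.
#'
#' @param table A validated `pospom_table`.
#' @param score_mean,score_sd Normal parameters before truncation.
#' @return A tibble with columns `score` and `prob` (summing to 1).
#' @export
score_distribution_pmf <- function(table, score_mean = 18.18, score_sd = 8.11) {
  att <- attainable_scores(table)
  lo <- min(att) - 0.5
  hi <- max(att) + 0.5
  cuts <- c(lo, utils::head(att, -1) + diff(att) / 2, hi)
  mass <- diff(pnorm(cuts, score_mean, score_sd))
  tibble::tibble(score = att, prob = mass / sum(mass))
}

# truncated-normal draws discretized to the nearest attainable score (ties up)
draw_scores <- function(n, mean, sd, attainable) {
  attainable <- sort(attainable)
  lo <- min(attainable) - 0.5
  hi <- max(attainable) + 0.5
  if (sd == 0) {
    if (mean < lo || mean > hi) {
      abort_gpospom("score distribution has no mass on the attainable range",
                    "gpospom_spec_error")
    }
    if (length(attainable) == 1L) return(rep(attainable, n))
    mid <- utils::head(attainable, -1) + diff(attainable) / 2
    return(rep(attainable[findInterval(mean, mid) + 1L], n))
  }
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  if (phi - plo <= 0) {
    abort_gpospom("score distribution has no mass on the attainable range",
                  "gpospom_spec_error")
  }
  x <- qnorm(plo + runif(n) * (phi - plo), mean, sd)
  if (length(attainable) == 1L) return(rep(attainable, n))
  mid <- utils::head(attainable, -1) + diff(attainable) / 2
  attainable[findInterval(x, mid) + 1L]
}

# registry rows for cases with a prescribed score vector
build_scored_stratum <- function(scores, table, died, sex, link = NULL) {
  n <- length(scores)
  decomp <- score_decompositions(table)
  idx <- match(scores, decomp$score)
  stopifnot(!anyNA(idx))
  age <- sample_age_in_band(n, decomp$band[idx], table)
  icd_by_score <- lapply(seq_len(nrow(decomp)), function(i) {
    vapply(table$comorbidities$prefixes[decomp$comorbidities[[i]]],
           function(p) p[[1]], character(1))
  })
  ops_by_score <- vapply(seq_len(nrow(decomp)),
                         function(i) table$surgeries$prefixes[[decomp$surgery[i]]][[1]],
                         character(1))
  admission <- as.Date("2006-01-01") +
    floor(runif(n) * as.numeric(as.Date("2017-12-31") - as.Date("2006-01-01")))
  los <- 1L + as.integer(floor(runif(n) * 29))
  tibble::tibble(
    case_id = NA_character_,
    age = age,
    sex = sex,
    icd_codes = icd_by_score[idx],
    ops_codes = as.list(ops_by_score[idx]),
    ops_dates = as.list(admission),
    admission_date = admission,
    discharge_date = admission + los,
    discharge_reason = ifelse(died, "07", "01")
  )
}

#' Generate an attrition fixture registry
#'
#' Builds a registry with exact stratum sizes so the eligibility cascade can
#' be exercised and audited: `n_without_index` cases whose only procedure
#' matches no surgery group, `n_minor` index cases younger than 18,
#' `n_incomplete` index cases with a missing age or discharge reason, and the
#' remainder eligible with exactly `n_deaths_among_included` death
#' dispositions. Included cases draw their score from the discretized
#' truncated normal (mean `score_mean`, SD `score_sd`). Row order is a seeded
#' shuffle; output is byte-identical for identical spec and seed.
#'
#' @param spec A [fixture_spec()].
#' @param table A validated `pospom_table` (default [default_point_table()]).
#' @param score_mean,score_sd Score distribution of the included stratum.
#' @return A case tibble in the [read_cases()] layout.
#' @export
generate_fixture <- function(spec, table = default_point_table(),
                             score_mean = 18.18, score_sd = 8.11) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  att <- attainable_scores(table)
  non_index_code <- "8-980"  # ICU complex treatment: matches no surgery group
  stopifnot(!codes_match_any(non_index_code, unlist(table$surgeries$prefixes)))
  index_code <- table$surgeries$prefixes[[1]][[1]]
  empty_date <- function(n) rep(list(as.Date(NA)), n)

  strata <- list()
  if (spec$n_without_index > 0L) {
    n <- spec$n_without_index
    strata$no_index <- tibble::tibble(
      case_id = NA_character_,
      age = as.integer(18 + floor(runif(n) * 73)),
      sex = ifelse(runif(n) < 0.5, "female", "male"),
      icd_codes = rep(list(character(0)), n),
      ops_codes = as.list(rep(non_index_code, n)),
      ops_dates = empty_date(n),
      admission_date = as.Date(NA), discharge_date = as.Date(NA),
      discharge_reason = rep("01", n)
    )
  }
  if (spec$n_minor > 0L) {
    n <- spec$n_minor
    strata$minor <- tibble::tibble(
      case_id = NA_character_,
      age = as.integer(floor(runif(n) * 18)),
      sex = ifelse(runif(n) < 0.5, "female", "male"),
      icd_codes = rep(list(character(0)), n),
      ops_codes = as.list(rep(index_code, n)),
      ops_dates = empty_date(n),
      admission_date = as.Date(NA), discharge_date = as.Date(NA),
      discharge_reason = rep("01", n)
    )
  }
  if (spec$n_incomplete > 0L) {
    n <- spec$n_incomplete
    miss_age <- seq_len(n) <= n / 2
    strata$incomplete <- tibble::tibble(
      case_id = NA_character_,
      age = ifelse(miss_age, NA_integer_, as.integer(18 + floor(runif(n) * 73))),
      sex = ifelse(runif(n) < 0.5, "female", "male"),
      icd_codes = rep(list(character(0)), n),
      ops_codes = as.list(rep(index_code, n)),
      ops_dates = empty_date(n),
      admission_date = as.Date(NA), discharge_date = as.Date(NA),
      discharge_reason = ifelse(miss_age, "01", NA_character_)
    )
  }
  if (spec$n_included > 0L) {
    n <- spec$n_included
    scores <- draw_scores(n, score_mean, score_sd, att)
    died <- rep(FALSE, n)
    died[sample.int(n, spec$n_deaths_among_included)] <- TRUE
    sex <- ifelse(runif(n) < 0.4924, "female", "male")
    strata$included <- build_scored_stratum(scores, table, died, sex)
  }
  registry <- dplyr::bind_rows(strata)
  registry <- registry[sample.int(nrow(registry)), ]
  registry$case_id <- sprintf("C%07d", seq_len(nrow(registry)))
  registry
}

#' Generate a statistical cohort with a known outcome link
#'
#' Draws each case's score from the discretized truncated normal, constructs
#' demographics and codes that score exactly that value (inverse
#' construction, so the generator controls the score distribution the
#' validation consumes), and draws in-hospital death as
#' `Bernoulli(predicted_risk(score, link))`. The intended scores and the
#' generating probabilities are attached as attributes `intended_scores` and
#' `true_risk`, so validation results can be compared against the known
#' truth.
#'
#' @param spec A [cohort_spec()].
#' @param table A validated `pospom_table` (default [default_point_table()]).
#' @param link A `pospom_risk_map` used as the outcome model (default
#'   [default_risk_map()]).
#' @return A case tibble in the [read_cases()] layout, with generator-truth
#'   attributes.
#' @export
generate_statistical <- function(spec, table = default_point_table(),
                                 link = default_risk_map()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  att <- attainable_scores(table)
  scores <- draw_scores(spec$n, spec$score_mean, spec$score_sd, att)
  p <- predicted_risk(scores, link)
  died <- runif(spec$n) < p
  sex <- ifelse(runif(spec$n) < spec$sex_ratio_female, "female", "male")
  registry <- build_scored_stratum(scores, table, died, sex)
  registry$case_id <- sprintf("S%07d", seq_len(nrow(registry)))
  attr(registry, "intended_scores") <- scores
  attr(registry, "true_risk") <- p
  registry
}
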