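# shared fixtures and independent oracles for the test suite

toy_table <- function() {
  load_point_table(system.file("extdata", "toy_point_table.yaml", package = "gpospom"))
}

toy_registry_path <- function() {
  system.file("extdata", "toy_registry.csv", package = "gpospom")
}

# a random small score definition with disjoint prefixes (so toy tables are
# always valid); uses the current RNG stream
random_toy_table <- function(n_bands = sample(2:4, 1), n_com = sample(1:5, 1),
                             n_surg = sample(1:4, 1)) {
  cuts <- sort(sample(19:90, n_bands - 1))
  lower <- c(18, cuts)
  upper <- c(cuts - 1, Inf)
  pospom_table(
    age_bands = data.frame(lower = lower, upper = upper,
                           points = sample(0:8, n_bands, replace = TRUE)),
    comorbidities = tibble::tibble(
      name = sprintf("com_%02d", seq_len(n_com)),
      points = sample(0:6, n_com, replace = TRUE),
      prefixes = lapply(seq_len(n_com), function(i) sprintf("Z%02d", i))
    ),
    surgeries = tibble::tibble(
      name = sprintf("surg_%02d", seq_len(n_surg)),
      points = sample(0:9, n_surg, replace = TRUE),
      prefixes = lapply(seq_len(n_surg), function(i) sprintf("5-9%02d", i))
    ),
    version = "random-toy"
  )
}

# a random case compatible with a toy table: some matching codes with random
# suffixes, some junk codes, random dates
random_cases <- function(n, table) {
  com_prefix <- vapply(table$comorbidities$prefixes, `[[`, character(1), 1)
  surg_prefix <- vapply(table$surgeries$prefixes, `[[`, character(1), 1)
  one_case <- function(i) {
    icd <- c(
      if (length(com_prefix)) sample(com_prefix, sample(0:length(com_prefix), 1)),
      sample(c("A00", "B99", "Y84"), sample(0:2, 1))
    )
    icd <- if (length(icd)) paste0(icd, sample(c("", "1", "9"), length(icd), TRUE)) else character(0)
    n_ops <- sample(0:3, 1)
    ops <- if (n_ops > 0) {
      paste0(sample(c(surg_prefix, "8-980", "1-100"), n_ops, replace = TRUE),
             sample(c("", "0", "2"), n_ops, TRUE))
    } else character(0)
    dates <- as.Date("2015-01-01") + sample(0:365, max(n_ops, 1))
    dates[runif(max(n_ops, 1)) < 0.3] <- NA
    tibble::tibble(
      case_id = sprintf("R%05d", i),
      age = sample(c(10:95, NA), 1, prob = c(rep(1, 86), 2)),
      sex = sample(c("female", "male", "other"), 1),
      icd_codes = list(normalize_code(icd)),
      ops_codes = list(normalize_code(ops)),
      ops_dates = list(dates[seq_len(max(n_ops, 0))]),
      admission_date = as.Date("2015-01-01"),
      discharge_date = as.Date("2015-02-01"),
      discharge_reason = sample(c("01", "07", NA_character_), 1, prob = c(8, 1, 1))
    )
  }
  dplyr::bind_rows(lapply(seq_len(n), one_case))
}

# one fully specified case record
make_case <- function(id = "X1", age = 60, sex = "female", icd = character(0),
                      ops = character(0), ops_dates = NULL, reason = "01") {
  if (is.null(ops_dates)) ops_dates <- as.Date(rep(NA_character_, length(ops)))
  tibble::tibble(
    case_id = id, age = as.integer(age), sex = sex,
    icd_codes = list(normalize_code(icd)),
    ops_codes = list(normalize_code(ops)),
    ops_dates = list(as.Date(ops_dates)),
    admission_date = as.Date(NA), discharge_date = as.Date(NA),
    discharge_reason = reason
  )
}

# a directly constructed scored cohort (bypasses the scoring engine) for
# metric tests
fake_scored <- function(score, died, sex = NULL, age = NULL,
                        predicted = NA_real_) {
  n <- length(score)
  tibble::tibble(
    case_id = sprintf("F%06d", seq_len(n)),
    age = if (is.null(age)) rep(50L, n) else as.integer(age),
    sex = if (is.null(sex)) rep("female", n) else sex,
    score = as.integer(score),
    age_points = as.integer(score), comorbidity_points = 0L, surgery_points = 0L,
    surgery_group = "g", matched_comorbidities = rep(list(character(0)), n),
    predicted_risk = predicted, died = as.logical(died)
  )
}

# --- independent oracles -----------------------------------------------------

# pairwise tie-corrected AUC by brute force over all death-survivor pairs
auc_pairwise <- function(scores, outcomes) {
  d <- scores[as.logical(outcomes)]
  s <- scores[!as.logical(outcomes)]
  total <- 0
  for (x in d) total <- total + sum(x > s) + 0.5 * sum(x == s)
  total / (length(d) * length(s))
}

# pairwise AUC for large cohorts whose predictor takes few distinct values:
# exact enumeration of death-survivor pairs grouped by predictor value
auc_pairwise_grouped <- function(values, outcomes) {
  v <- sort(unique(values))
  d <- vapply(v, function(x) sum(outcomes & values == x), numeric(1))
  s <- vapply(v, function(x) sum(!outcomes & values == x), numeric(1))
  conc <- 0
  for (i in seq_along(v)) {
    if (i > 1) conc <- conc + d[i] * sum(s[seq_len(i - 1)])
    conc <- conc + 0.5 * d[i] * s[i]
  }
  conc / (sum(d) * sum(s))
}

# comorbidity points by brute-force double loop over groups x codes
comorbidity_oracle <- function(codes, table) {
  pts <- 0L
  matched <- character(0)
  for (g in seq_len(nrow(table$comorbidities))) {
    hit <- FALSE
    for (p in table$comorbidities$prefixes[[g]]) {
      for (code in codes) if (startsWith(code, p)) hit <- TRUE
    }
    if (hit) {
      pts <- pts + table$comorbidities$points[g]
      matched <- c(matched, table$comorbidities$name[g])
    }
  }
  list(points = as.integer(pts), matched = matched)
}

# age points by linear scan over bands
age_points_oracle <- function(age, table) {
  for (i in seq_len(nrow(table$age_bands))) {
    b <- table$age_bands[i, ]
    if (age >= b$lower && age <= b$upper) return(b$points)
  }
  NA_integer_
}

# closed-form unweighted OLS
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}
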