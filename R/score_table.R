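#' Construct a POSPOM point table
#'
#' The point table is the full definition of the score: age bands, comorbidity
#' groups identified by ICD-10 code prefixes, and index-surgery groups
#' identified by OPS code prefixes, each carrying a non-negative integer point
#' value. The published score has 15 comorbidity groups; the number is not
#' enforced so that toy tables can be built for testing. Point values are
#' configuration supplied by the user (transcribed from the original
#' publication's supplementary table), never hard-coded by this package.
#'
#' @param age_bands Data frame with columns `lower`, `upper` (use `Inf` for an
#'   open-ended top band) and `points`. Bands are inclusive on both ends.
#' @param comorbidities Data frame with columns `name`, `points` and a
#'   list-column `prefixes` of ICD-10 prefixes (normalized on construction).
#' @param surgeries Data frame with columns `name`, `points` and a list-column
#'   `prefixes` of OPS prefixes.
#' @param version Free-text provenance string.
#' @return An object of class `pospom_table`.
#' @seealso [load_point_table()], [validate_point_table()],
#'   [max_attainable_score()]
#' @export
pospom_table <- function(age_bands, comorbidities, surgeries, version = "unversioned") {
  age_bands <- tibble::as_tibble(age_bands)
  age_bands$lower <- as.numeric(age_bands$lower)
  age_bands$upper <- as.numeric(age_bands$upper)
  age_bands$points <- as.integer(age_bands$points)
  norm_groups <- function(g) {
    g <- tibble::as_tibble(g)
    g$name <- as.character(g$name)
    g$points <- as.integer(g$points)
    g$prefixes <- lapply(g$prefixes, normalize_code)
    g
  }
  structure(
    list(
      version = as.character(version),
      age_bands = age_bands[order(age_bands$lower), ],
      comorbidities = norm_groups(comorbidities),
      surgeries = norm_groups(surgeries)
    ),
    class = "pospom_table"
  )
}

#' @export
print.pospom_table <- function(x, ...) {
  cat("<pospom_table> version:", x$version, "\n")
  cat("  age bands:    ", nrow(x$age_bands), "\n")
  cat("  comorbidities:", nrow(x$comorbidities), "\n")
  cat("  surgeries:    ", nrow(x$surgeries), "\n")
  cat("  max attainable score:", max_attainable_score(x), "\n")
  invisible(x)
}

#' Load a point table from YAML or JSON
#'
#' Reads a point-table file with top-level keys `version`, `age_bands`,
#' `comorbidities`, `surgeries` (see the JSON Schema shipped under
#' `extdata/schema/`). All code prefixes are normalized (uppercase, dots and
#' whitespace stripped) on load, and the result must pass
#' [validate_point_table()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param format `"auto"` (from the extension), `"yaml"` or `"json"`.
#' @return A validated `pospom_table`.
#' @export
load_point_table <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  raw <- read_config(path, format)
  for (key in c("age_bands", "comorbidities", "surgeries")) {
    if (is.null(raw[[key]])) {
      abort_gpospom(sprintf("point table '%s': missing top-level key '%s'", path, key),
                    "gpospom_format_error")
    }
  }
  bands <- do.call(rbind, lapply(raw$age_bands, function(b) {
    upper <- b$upper
    if (is.null(upper) || (is.character(upper) && toupper(upper) %in% c("INF", ".INF")) ||
        is.na(suppressWarnings(as.numeric(upper)))) {
      upper <- Inf
    }
    data.frame(lower = as.numeric(b$lower), upper = as.numeric(upper),
               points = as.integer(b$points))
  }))
  groups <- function(entries) {
    tibble::tibble(
      name = vapply(entries, function(g) as.character(g$name), character(1)),
      points = vapply(entries, function(g) as.integer(g$points), integer(1)),
      prefixes = lapply(entries, function(g) as.character(unlist(g$prefixes)))
    )
  }
  table <- pospom_table(
    age_bands = bands,
    comorbidities = groups(raw$comorbidities),
    surgeries = groups(raw$surgeries),
    version = raw$version %||% "unversioned"
  )
  violations <- validate_point_table(table)
  if (length(violations) > 0L) {
    abort_gpospom(
      paste0("point table '", path, "' failed validation:\n  - ",
             paste(violations, collapse = "\n  - ")),
      "gpospom_validation_error"
    )
  }
  table
}

#' Serialize a point table to YAML or JSON
#'
#' Inverse of [load_point_table()]: `load(write(x))` round-trips to an equal
#' table.
#'
#' @param table A `pospom_table`.
#' @param path Output path.
#' @param format `"auto"`, `"yaml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_point_table <- function(table, path, format = c("auto", "yaml", "json")) {
  format <- resolve_format(path, match.arg(format))
  obj <- list(
    version = table$version,
    age_bands = lapply(seq_len(nrow(table$age_bands)), function(i) {
      b <- table$age_bands[i, ]
      list(lower = b$lower, upper = if (is.infinite(b$upper)) "Inf" else b$upper,
           points = b$points)
    }),
    comorbidities = groups_to_list(table$comorbidities),
    surgeries = groups_to_list(table$surgeries)
  )
  write_config(obj, path, format)
  invisible(path)
}

groups_to_list <- function(g) {
  lapply(seq_len(nrow(g)), function(i) {
    list(name = g$name[i], points = g$points[i],
         prefixes = as.list(g$prefixes[[i]]))
  })
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
}

read_config <- function(path, format = "auto") {
  if (!file.exists(path)) {
    abort_gpospom(sprintf("file not found: '%s'", path), "gpospom_io_error")
  }
  format <- resolve_format(path, format)
  if (format == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

write_config <- function(obj, path, format) {
  if (format == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
}

#' Validate a POSPOM point table
#'
#' Checks every structural invariant of the score definition and returns a
#' character vector of human-readable violations (empty when the table is
#' valid). Checked: age bands are non-overlapping and jointly cover every age
#' from 18 upwards with an open-ended top band; all point values are
#' non-negative; every comorbidity and surgery group has at least one prefix;
#' group names are unique; and no two distinct surgery groups can both match
#' one identical full OPS code (which happens exactly when a prefix of one
#' group is a prefix of — or equal to — a prefix of the other).
#'
#' @param table A `pospom_table`.
#' @param min_age Lowest age the bands must cover (default 18, the adult
#'   eligibility threshold).
#' @return Character vector of violation descriptions; `character(0)` if valid.
#' @export
validate_point_table <- function(table, min_age = 18) {
  v <- character(0)
  ab <- table$age_bands
  if (nrow(ab) == 0L) {
    v <- c(v, "age coverage gap: no age bands defined")
  } else {
    if (any(ab$points < 0, na.rm = TRUE)) v <- c(v, "age band with negative points")
    if (min(ab$lower) > min_age) {
      v <- c(v, sprintf("age coverage gap: first band starts at %g, must cover age %g",
                        min(ab$lower), min_age))
    }
    if (nrow(ab) > 1L) {
      for (i in seq_len(nrow(ab) - 1L)) {
        if (ab$upper[i] >= ab$lower[i + 1L]) {
          v <- c(v, sprintf("age bands overlap: [%g,%g] and [%g,%g]",
                            ab$lower[i], ab$upper[i], ab$lower[i + 1L], ab$upper[i + 1L]))
        } else if (ab$lower[i + 1L] != ab$upper[i] + 1) {
          v <- c(v, sprintf("age coverage gap: ages %g-%g fall between bands",
                            ab$upper[i] + 1, ab$lower[i + 1L] - 1))
        }
      }
    }
    if (is.finite(ab$upper[nrow(ab)])) {
      v <- c(v, sprintf("age coverage gap: ages above %g are uncovered (no open-ended band)",
                        ab$upper[nrow(ab)]))
    }
  }
  v <- c(v, validate_groups(table$comorbidities, "comorbidity"))
  v <- c(v, validate_groups(table$surgeries, "surgery"))
  # surgery ambiguity: one full code may never match two distinct groups
  sg <- table$surgeries
  if (nrow(sg) > 1L) {
    for (i in seq_len(nrow(sg) - 1L)) {
      for (j in (i + 1L):nrow(sg)) {
        pi <- sg$prefixes[[i]]; pj <- sg$prefixes[[j]]
        clash <- outer(pi, pj, function(a, b) startsWith(a, b) | startsWith(b, a))
        if (any(clash)) {
          k <- which(clash, arr.ind = TRUE)[1, ]
          v <- c(v, sprintf(
            "surgery ambiguity: groups '%s' and '%s' can both match a code (prefixes '%s' / '%s')",
            sg$name[i], sg$name[j], pi[k[1]], pj[k[2]]))
        }
      }
    }
  }
  v
}

validate_groups <- function(g, kind) {
  v <- character(0)
  if (nrow(g) == 0L) return(v)
  if (anyDuplicated(g$name)) {
    v <- c(v, sprintf("duplicate %s group name: '%s'", kind, g$name[duplicated(g$name)][1]))
  }
  for (i in seq_len(nrow(g))) {
    if (length(g$prefixes[[i]]) == 0L || all(!nzchar(g$prefixes[[i]]))) {
      v <- c(v, sprintf("%s group '%s' has an empty prefix list", kind, g$name[i]))
    }
    if (is.na(g$points[i]) || g$points[i] < 0L) {
      v <- c(v, sprintf("%s group '%s' has negative or missing points", kind, g$name[i]))
    }
  }
  v
}

#' Maximum attainable POSPOM score under a table
#'
#' The bound is the maximum age-band points plus the sum of all comorbidity
#' points (every group can co-occur) plus the maximum surgery points. Every
#' computed case score is bounded by this value.
#'
#' @param table A `pospom_table`.
#' @return A non-negative integer.
#' @export
max_attainable_score <- function(table) {
  max_or0 <- function(x) if (length(x)) max(x) else 0L
  as.integer(max_or0(table$age_bands$points) +
               sum(table$comorbidities$points) +
               max_or0(table$surgeries$points))
}

#' Construct a score-to-probability risk map
#'
#' Maps an integer POSPOM score to a predicted in-hospital mortality
#' probability, either via an explicit per-score lookup table (`mode =
#' "table"`) or a logistic equation `plogis(intercept + slope * score)`
#' (`mode = "logistic"`).
#'
#' @param mode `"logistic"` or `"table"`.
#' @param intercept,slope Logit-scale coefficients (logistic mode).
#' @param table Named numeric vector or list mapping score (name) to
#'   probability (table mode).
#' @return An object of class `pospom_risk_map`.
#' @export
risk_map <- function(mode = c("logistic", "table"), intercept = NULL,
                     slope = NULL, table = NULL) {
  mode <- match.arg(mode)
  if (mode == "logistic") {
    if (is.null(intercept) || is.null(slope)) {
      abort_gpospom("logistic risk map needs 'intercept' and 'slope'",
                    "gpospom_validation_error")
    }
    map <- structure(list(mode = "logistic",
                          intercept = as.numeric(intercept),
                          slope = as.numeric(slope)),
                     class = "pospom_risk_map")
  } else {
    tab <- unlist(table)
    if (is.null(names(tab)) || any(!nzchar(names(tab)))) {
      abort_gpospom("table risk map needs scores as names", "gpospom_validation_error")
    }
    if (any(tab < 0 | tab > 1)) {
      abort_gpospom("table risk map probabilities must lie in [0,1]",
                    "gpospom_validation_error")
    }
    map <- structure(list(mode = "table", table = tab),
                     class = "pospom_risk_map")
  }
  map
}

#' Load a risk map from YAML or JSON
#'
#' File keys: `mode`, then either `logistic: {intercept, slope}` or
#' `table: {<score>: <probability>, ...}`.
#'
#' @inheritParams load_point_table
#' @return A `pospom_risk_map`.
#' @export
load_risk_map <- function(path, format = c("auto", "yaml", "json")) {
  raw <- read_config(path, match.arg(format))
  mode <- raw$mode %||% "logistic"
  if (identical(mode, "logistic")) {
    risk_map("logistic", intercept = raw$logistic$intercept, slope = raw$logistic$slope)
  } else {
    risk_map("table", table = raw$table)
  }
}

#' Predicted mortality probability for a score
#'
#' In logistic mode returns `plogis(intercept + slope * score)`; in table mode
#' looks the score up and errors on scores the table does not define.
#' Vectorized over `score`.
#'
#' @param score Integer score(s).
#' @param map A `pospom_risk_map`.
#' @return Probabilities in `[0, 1]`.
#' @export
predicted_risk <- function(score, map) {
  stopifnot(inherits(map, "pospom_risk_map"))
  if (map$mode == "logistic") {
    plogis(map$intercept + map$slope * score)
  } else {
    idx <- match(as.character(score), names(map$table))
    if (anyNA(idx)) {
      abort_gpospom(
        sprintf("risk map does not define score(s): %s",
                paste(unique(score[is.na(idx)]), collapse = ", ")),
        "gpospom_undefined_score_error"
      )
    }
    unname(map$table[idx])
  }
}

#' Validate a risk map against a point table
#'
#' In table mode the map must define a probability for every attainable score
#' of `table`; in logistic mode probabilities are automatically in `[0, 1]`
#' and monotone increasing when `slope > 0`.
#'
#' @param map A `pospom_risk_map`.
#' @param table A `pospom_table` supplying the attainable score set.
#' @return Character vector of violations (empty if valid).
#' @export
validate_risk_map <- function(map, table) {
  v <- character(0)
  if (map$mode == "table") {
    attainable <- attainable_scores(table)
    missing <- setdiff(attainable, as.integer(names(map$table)))
    if (length(missing) > 0L) {
      v <- c(v, sprintf("risk table leaves attainable scores undefined: %s",
                        paste(head(missing, 10), collapse = ", ")))
    }
  }
  v
}
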