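#' Normalize an ICD-10 or OPS code
#'
#' Uppercases and strips dots and whitespace, so that `"I50.1"` becomes
#' `"I501"` and `"5-511.2"` becomes `"5-5112"`. Hyphens are structural in OPS
#' codes and are kept. Normalization is idempotent and is applied to every
#' code and prefix on ingest, so matching never depends on the punctuation
#' dialect of a particular export.
#'
#' @param x Character vector of codes (NA passes through).
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code(c("I50.1", " e11.9 ", "5-511.2"))
#' @export
normalize_code <- function(x) {
  if (length(x) == 0L) return(character(0))
  toupper(gsub("[.[:space:]]", "", as.character(x)))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in clinical
#' reports conventionally round half up. `round_half_up(2.035, 2)` is 2.04.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# code matches prefix iff normalized code starts with normalized prefix
codes_match_any <- function(codes, prefixes) {
  if (length(codes) == 0L || length(prefixes) == 0L) return(FALSE)
  for (p in prefixes) if (any(startsWith(codes, p))) return(TRUE)
  FALSE
}

# split a "|"-joined list field into a character vector (zero-length for "")
split_list_field <- function(x, sep) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, sep, fixed = TRUE)[[1]]
}

join_list_field <- function(x, sep) {
  if (length(x) == 0L) return("")
  paste(x, collapse = sep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_gpospom <- function(msg, class) {
  stop(structure(
    class = c(class, "gpospom_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
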