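# Shared vocabularies, rounding conventions and small text helpers.

#' The four population characteristics
#'
#' @return Character vector of the characteristic kinds handled by the
#'   extraction pipeline.
#' @export
characteristics <- function() {
  c("AGE", "SEX", "NATIONALITY", "OFFENDER_TYPE")
}

#' Australian Bureau of Statistics age groups
#'
#' The standardized age bins used for numeric and textual age mentions:
#' minors (<18), six adult bins, and an `unknown_adult` bucket for bare
#' "adults" mentions that carry no numeric information. Numeric bins are
#' closed integer intervals: `18-24` covers ages 18 to 24 inclusive, `65+`
#' is open-ended.
#'
#' @return A tibble with columns `group`, `lo`, `hi` (`hi` is `Inf` for the
#'   open-ended bin; `unknown_adult` has `NA` bounds since it never matches
#'   a numeric range).
#' @export
age_groups <- function() {
  tibble::tibble(
    group = c("minor", "18-24", "25-34", "35-44", "45-54", "55-64", "65+",
              "unknown_adult"),
    lo = c(0, 18, 25, 35, 45, 55, 65, NA),
    hi = c(17, 24, 34, 44, 54, 64, Inf, NA)
  )
}

#' Sex categories
#' @return The five closed sex category labels.
#' @export
sex_categories <- function() {
  c("male", "female", "transgender", "transgender_man", "transgender_woman")
}

#' Offender-type categories
#' @return The seven offender category labels (six substantive plus
#'   `miscellaneous` for surfaces that map to no substantive category).
#' @export
offender_categories <- function() {
  c("child_crime_related", "sex", "violent", "nonviolent", "mentally_ill",
    "drug_related", "miscellaneous")
}

#' Collapse runs of whitespace to single spaces
#'
#' Applied to abstract text before any matching: the lexical-pattern rules
#' anchor on token sequences and assume single-space separation.
#'
#' @param x Character vector.
#' @return Character vector with internal whitespace collapsed and ends
#'   trimmed.
#' @export
normalize_whitespace <- function(x) {
  stringr::str_squish(x)
}

# Round half-up to `digits` decimals. Used for all descriptive analytics
# percentages and the per-1000 rates; base round() is half-even and gets
# e.g. 1000*138/3289 wrong relative to the published tables.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

# Truncate to `digits` decimals. The evaluation metrics tables use
# truncation, not rounding (see the methods vignette); the small epsilon
# guards against binary-representation artefacts like 93.1 stored as
# 93.0999...
trunc_dec <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 1e-9) / m
}

# Percentage of num/den, half-up to one decimal.
pct <- function(num, den, digits = 1) {
  round_half_up(100 * num / den, digits)
}

# Case/hyphen-insensitive folding used for dictionary lookup keys:
# lowercase, hyphens (ASCII and typographic) treated as spaces, whitespace
# squashed.
fold_term <- function(x) {
  stringr::str_squish(stringr::str_replace_all(tolower(x), "[-‐‑–]", " "))
}

# A canonical key for a standardized value row, used for set semantics:
# attribute NA and empty string compare equal.
value_key <- function(characteristic, value, attribute) {
  attribute <- ifelse(is.na(attribute) | attribute == "", "", attribute)
  paste(characteristic, value, attribute, sep = "\r")
}

# An empty standardized-values tibble with the canonical schema.
empty_values <- function() {
  tibble::tibble(
    pmid = character(), characteristic = character(),
    value = character(), attribute = character()
  )
}

assert_values_frame <- function(x, arg = "values") {
  need <- c("pmid", "characteristic", "value")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    rlang::abort(sprintf(
      "`%s` must be a data frame with columns %s",
      arg, paste(need, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)
  if (!"attribute" %in% names(x)) x$attribute <- NA_character_
  bad <- setdiff(unique(x$characteristic), characteristics())
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "unknown characteristic kind(s) in `%s`: %s",
      arg, paste(bad, collapse = ", ")
    ))
  }
  x
}
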