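# Standardization: raw mention surfaces -> canonical values (ABS age
# groups, five sex categories, nationality demonyms, the two-level
# offender taxonomy), plus per-abstract deduplication.

#' Load the offender category table
#'
#' Maps each offense-lexicon canonical to one of the seven offender
#' categories and an optional attribute (the specific descriptor kept
#' alongside the higher offense node, e.g. `rape` under the `sex`
#' category; generic canonicals such as "sex offence" carry no
#' attribute). Columns: `canonical`, `category`, `attribute`.
#'
#' @param path Path to the category TSV (defaults to the shipped table).
#' @return A tibble `canonical`/`category`/`attribute`.
#' @export
load_offense_categories <- function(path = system.file("extdata", "tables",
                                                       "offense_categories.tsv",
                                                       package = "jhminer")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("canonical", "category")
  if (!all(need %in% names(tab))) {
    rlang::abort("offense category table needs columns canonical, category")
  }
  if (!"attribute" %in% names(tab)) tab$attribute <- NA_character_
  bad <- setdiff(unique(tab$category), offender_categories())
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown offender categor(ies) in table: %s",
                         paste(bad, collapse = ", ")))
  }
  dup <- tab$canonical[duplicated(fold_term(tab$canonical))]
  if (length(dup) > 0) {
    rlang::abort(sprintf("offense category table: duplicate canonical(s): %s",
                         paste(dup, collapse = ", ")))
  }
  miss_attr <- tab$category == "miscellaneous" &
    (is.na(tab$attribute) | !nzchar(tab$attribute))
  if (any(miss_attr)) {
    rlang::abort("miscellaneous categories require an attribute")
  }
  tab
}

# Category-closure validation: every offense-lexicon canonical must map to
# exactly one category. Run at load time by the pipeline wrappers.
validate_offense_closure <- function(offense_lexicon, categories) {
  missing <- setdiff(fold_term(unique(offense_lexicon$canonical)),
                     fold_term(categories$canonical))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "offense canonical(s) without a category mapping: %s",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Map numeric age bounds to standardized age groups
#'
#' A numeric range maps to every ABS group whose closed integer interval
#' it overlaps: ages 18-25 touch both `18-24` and `25-34`; a range fully
#' inside one group yields a singleton.
#'
#' @param low,high Bounds in years (`high` may be `Inf`).
#' @return Character vector of group labels.
#' @export
age_groups_for_range <- function(low, high) {
  g <- age_groups()
  g <- g[!is.na(g$lo), ]
  g$group[low <= g$hi & high >= g$lo]
}

#' Standardize one age mention
#'
#' Numeric captures (parsed bounds) map by interval overlap; textual terms
#' map through the shipped textual-age dictionary (bare "adults" goes to
#' `unknown_adult`). Unknown textual terms yield an empty result with a
#' warning (the mention is dropped).
#'
#' @param surface Mention surface text.
#' @param age_low,age_high Parsed numeric bounds, or `NA` for textual
#'   mentions.
#' @param age_lexicon The textual-age lexicon (canonical labels are group
#'   names joined by `|`).
#' @return Character vector of age-group labels (possibly empty).
#' @export
normalize_age <- function(surface, age_low = NA, age_high = NA,
                          age_lexicon = default_lexicons()[["age_terms"]]) {
  if (!is.na(age_low)) {
    return(age_groups_for_range(age_low, age_high))
  }
  canon <- lookup_canonical(surface, age_lexicon)
  if (is.na(canon)) {
    rlang::warn(sprintf("dropping unknown textual age term '%s'", surface))
    return(character(0))
  }
  strsplit(canon, "|", fixed = TRUE)[[1]]
}

#' Standardize a sex mention
#'
#' The surface is scanned with the sex lexicon, so conjoined surfaces
#' ("boys and girls") yield multiple categories. Unknown surfaces yield an
#' empty result with a warning.
#'
#' @param surface Mention surface text.
#' @param sex_lexicon The sex-terms lexicon.
#' @return Character vector of sex category labels (possibly empty).
#' @export
normalize_sex <- function(surface, sex_lexicon = default_lexicons()[["sex_terms"]]) {
  if (is.na(surface) || !nzchar(str_trim(surface))) {
    rlang::warn("dropping empty sex mention")
    return(character(0))
  }
  hits <- match_terms(normalize_whitespace(surface), sex_lexicon)
  if (nrow(hits) == 0) {
    rlang::warn(sprintf("dropping unknown sex term '%s'", surface))
    return(character(0))
  }
  unique(hits$canonical)
}

#' Standardize a nationality mention
#'
#' Country, city, state/county and nationality surfaces map to one
#' canonical demonym; all US subdivisions standardize to `American`;
#' defunct nationalities (e.g. Czechoslovakian) map to `miscellaneous`.
#' The mapping is total over the shipped geo lexicons.
#'
#' @param surface Mention surface text.
#' @param lexicons Named list holding the geo lexicons.
#' @return A single demonym label (or `NA` with a warning if the surface
#'   is in no geo lexicon, which cannot happen for rule-captured slots).
#' @export
normalize_nationality <- function(surface, lexicons = default_lexicons()) {
  geo <- lexicons[intersect(geo_lexicons(), names(lexicons))]
  canon <- lookup_canonical(surface, geo, precedence = geo_lexicons())
  if (is.na(canon)) {
    rlang::warn(sprintf("dropping unknown nationality surface '%s'", surface))
  }
  canon
}

#' Standardize an offender-type mention
#'
#' Two-level mapping: the surface resolves to an offense canonical through
#' the offense/population lexicons, and the canonical resolves to a
#' `(category, attribute)` pair through the category table. Canonicals
#' with no category mapping fall back to `miscellaneous` with the
#' canonical (lower-cased) as the attribute, so the mapping is total.
#'
#' @param surface Mention surface text.
#' @param lexicons Named list holding `offense_terms` (and optionally
#'   `population_terms`).
#' @param categories Category table from [load_offense_categories()].
#' @return A one-row tibble `category`/`attribute`.
#' @export
normalize_offender <- function(surface, lexicons = default_lexicons(),
                               categories = load_offense_categories()) {
  lex <- lexicons[intersect(c("offense_terms", "population_terms"), names(lexicons))]
  canon <- lookup_canonical(surface, lex,
                            precedence = c("offense_terms", "population_terms"))
  if (is.na(canon)) {
    # modifier-carrying surfaces ("Male sex offenders"): take the longest
    # dictionary hit inside the surface
    hits <- match_terms(normalize_whitespace(surface), lex)
    if (nrow(hits) > 0) {
      canon <- hits$canonical[which.max(hits$end - hits$start)]
    }
  }
  if (is.na(canon)) canon <- tolower(str_trim(surface))
  hit <- match(fold_term(canon), fold_term(categories$canonical))
  if (is.na(hit)) {
    tibble::tibble(category = "miscellaneous", attribute = tolower(canon))
  } else {
    att <- categories$attribute[hit]
    tibble::tibble(category = categories$category[hit],
                   attribute = ifelse(is.na(att) | !nzchar(att), NA_character_, att))
  }
}

#' Standardize a raw-mentions table
#'
#' Applies the per-characteristic standardizations to every mention row
#' (an age mention can yield several group rows; a conjoined sex mention
#' several category rows) and returns the flat standardized-values table,
#' still with duplicates — call [dedupe_values()] for abstract-level sets.
#'
#' @param mentions Mentions tibble from [extract_mentions()] (needs a
#'   `pmid` column) or [apply_rules()] (a `pmid` of `NA` is filled in).
#' @param lexicons Named list of lexicons.
#' @param categories Offender category table.
#' @return Standardized-values tibble (`pmid`, `characteristic`, `value`,
#'   `attribute`).
#' @export
normalize_mentions <- function(mentions, lexicons = default_lexicons(),
                               categories = load_offense_categories()) {
  if (!"pmid" %in% names(mentions)) mentions$pmid <- NA_character_
  if (nrow(mentions) == 0) return(empty_values())
  rows <- purrr::map(seq_len(nrow(mentions)), function(i) {
    m <- mentions[i, ]
    if (m$characteristic == "AGE") {
      groups <- normalize_age(m$surface, m$age_low, m$age_high,
                              lexicons[["age_terms"]])
      if (length(groups) == 0) return(NULL)
      tibble::tibble(pmid = m$pmid, characteristic = "AGE", value = groups,
                     attribute = NA_character_)
    } else if (m$characteristic == "SEX") {
      cats <- normalize_sex(m$surface, lexicons[["sex_terms"]])
      if (length(cats) == 0) return(NULL)
      tibble::tibble(pmid = m$pmid, characteristic = "SEX", value = cats,
                     attribute = NA_character_)
    } else if (m$characteristic == "NATIONALITY") {
      demonym <- normalize_nationality(m$surface, lexicons)
      if (is.na(demonym)) return(NULL)
      tibble::tibble(pmid = m$pmid, characteristic = "NATIONALITY",
                     value = demonym, attribute = NA_character_)
    } else {
      ov <- normalize_offender(m$surface, lexicons, categories)
      tibble::tibble(pmid = m$pmid, characteristic = "OFFENDER_TYPE",
                     value = ov$category, attribute = ov$attribute)
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_values())
  purrr::list_rbind(rows)
}

#' Deduplicate standardized values per abstract
#'
#' Structural-equality set semantics over `(pmid, characteristic, value,
#' attribute)`; order-independent and idempotent.
#'
#' @param values Standardized-values tibble.
#' @return The tibble with duplicate rows removed, sorted for stable
#'   output.
#' @export
dedupe_values <- function(values) {
  values <- assert_values_frame(values)
  out <- dplyr::distinct(values, .data$pmid, .data$characteristic,
                         .data$value, .data$attribute)
  dplyr::arrange(out, .data$pmid, .data$characteristic, .data$value)
}

#' Run the full extraction pipeline on a corpus
#'
#' Whitespace normalization, rule application, standardization and
#' per-abstract deduplication in one call.
#'
#' @param corpus Corpus tibble.
#' @param lexicons Named list of lexicons (defaults to the shipped seed
#'   set).
#' @param rules Compiled rules (defaults to the shipped starter set).
#' @param categories Offender category table.
#' @param keep_mentions Attach the raw mentions tibble as the `mentions`
#'   attribute of the result.
#' @return Deduplicated standardized-values tibble.
#' @export
extract_characteristics <- function(corpus, lexicons = default_lexicons(),
                                    rules = default_rules(lexicons),
                                    categories = load_offense_categories(),
                                    keep_mentions = FALSE) {
  validate_offense_closure(lexicons[["offense_terms"]], categories)
  mentions <- extract_mentions(corpus, rules)
  values <- dedupe_values(normalize_mentions(mentions, lexicons, categories))
  if (keep_mentions) attr(values, "mentions") <- mentions
  values
}
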