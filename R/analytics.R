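# Descriptive gap analytics over per-abstract standardized values:
# coverage, age-group and offender-type distributions, sex-proportion
# time series, and crude vs prisoner-population-adjusted country
# rankings. All percentages are half-up to one decimal.

#' Corpus-level characteristic coverage
#'
#' How many abstracts report each characteristic, all four, or none.
#'
#' @param values Deduplicated standardized-values tibble.
#' @param corpus Corpus tibble (defines the abstract universe).
#' @return A long tibble (`statistic`, `n`, `pct`) with rows `total`,
#'   one per characteristic, `all_four` and `none`; percentages are of
#'   the total corpus.
#' @export
summarize_corpus <- function(values, corpus) {
  values <- assert_values_frame(values)
  validate_corpus(corpus)
  total <- nrow(corpus)
  if (total == 0) rlang::abort("summarize_corpus: empty corpus")
  stray <- setdiff(values$pmid, corpus$pmid)
  if (length(stray) > 0) {
    rlang::abort(sprintf("values for pmid(s) not in corpus: %s",
                         paste(head(stray, 5), collapse = ", ")))
  }
  per_char <- vapply(characteristics(), function(k) {
    dplyr::n_distinct(values$pmid[values$characteristic == k])
  }, integer(1))
  n_chars <- values |>
    dplyr::distinct(.data$pmid, .data$characteristic) |>
    dplyr::count(.data$pmid)
  all_four <- sum(n_chars$n == length(characteristics()))
  none <- total - dplyr::n_distinct(values$pmid)
  n <- unname(c(total, per_char, all_four, none))
  tibble::tibble(
    statistic = c("total", tolower(characteristics()), "all_four", "none"),
    n = n,
    pct = pct(n, total)
  )
}

#' Age-group distribution over age-reporting abstracts
#'
#' One abstract can include more than one age group, so percentages need
#' not sum to 100; the denominator is the number of age-reporting
#' abstracts.
#'
#' @param values Deduplicated standardized-values tibble.
#' @return A tibble (`group`, `n`, `denom`, `pct`) with one row per ABS
#'   group in canonical order.
#' @export
age_distribution <- function(values) {
  values <- assert_values_frame(values)
  age <- values[values$characteristic == "AGE", ]
  denom <- dplyr::n_distinct(age$pmid)
  counts <- age |>
    dplyr::distinct(.data$pmid, .data$value) |>
    dplyr::count(.data$value)
  out <- tibble::tibble(group = age_groups()$group) |>
    dplyr::left_join(counts, by = c(group = "value"))
  out$n <- tidyr::replace_na(out$n, 0L)
  out$denom <- denom
  out$pct <- if (denom > 0) pct(out$n, denom) else NA_real_
  out
}

# Classify each abstract's sex-category set.
sex_flags <- function(values) {
  values[values$characteristic == "SEX", ] |>
    dplyr::distinct(.data$pmid, .data$value) |>
    dplyr::summarise(
      female_only = setequal(.data$value, "female"),
      male_only = setequal(.data$value, "male"),
      both = all(c("male", "female") %in% .data$value),
      .by = "pmid"
    )
}

#' Yearly proportions of female-only, male-only and mixed-sex abstracts
#'
#' `female_only` means the abstract's deduplicated sex set is exactly
#' `{female}` (likewise `male_only`); `both` means it contains male and
#' female. The denominator is the number of sex-reporting abstracts that
#' year; years with a zero denominator are omitted, and abstracts with a
#' missing year are excluded with a reported count.
#'
#' @param values Deduplicated standardized-values tibble.
#' @param corpus Corpus tibble supplying publication years.
#' @return A long tibble (`year`, `series`, `n`, `denom`, `pct`).
#' @export
sex_series <- function(values, corpus) {
  values <- assert_values_frame(values)
  validate_corpus(corpus)
  flags <- sex_flags(values) |>
    dplyr::left_join(corpus[, c("pmid", "year")], by = "pmid")
  n_noyear <- sum(is.na(flags$year))
  if (n_noyear > 0) {
    rlang::inform(sprintf("sex_series: excluded %d abstract(s) without a year",
                          n_noyear))
  }
  flags <- flags[!is.na(flags$year), ]
  if (nrow(flags) == 0) {
    return(tibble::tibble(year = integer(), series = character(),
                          n = integer(), denom = integer(), pct = double()))
  }
  flags |>
    tidyr::pivot_longer(cols = c("female_only", "male_only", "both"),
                        names_to = "series", values_to = "hit") |>
    dplyr::summarise(n = sum(.data$hit), denom = dplyr::n_distinct(.data$pmid),
                     .by = c("year", "series")) |>
    dplyr::mutate(pct = pct(.data$n, .data$denom)) |>
    dplyr::arrange(.data$year, .data$series)
}

#' Offender-type distribution with sex cross-tabulation
#'
#' Per category: the number of offender-type-reporting abstracts
#' mentioning it (one abstract may carry several categories) and its
#' share of all offender-type-reporting abstracts, cross-tabulated by
#' whether those abstracts also report male, female, or no sex at all
#' (shares within the category).
#'
#' @param values Deduplicated standardized-values tibble (offender and
#'   sex rows are both used).
#' @return A tibble (`category`, `n`, `denom`, `pct`, `male_n`,
#'   `male_pct`, `female_n`, `female_pct`, `unknown_sex_n`,
#'   `unknown_sex_pct`).
#' @export
offender_distribution <- function(values) {
  values <- assert_values_frame(values)
  off <- values[values$characteristic == "OFFENDER_TYPE", ] |>
    dplyr::distinct(.data$pmid, .data$value)
  denom <- dplyr::n_distinct(off$pmid)
  sex <- values[values$characteristic == "SEX", ]
  has_male <- unique(sex$pmid[sex$value == "male"])
  has_female <- unique(sex$pmid[sex$value == "female"])
  has_sex <- unique(sex$pmid)
  out <- off |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$pmid),
      male_n = dplyr::n_distinct(intersect(.data$pmid, has_male)),
      female_n = dplyr::n_distinct(intersect(.data$pmid, has_female)),
      unknown_sex_n = dplyr::n_distinct(setdiff(.data$pmid, has_sex)),
      .by = "value"
    ) |>
    dplyr::rename(category = "value")
  out <- tibble::tibble(category = offender_categories()) |>
    dplyr::left_join(out, by = "category") |>
    dplyr::mutate(dplyr::across(c("n", "male_n", "female_n", "unknown_sex_n"),
                                \(x) tidyr::replace_na(x, 0L)))
  out$denom <- denom
  out$pct <- if (denom > 0) pct(out$n, denom) else NA_real_
  out$male_pct <- ifelse(out$n > 0, pct(out$male_n, out$n), NA_real_)
  out$female_pct <- ifelse(out$n > 0, pct(out$female_n, out$n), NA_real_)
  out$unknown_sex_pct <- ifelse(out$n > 0, pct(out$unknown_sex_n, out$n), NA_real_)
  out |>
    dplyr::select("category", "n", "denom", "pct", "male_n", "male_pct",
                  "female_n", "female_pct", "unknown_sex_n", "unknown_sex_pct") |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Yearly offender-category rates
#'
#' Per year and category: abstracts mentioning the category divided by
#' offender-type-reporting abstracts that year. An abstract with two
#' categories increments both numerators but the denominator once.
#'
#' @param values Deduplicated standardized-values tibble.
#' @param corpus Corpus tibble supplying publication years.
#' @return A long tibble (`year`, `category`, `n`, `denom`, `pct`).
#' @export
offender_rates <- function(values, corpus) {
  values <- assert_values_frame(values)
  validate_corpus(corpus)
  off <- values[values$characteristic == "OFFENDER_TYPE", ] |>
    dplyr::distinct(.data$pmid, .data$value) |>
    dplyr::left_join(corpus[, c("pmid", "year")], by = "pmid")
  n_noyear <- dplyr::n_distinct(off$pmid[is.na(off$year)])
  if (n_noyear > 0) {
    rlang::inform(sprintf("offender_rates: excluded %d abstract(s) without a year",
                          n_noyear))
  }
  off <- off[!is.na(off$year), ]
  if (nrow(off) == 0) {
    return(tibble::tibble(year = integer(), category = character(),
                          n = integer(), denom = integer(), pct = double()))
  }
  denoms <- off |>
    dplyr::summarise(denom = dplyr::n_distinct(.data$pmid), .by = "year")
  off |>
    dplyr::count(.data$year, category = .data$value) |>
    dplyr::left_join(denoms, by = "year") |>
    dplyr::mutate(pct = pct(.data$n, .data$denom)) |>
    dplyr::arrange(.data$year, .data$category)
}

#' Article rate per 1000 prisoners
#'
#' @param articles,population Numeric vectors (article counts and average
#'   prisoner populations).
#' @return `1000 * articles / population`, half-up to one decimal.
#' @export
rate_per_1000 <- function(articles, population) {
  if (any(population <= 0)) rlang::abort("prisoner population must be positive")
  round_half_up(1000 * articles / population)
}

#' Load the shipped average-prisoner-population table
#'
#' Country, demonym, continent and the average prisoner population over
#' 2000-2020 for the 20 most-published countries.
#'
#' @param path Path to the TSV file.
#' @return A tibble `country`/`nationality`/`continent`/`population`.
#' @export
load_prisoner_table <- function(path = system.file("extdata", "tables",
                                                   "prisoner_population.tsv",
                                                   package = "jhminer")) {
  readr::read_tsv(path, col_types = readr::cols(
    country = readr::col_character(), nationality = readr::col_character(),
    continent = readr::col_character(), population = readr::col_double()
  ), progress = FALSE)
}

#' Crude and prisoner-population-adjusted country rankings
#'
#' Counts nationality-reporting abstracts per demonym, ranks them by raw
#' article count (crude rank) and by articles per 1000 prisoners (rate
#' rank). Rate ranks are computed on unrounded rates with competition
#' ranking; countries whose *rounded* rates tie share a rank-range label
#' (e.g. `13/14`). Countries missing from the prisoner table are excluded
#' with a warning.
#'
#' @param x Either a standardized-values tibble (nationality rows are
#'   counted per abstract) or a precomputed counts tibble with columns
#'   `nationality` and `n`.
#' @param prisoner_table Tibble from [load_prisoner_table()].
#' @return A tibble (`country`, `nationality`, `continent`, `n`, `pct`,
#'   `crude_rank`, `population`, `rate`, `rate_rank`, `rate_rank_label`)
#'   sorted by crude rank.
#' @export
country_ranking <- function(x, prisoner_table = load_prisoner_table()) {
  if ("characteristic" %in% names(x)) {
    x <- assert_values_frame(x)
    nat <- x[x$characteristic == "NATIONALITY", ]
    counts <- nat |>
      dplyr::distinct(.data$pmid, .data$value) |>
      dplyr::count(nationality = .data$value)
    denom <- dplyr::n_distinct(nat$pmid)
  } else {
    stopifnot(all(c("nationality", "n") %in% names(x)))
    counts <- tibble::as_tibble(x)
    denom <- sum(counts$n)
  }
  missing <- setdiff(counts$nationality, prisoner_table$nationality)
  if (length(missing) > 0) {
    rlang::warn(sprintf("excluding nationalit(ies) missing from the prisoner table: %s",
                        paste(missing, collapse = ", ")))
  }
  out <- dplyr::inner_join(counts, prisoner_table, by = "nationality")
  if (nrow(out) == 0) {
    rlang::abort("country_ranking: no nationalities matched the prisoner table")
  }
  raw_rate <- 1000 * out$n / out$population
  out <- out |>
    dplyr::mutate(
      pct = if (denom > 0) pct(.data$n, denom) else NA_real_,
      # ordinal: countries tied on articles get successive ranks, in
      # input order (the published table's convention)
      crude_rank = rank(-.data$n, ties.method = "first"),
      rate = rate_per_1000(.data$n, .data$population),
      rate_rank = dplyr::min_rank(dplyr::desc(raw_rate))
    )
  labels <- out |>
    dplyr::summarise(rate_rank_label = paste(sort(.data$rate_rank), collapse = "/"),
                     .by = "rate") |>
    dplyr::select("rate", "rate_rank_label")
  out |>
    dplyr::left_join(labels, by = "rate") |>
    dplyr::select("country", "nationality", "continent", "n", "pct",
                  "crude_rank", "population", "rate", "rate_rank",
                  "rate_rank_label") |>
    dplyr::arrange(.data$crude_rank)
}

#' Pearson product-moment correlation
#'
#' Validated wrapper used for the publication-volume versus
#' prisoner-population association.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, nonzero variance.
#' @return The Pearson coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  if (length(x) < 3) rlang::abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) rlang::abort("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) rlang::abort("zero variance")
  stats::cor(x, y, method = "pearson")
}
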