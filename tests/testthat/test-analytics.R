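corpus_of <- function(pmids, years = 2000L) {
  tibble::tibble(pmid = pmids, year = rep_len(years, length(pmids)),
                 title = NA_character_, text = "placeholder text",
                 language = "eng")
}

test_that("corpus summary counts coverage, all-four and none", {
  corpus <- corpus_of(c("a", "b", "c", "d"))
  vals <- dplyr::bind_rows(
    values_row("a", "SEX", "female"), values_row("a", "AGE", "minor"),
    values_row("a", "NATIONALITY", "Norwegian"),
    values_row("a", "OFFENDER_TYPE", "sex", "rape"),
    values_row("c", "SEX", "male"), values_row("d", "SEX", "male")
  )
  s <- summarize_corpus(vals, corpus)
  get <- function(k) s$n[s$statistic == k]
  expect_equal(get("none"), 1)
  expect_equal(get("all_four"), 1)
  expect_equal(get("sex"), 3)
  expect_equal(get("total"), 4)
  # permutation invariance over abstract order
  s2 <- summarize_corpus(vals[sample.int(nrow(vals)), ],
                         corpus[c(3, 1, 4, 2), ])
  expect_equal(s2, s)

  all_empty <- summarize_corpus(empty_values_for_tests(), corpus)
  expect_equal(all_empty$n[all_empty$statistic == "none"], 4)
  expect_error(summarize_corpus(vals, corpus[0, ]), "empty")
  expect_error(summarize_corpus(values_row("zz", "SEX", "male"), corpus),
               "not in corpus")
})

test_that("published coverage fractions recompute under half-up rounding", {
  n <- 34481L
  corpus <- corpus_of(sprintf("c%05d", 1:n))
  vals <- values_row(sprintf("c%05d", 1:(n - 17039L)), "SEX", "male")
  s <- summarize_corpus(vals, corpus)
  expect_equal(s$pct[s$statistic == "none"], 49.4)
})

test_that("age distribution uses age-reporting abstracts as denominator", {
  vals <- dplyr::bind_rows(
    values_row("p1", "AGE", "minor"), values_row("p1", "AGE", "18-24"),
    values_row("p2", "AGE", "minor"),
    values_row("p3", "SEX", "male") # not age-reporting
  )
  d <- age_distribution(vals)
  expect_equal(d$denom[1], 2)
  expect_equal(d$n[d$group == "minor"], 2)
  expect_equal(d$n[d$group == "18-24"], 1)
  expect_equal(d$pct[d$group == "minor"], 100)
  # one abstract can contribute to several groups: counts may exceed denom sums
  expect_equal(sum(d$n), 3)
  # published shares: 3581/5170 and 1728/5170
  big <- dplyr::bind_rows(
    values_row(sprintf("a%04d", 1:3581), "AGE", "minor"),
    values_row(sprintf("a%04d", 3582:5170), "AGE", "25-34"),
    values_row(sprintf("a%04d", 1:1728), "AGE", "18-24"))
  db <- age_distribution(big)
  expect_equal(db$denom[1], 5170)
  expect_equal(db$pct[db$group == "minor"], 69.3)
  expect_equal(db$pct[db$group == "18-24"], 33.4)
})

test_that("sex series classifies female-only, male-only and both by year", {
  corpus <- corpus_of(sprintf("s%d", 1:6), years = c(1990L, 1990L, 1990L,
                                                     2000L, 2000L, 2001L))
  vals <- dplyr::bind_rows(
    values_row("s1", "SEX", "female"),
    values_row("s2", "SEX", "male"),
    values_row("s3", "SEX", "female"), values_row("s3", "SEX", "male"),
    values_row("s4", "SEX", "female"), values_row("s4", "SEX", "transgender"),
    values_row("s5", "SEX", "female")
    # s6 has no sex values: its year contributes no denominator
  )
  ser <- sex_series(vals, corpus)
  expect_false(2001 %in% ser$year)
  g <- function(y, s) ser$pct[ser$year == y & ser$series == s]
  expect_equal(g(1990, "female_only"), 33.3)
  expect_equal(g(1990, "male_only"), 33.3)
  expect_equal(g(1990, "both"), 33.3)
  # a sex set beyond {female} is not female-only
  expect_equal(g(2000, "female_only"), 50.0)
  expect_equal(ser$denom[ser$year == 2000][1], 2)
  # a year with only mixed abstracts has female-only 0
  only_both <- dplyr::bind_rows(values_row("s1", "SEX", "male"),
                                values_row("s1", "SEX", "female"))
  sb <- sex_series(only_both, corpus_of("s1", 1995L))
  expect_equal(sb$pct[sb$series == "female_only"], 0)
})

test_that("published 1990 and 2023 female-only shares recompute", {
  make_year <- function(year, n_f, n_m, n_rest, prefix) {
    ids <- sprintf("%s%04d", prefix, seq_len(n_f + n_m + n_rest))
    vals <- dplyr::bind_rows(
      values_row(ids[seq_len(n_f)], "SEX", "female"),
      values_row(ids[n_f + seq_len(n_m)], "SEX", "male"),
      values_row(ids[n_f + n_m + seq_len(n_rest)], "SEX", "male"),
      values_row(ids[n_f + n_m + seq_len(n_rest)], "SEX", "female"))
    list(corpus = corpus_of(ids, year), vals = vals)
  }
  y2023 <- make_year(2023L, 105, 72, 39, "x")
  ser <- sex_series(y2023$vals, y2023$corpus)
  expect_equal(ser$denom[1], 216)
  expect_equal(ser$pct[ser$series == "female_only"], 48.6)
  expect_equal(ser$pct[ser$series == "male_only"], 33.3)
  y1990 <- make_year(1990L, 19, 33, 13, "y")
  ser90 <- sex_series(y1990$vals, y1990$corpus)
  expect_equal(ser90$pct[ser90$series == "female_only"], 29.2)
  expect_equal(ser90$pct[ser90$series == "male_only"], 50.8)
})

test_that("offender distribution cross-tabulates by reported sex", {
  vals <- dplyr::bind_rows(
    values_row("o1", "OFFENDER_TYPE", "mentally_ill", "psychosis"),
    values_row("o1", "SEX", "male"),
    values_row("o2", "OFFENDER_TYPE", "mentally_ill"),
    values_row("o2", "OFFENDER_TYPE", "sex"), # two categories, one denom
    values_row("o3", "OFFENDER_TYPE", "sex")
  )
  d <- offender_distribution(vals)
  mi <- d[d$category == "mentally_ill", ]
  expect_equal(mi$n, 2)
  expect_equal(mi$denom, 3)
  expect_equal(mi$pct, 66.7)
  expect_equal(mi$male_n, 1)
  expect_equal(mi$unknown_sex_n, 1)
  sx <- d[d$category == "sex", ]
  expect_equal(sx$n, 2)
  expect_equal(sx$unknown_sex_pct, 100)
  # published share: 840/4814 mentally ill, 84/4814 child crime-related
  big <- dplyr::bind_rows(
    values_row(sprintf("b%04d", 1:840), "OFFENDER_TYPE", "mentally_ill"),
    values_row(sprintf("b%04d", 1:84), "OFFENDER_TYPE", "child_crime_related"),
    values_row(sprintf("b%04d", 841:4814), "OFFENDER_TYPE", "miscellaneous",
               "prisoner"))
  db <- offender_distribution(big)
  expect_equal(db$pct[db$category == "mentally_ill"], 17.4)
  expect_equal(db$pct[db$category == "child_crime_related"], 1.7)
})

test_that("offender yearly rates divide by offender-reporting abstracts", {
  corpus <- corpus_of(c("r1", "r2", "r3"), c(1991L, 1991L, 1992L))
  vals <- dplyr::bind_rows(
    values_row("r1", "OFFENDER_TYPE", "sex"),
    values_row("r2", "OFFENDER_TYPE", "sex"),
    values_row("r2", "OFFENDER_TYPE", "violent"),
    values_row("r3", "OFFENDER_TYPE", "violent"))
  rt <- offender_rates(vals, corpus)
  expect_equal(rt$pct[rt$year == 1991 & rt$category == "sex"], 100)
  expect_equal(rt$pct[rt$year == 1991 & rt$category == "violent"], 50)
  expect_equal(rt$denom[rt$year == 1991][1], 2)
  expect_equal(rt$pct[rt$year == 1992 & rt$category == "violent"], 100)
})

test_that("country rates and both rankings match the published table", {
  top <- readr::read_tsv(system.file("extdata", "tables", "top_countries.tsv",
                                     package = "jhminer"),
                         show_col_types = FALSE)
  counts <- tibble::tibble(nationality = top$nationality, n = top$articles)
  rk <- country_ranking(counts, load_prisoner_table())
  expect_equal(rk$crude_rank, top$crude_rank)
  pick <- function(nat, col) rk[[col]][rk$nationality == nat]
  expect_equal(pick("Norwegian", "rate"), 42.0)
  expect_equal(pick("Swedish", "rate"), 40.1)
  expect_equal(pick("Finnish", "rate"), 41.7)
  expect_equal(pick("Danish", "rate"), 33.5)
  expect_equal(pick("Australian", "rate"), 23.8)
  expect_equal(pick("Norwegian", "rate_rank"), 1)
  expect_equal(pick("Finnish", "rate_rank"), 2)
  expect_equal(pick("Swedish", "rate_rank"), 3)
  expect_equal(pick("American", "rate_rank"), 16)
  expect_equal(pick("Chinese", "rate_rank"), 20)
  # Japan and Spain share the rounded rate 3.1: tie label, distinct ranks
  expect_equal(pick("Japanese", "rate_rank_label"), "13/14")
  expect_equal(pick("Spanish", "rate_rank_label"), "13/14")
  expect_equal(pick("Spanish", "rate_rank"), 13)
  expect_equal(pick("Japanese", "rate_rank"), 14)
})

test_that("country ranking warns on unknown nationalities and scales in rank only", {
  counts <- tibble::tibble(nationality = c("Norwegian", "Swedish", "Atlantean"),
                           n = c(138L, 261L, 5L))
  expect_warning(rk <- country_ranking(counts), "Atlantean")
  expect_equal(nrow(rk), 2)
  # doubling all article counts doubles rates but preserves ranks
  rk2 <- country_ranking(dplyr::mutate(counts[1:2, ], n = n * 2L))
  expect_equal(rk2$rate_rank, rk$rate_rank)
  expect_equal(rk2$crude_rank, rk$crude_rank)
  expect_false(any(rk2$rate == rk$rate))
  # zero articles sit at the bottom with rate 0
  rk3 <- country_ranking(tibble::tibble(nationality = c("Norwegian", "Swedish"),
                                        n = c(0L, 10L)))
  expect_equal(rk3$rate[rk3$nationality == "Norwegian"], 0)
  expect_equal(rk3$rate_rank[rk3$nationality == "Norwegian"], 2)
})

test_that("values-level country ranking counts distinct abstracts", {
  vals <- dplyr::bind_rows(
    values_row(c("n1", "n2", "n3"), "NATIONALITY", "Norwegian"),
    values_row("n1", "NATIONALITY", "Swedish"),
    values_row("n1", "SEX", "male"))
  rk <- country_ranking(vals)
  expect_equal(rk$n[rk$nationality == "Norwegian"], 3)
  expect_equal(rk$n[rk$nationality == "Swedish"], 1)
  expect_equal(rk$crude_rank, c(1L, 2L))
})

test_that("pearson correlation behaves and validates", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1.0)
  expect_equal(pearson_correlation(x, -x), -1.0)
  set.seed(13)
  a <- rnorm(20)
  b <- a + rnorm(20)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_correlation(a, b), manual)
  expect_error(pearson_correlation(1:2, 1:2), "3 observations")
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("aggregation counts match a direct-count oracle on random fixtures", {
  set.seed(77)
  for (trial in 1:20) {
    ids <- sprintf("t%02d", 1:15)
    vals <- random_values(ids)
    corpus <- corpus_of(ids, sample(1995:1999, 15, replace = TRUE))
    s <- summarize_corpus(vals, corpus)
    expect_equal(s$n[s$statistic == "none"],
                 sum(!ids %in% vals$pmid))
    for (k in characteristics()) {
      expect_equal(s$n[s$statistic == tolower(k)],
                   length(unique(vals$pmid[vals$characteristic == k])))
    }
    d <- age_distribution(vals)
    age <- vals[vals$characteristic == "AGE", ]
    for (gr in d$group) {
      expect_equal(d$n[d$group == gr],
                   length(unique(age$pmid[age$value == gr])))
    }
    rt <- offender_rates(vals, corpus)
    off <- dplyr::distinct(vals[vals$characteristic == "OFFENDER_TYPE", ],
                           pmid, value)
    off$year <- corpus$year[match(off$pmid, corpus$pmid)]
    for (i in seq_len(nrow(rt))) {
      expect_equal(rt$n[i], sum(off$value == rt$category[i] &
                                  off$year == rt$year[i]))
      expect_equal(rt$denom[i],
                   length(unique(off$pmid[off$year == rt$year[i]])))
    }
  }
})
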