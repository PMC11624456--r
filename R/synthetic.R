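# Synthetic abstracts with known gold annotations: template-composed
# paragraphs whose planted surfaces are drawn from the shipped lexicons
# and realized through the shipped rule patterns, so that on noise-free
# text the extraction pipeline recovers the gold exactly.

# Surface/value pairs used for planting. Restricted to surfaces that
# trigger exactly one characteristic (e.g. "boys" is both a sex term and
# a textual age term in the dictionaries, so it is never planted): the
# recoverability contract requires pipeline output == gold.
synth_sex_surfaces <- function() {
  tibble::tibble(
    surface = c("women", "men", "females", "males", "female", "male",
                "transgender", "transgender men", "transgender women"),
    value = c("female", "male", "female", "male", "female", "male",
              "transgender", "transgender_man", "transgender_woman")
  )
}

synth_age_terms <- function() {
  tibble::tibble(
    surface = c("adolescents", "teenagers", "adults", "teens"),
    groups = c("minor|18-24", "minor|18-24", "unknown_adult", "minor|18-24")
  )
}

synth_countries <- function() {
  tibble::tibble(
    surface = c("Norway", "Sweden", "Finland", "Denmark", "Australia",
                "Canada", "Germany", "France", "Netherlands", "Japan",
                "Spain", "Brazil", "China", "India", "Switzerland",
                "South Africa", "Iowa", "Minnesota", "United Kingdom"),
    value = c("Norwegian", "Swedish", "Finnish", "Danish", "Australian",
              "Canadian", "German", "French", "Dutch", "Japanese",
              "Spanish", "Brazilian", "Chinese", "Indian", "Swiss",
              "South African", "American", "American", "British")
  )
}

synth_offenders <- function() {
  tibble::tibble(
    surface = c("sex offenders", "serial rapists", "pedophiles",
                "psychotic inmates", "drug traffickers", "violent offenders",
                "shoplifters", "ex-offenders", "prisoners", "detainees"),
    category = c("sex", "sex", "child_crime_related", "mentally_ill",
                 "drug_related", "violent", "nonviolent", "miscellaneous",
                 "miscellaneous", "miscellaneous"),
    attribute = c(NA, "rape", "child sex abuse", "psychosis",
                  "drug trafficking", NA, "theft", "ex-offender",
                  "prisoner", "detainee")
  )
}

synth_fillers <- function() {
  c("This study examined patterns of service contact over the follow-up period.",
    "We analysed routinely collected administrative data.",
    "Outcomes were compared across settings using standard methods.",
    "The design was retrospective and relied on linked registry data.")
}

# Build one age sentence; returns the sentence, the capture phrase the
# age rules will produce, and the gold group set.
synth_age_sentence <- function() {
  form <- sample(c("range", "between", "older", "point", "pair", "textual"),
                 1, prob = c(0.3, 0.15, 0.1, 0.1, 0.1, 0.25))
  if (form == "textual") {
    row <- synth_age_terms()[sample.int(nrow(synth_age_terms()), 1), ]
    sentence <- sprintf("The study focused on %s in contact with services.",
                        row$surface)
    return(list(sentence = sentence, span = row$surface,
                groups = strsplit(row$groups, "|", fixed = TRUE)[[1]]))
  }
  lo <- sample(10:60, 1)
  hi <- lo + sample(1:20, 1)
  if (form == "range") {
    span <- sprintf("aged %d to %d years", lo, hi)
    sentence <- sprintf("Participants were %s.", span)
    bounds <- c(lo, hi)
  } else if (form == "between") {
    span <- sprintf("between %d and %d years of age", lo, hi)
    sentence <- sprintf("Eligibility was restricted to individuals %s.", span)
    bounds <- c(lo, hi)
  } else if (form == "older") {
    span <- sprintf("older than %d years", lo)
    sentence <- sprintf("Respondents %s were included.", span)
    bounds <- c(lo + 1, Inf)
  } else if (form == "point") {
    span <- sprintf("aged %d years", lo)
    sentence <- sprintf("Participants %s took part.", span)
    bounds <- c(lo, lo)
  } else { # pair
    span <- sprintf("%d and %d-year-old", lo, hi)
    sentence <- sprintf("The study enrolled %s participants.", span)
    bounds <- c(lo, hi)
  }
  list(sentence = sentence, span = span,
       groups = age_groups_for_range(bounds[1], bounds[2]))
}

#' Generate a synthetic corpus with gold annotations
#'
#' Each abstract is a template-composed paragraph; each characteristic is
#' included by an independent Bernoulli draw, with surfaces sampled from
#' the shipped lexicons and gold recorded at the standardization level.
#' The default inclusion probabilities are the observed coverage rates in
#' the justice health literature (age 14.9%, sex 23.7%, nationality
#' 27.6%, offender type 13.9%). Deterministic under a fixed seed.
#'
#' @param n Number of abstracts.
#' @param p_age,p_sex,p_nationality,p_offender Per-characteristic
#'   inclusion probabilities in `[0, 1]`.
#' @param years Inclusive year range publications are drawn from.
#' @param seed Random seed fixing all randomness.
#' @return An object of class `jh_synthetic`: a list with `corpus` (a
#'   corpus tibble), `gold` (a standardized-values tibble) and `spans`
#'   (planted spans with 0-based offsets into the abstract text).
#' @export
generate_corpus <- function(n, p_age = 0.149, p_sex = 0.237,
                            p_nationality = 0.276, p_offender = 0.139,
                            years = c(1990, 2023), seed = 1L) {
  probs <- c(age = p_age, sex = p_sex, nationality = p_nationality,
             offender = p_offender)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("inclusion probabilities must be in [0, 1]")
  }
  if (n < 0) rlang::abort("n must be >= 0")
  set.seed(seed)
  corpus_rows <- vector("list", n)
  gold_rows <- list()
  span_rows <- list()
  for (i in seq_len(n)) {
    pmid <- sprintf("S%05d", i)
    sentences <- character(0)
    spans <- character(0) # capture phrase per planted sentence
    span_chars <- character(0)
    filler <- sample(synth_fillers(), 1)
    sentences <- c(sentences, filler)
    if (runif(1) < probs["sex"]) {
      k <- sample(1:2, 1, prob = c(0.8, 0.2))
      rows <- synth_sex_surfaces()[sample.int(nrow(synth_sex_surfaces())), ]
      rows <- rows[!duplicated(rows$value), ][seq_len(k), ]
      phrase <- paste(rows$surface, collapse = " and ")
      sentences <- c(sentences, sprintf("The sample comprised %s participants.", phrase))
      for (j in seq_len(k)) {
        spans <- c(spans, rows$surface[j])
        span_chars <- c(span_chars, "SEX")
        gold_rows[[length(gold_rows) + 1L]] <- tibble::tibble(
          pmid = pmid, characteristic = "SEX", value = rows$value[j],
          attribute = NA_character_)
      }
    }
    if (runif(1) < probs["age"]) {
      a <- synth_age_sentence()
      sentences <- c(sentences, a$sentence)
      spans <- c(spans, a$span)
      span_chars <- c(span_chars, "AGE")
      gold_rows[[length(gold_rows) + 1L]] <- tibble::tibble(
        pmid = pmid, characteristic = "AGE", value = a$groups,
        attribute = NA_character_)
    }
    if (runif(1) < probs["offender"]) {
      row <- synth_offenders()[sample.int(nrow(synth_offenders()), 1), ]
      tmpl <- sample(c("The analysis focused on %s.",
                       "We studied the characteristics of %s in the justice system."), 1)
      sentences <- c(sentences, sprintf(tmpl, row$surface))
      spans <- c(spans, row$surface)
      span_chars <- c(span_chars, "OFFENDER_TYPE")
      gold_rows[[length(gold_rows) + 1L]] <- tibble::tibble(
        pmid = pmid, characteristic = "OFFENDER_TYPE", value = row$category,
        attribute = row$attribute)
    }
    if (runif(1) < probs["nationality"]) {
      row <- synth_countries()[sample.int(nrow(synth_countries()), 1), ]
      sentences <- c(sentences, sprintf("Data were drawn from %s health registers.",
                                        row$surface))
      spans <- c(spans, row$surface)
      span_chars <- c(span_chars, "NATIONALITY")
      gold_rows[[length(gold_rows) + 1L]] <- tibble::tibble(
        pmid = pmid, characteristic = "NATIONALITY", value = row$value,
        attribute = NA_character_)
    }
    text <- paste(sentences, collapse = " ")
    cursor <- 0L # spans were planted in order; resolve repeats left-to-right
    for (j in seq_along(spans)) {
      loc <- str_locate(substr(text, cursor + 1L, nchar(text)),
                        stringr::fixed(spans[j]))
      start <- cursor + as.integer(loc[1, 1]) - 1L
      end <- cursor + as.integer(loc[1, 2])
      cursor <- end
      span_rows[[length(span_rows) + 1L]] <- tibble::tibble(
        pmid = pmid, characteristic = span_chars[j], surface = spans[j],
        start = start, end = end)
    }
    corpus_rows[[i]] <- tibble::tibble(
      pmid = pmid, year = sample(years[1]:years[2], 1),
      title = sprintf("Synthetic justice health abstract %d", i),
      text = text, language = "eng")
  }
  corpus <- if (n == 0) {
    tibble::tibble(pmid = character(), year = integer(), title = character(),
                   text = character(), language = character())
  } else {
    purrr::list_rbind(corpus_rows)
  }
  gold <- if (length(gold_rows) == 0) empty_values() else
    dedupe_values(purrr::list_rbind(gold_rows))
  spans <- if (length(span_rows) == 0) {
    tibble::tibble(pmid = character(), characteristic = character(),
                   surface = character(), start = integer(), end = integer())
  } else {
    purrr::list_rbind(span_rows)
  }
  structure(list(corpus = corpus, gold = gold, spans = spans,
                 config = list(n = n, probs = probs, years = years, seed = seed)),
            class = "jh_synthetic")
}

#' @export
print.jh_synthetic <- function(x, ...) {
  cat(sprintf("Synthetic corpus: %d abstracts, %d gold values, %d planted spans\n",
              nrow(x$corpus), nrow(x$gold), nrow(x$spans)))
  invisible(x)
}

# Length-preserving word scramble: reverse the interior (whole word for
# 2-3 letters); fall back to swapping the first two characters, then to a
# 'q' substitution, so the output always differs for words of 2+ letters.
scramble_word <- function(w) {
  n <- nchar(w)
  if (n < 2) return(w)
  out <- if (n <= 3) {
    paste(rev(strsplit(w, "")[[1]]), collapse = "")
  } else {
    paste0(substr(w, 1, 1),
           paste(rev(strsplit(substr(w, 2, n - 1), "")[[1]]), collapse = ""),
           substr(w, n, n))
  }
  if (out == w) out <- paste0(substr(w, 2, 2), substr(w, 1, 1), substr(w, 3, n))
  if (out == w) out <- paste0(substr(w, 1, 1), "q", substr(w, 3, n))
  out
}

corrupt_phrase <- function(phrase) {
  tokens <- strsplit(phrase, "(?<=[ -])|(?=[ -])", perl = TRUE)[[1]]
  corrupted <- vapply(tokens, function(tk) {
    if (grepl("^[A-Za-z]{2,}$", tk)) scramble_word(tk) else tk
  }, character(1))
  paste(corrupted, collapse = "")
}

#' Inject misspelling noise into planted mentions
#'
#' Emulates the documented real-text failure mode where misspellings in
#' the published abstract do not trigger the extraction rules. Each
#' planted span of the selected characteristics is corrupted with
#' probability `p`: every alphabetic token in the span (including rule
#' anchors such as "aged" and "years") is scrambled length-preservingly,
#' so offsets stay valid, the mention becomes unextractable, and the
#' expected error is a clean false negative. Gold is left unchanged — it
#' reflects the intended content.
#'
#' @param synth A `jh_synthetic` object.
#' @param p Per-span corruption probability in `[0, 1]`.
#' @param characteristic Characteristics whose spans are eligible.
#' @param seed Random seed.
#' @return The `jh_synthetic` object with corrupted corpus text and a
#'   `noise_log` tibble (one row per perturbed span).
#' @export
inject_noise <- function(synth, p, characteristic = characteristics(),
                         seed = 1L) {
  stopifnot(inherits(synth, "jh_synthetic"))
  if (p < 0 || p > 1) rlang::abort("noise probability must be in [0, 1]")
  set.seed(seed)
  log_rows <- list()
  corpus <- synth$corpus
  spans <- synth$spans
  for (i in seq_len(nrow(spans))) {
    if (!spans$characteristic[i] %in% characteristic) next
    if (runif(1) >= p) next
    idx <- match(spans$pmid[i], corpus$pmid)
    text <- corpus$text[idx]
    original <- substr(text, spans$start[i] + 1L, spans$end[i])
    corrupted <- corrupt_phrase(original)
    if (identical(corrupted, original)) next
    corpus$text[idx] <- paste0(substr(text, 1, spans$start[i]), corrupted,
                               substr(text, spans$end[i] + 1L, nchar(text)))
    log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
      pmid = spans$pmid[i], characteristic = spans$characteristic[i],
      original = original, corrupted = corrupted,
      start = spans$start[i], end = spans$end[i])
  }
  synth$corpus <- corpus
  synth$noise_log <- if (length(log_rows) == 0) {
    tibble::tibble(pmid = character(), characteristic = character(),
                   original = character(), corrupted = character(),
                   start = integer(), end = integer())
  } else {
    purrr::list_rbind(log_rows)
  }
  synth
}
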