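# Fixtures are built in code at test time; nothing binary is stored.

shipped_lexicons <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_lexicons()
    cache
  }
})

shipped_rules <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_rules(shipped_lexicons())
    cache
  }
})

shipped_categories <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_offense_categories()
    cache
  }
})

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = TRUE)
  path
}

medline_fixture <- function(records) {
  # records: list of named character vectors tag -> value
  lines <- unlist(lapply(records, function(r) {
    c(vapply(names(r), function(tag) {
      sprintf("%-4s- %s", tag, r[[tag]])
    }, character(1)), "")
  }))
  write_tmp(lines, ".medline")
}

pubmed_xml_fixture <- function(articles) {
  # articles: list with pmid, year, title, abstract (character vector of
  # sections), language
  body <- vapply(articles, function(a) {
    sections <- paste(sprintf("<AbstractText>%s</AbstractText>", a$abstract),
                      collapse = "")
    sprintf(paste0(
      "<PubmedArticle><MedlineCitation><PMID>%s</PMID><Article>",
      "<Journal><JournalIssue><PubDate><Year>%s</Year></PubDate></JournalIssue></Journal>",
      "<ArticleTitle>%s</ArticleTitle><Abstract>%s</Abstract>",
      "<Language>%s</Language></Article></MedlineCitation></PubmedArticle>"
    ), a$pmid, a$year, a$title, sections, a$language)
  }, character(1))
  write_tmp(c("<?xml version=\"1.0\"?>", "<PubmedArticleSet>", body,
              "</PubmedArticleSet>"), ".xml")
}

empty_values_for_tests <- function() {
  tibble::tibble(pmid = character(), characteristic = character(),
                 value = character(), attribute = character())
}

values_row <- function(pmid, characteristic, value, attribute = NA_character_) {
  tibble::tibble(pmid = pmid, characteristic = characteristic, value = value,
                 attribute = attribute)
}

# ---- independent oracles ----------------------------------------------

# Brute-force abstract-level alignment: loops and set arithmetic only.
oracle_align <- function(gold, predicted, pmids) {
  out <- tibble::tibble(characteristic = characteristics(),
                        tp = 0L, fp = 0L, fn = 0L)
  keyify <- function(df) {
    paste(df$characteristic, df$value,
          ifelse(is.na(df$attribute), "", df$attribute))
  }
  for (id in pmids) {
    g <- unique(keyify(gold[gold$pmid == id, ]))
    p <- unique(keyify(predicted[predicted$pmid == id, ]))
    for (k in seq_len(nrow(out))) {
      ch <- out$characteristic[k]
      gk <- g[startsWith(g, paste0(ch, " "))]
      pk <- p[startsWith(p, paste0(ch, " "))]
      out$tp[k] <- out$tp[k] + length(intersect(gk, pk))
      out$fp[k] <- out$fp[k] + length(setdiff(pk, gk))
      out$fn[k] <- out$fn[k] + length(setdiff(gk, pk))
    }
  }
  out
}

# Enumerate every dictionary-term occurrence by scanning all start
# positions, then apply longest-wins / leftmost-tie selection.
oracle_match <- function(text, lexicon) {
  is_word <- function(ch) grepl("[A-Za-z0-9]", ch)
  cand <- list()
  lower <- tolower(text)
  for (i in seq_len(nrow(lexicon))) {
    term <- tolower(lexicon$term[i])
    variants <- unique(c(term, gsub("-", " ", term), gsub(" ", "-", term)))
    for (v in variants) {
      start <- 1L
      repeat {
        hit <- regexpr(v, substr(lower, start, nchar(lower)), fixed = TRUE)
        if (hit == -1) break
        s <- start + as.integer(hit) - 1L
        e <- s + nchar(v) - 1L
        before <- if (s > 1) substr(text, s - 1, s - 1) else ""
        before2 <- if (s > 2) substr(text, s - 2, s - 2) else ""
        after <- if (e < nchar(text)) substr(text, e + 1, e + 1) else ""
        after2 <- if (e + 1 < nchar(text)) substr(text, e + 2, e + 2) else ""
        ok_l <- !is_word(before) &&
          !(before %in% c("-", "'") && is_word(before2))
        ok_r <- !is_word(after) &&
          !(after %in% c("-", "'") && is_word(after2))
        if (ok_l && ok_r) {
          cand[[length(cand) + 1L]] <- tibble::tibble(
            start = s - 1L, end = e, canonical = lexicon$canonical[i])
        }
        start <- s + 1L
      }
    }
  }
  if (length(cand) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          canonical = character()))
  }
  cand <- dplyr::distinct(dplyr::bind_rows(cand))
  cand <- cand[order(-(cand$end - cand$start), cand$start), ]
  taken <- rep(FALSE, nchar(text))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):cand$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

# Random standardized-value sets for property tests.
random_values <- function(pmids, n_per = 3) {
  pool <- dplyr::bind_rows(
    tidyr::crossing(characteristic = "AGE",
                    value = c("minor", "18-24", "65+"), attribute = NA_character_),
    tidyr::crossing(characteristic = "SEX",
                    value = c("male", "female"), attribute = NA_character_),
    tidyr::crossing(characteristic = "NATIONALITY",
                    value = c("Norwegian", "American", "Swedish"),
                    attribute = NA_character_),
    tibble::tibble(characteristic = "OFFENDER_TYPE",
                   value = c("sex", "sex", "mentally_ill"),
                   attribute = c(NA, "rape", "psychosis"))
  )
  out <- dplyr::bind_rows(lapply(pmids, function(id) {
    k <- sample(0:n_per, 1)
    if (k == 0) return(NULL)
    rows <- pool[sample.int(nrow(pool), k), ]
    rows$pmid <- id
    rows[, c("pmid", "characteristic", "value", "attribute")]
  }))
  if (nrow(out) == 0) empty_values_for_tests() else out
}
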