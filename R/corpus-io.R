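# Readers and writers for bibliographic and annotation formats:
# MEDLINE flat files, PubMed XML, tab-separated gold annotations and
# JSON-lines result files.

validate_corpus <- function(corpus, arg = "corpus") {
  need <- c("pmid", "year", "title", "text", "language")
  missing <- setdiff(need, names(corpus))
  if (length(missing) > 0) {
    rlang::abort(sprintf("`%s` lacks column(s): %s", arg,
                         paste(missing, collapse = ", ")))
  }
  dup <- corpus$pmid[duplicated(corpus$pmid)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate PMID(s) in %s: %s", arg,
                         paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(corpus$pmid))) rlang::abort("empty PMID in corpus")
  bad_year <- !is.na(corpus$year) & (corpus$year < 1900 | corpus$year > 2100)
  if (any(bad_year)) {
    rlang::abort(sprintf("publication year out of range [1900, 2100] for PMID(s): %s",
                         paste(corpus$pmid[bad_year], collapse = ", ")))
  }
  invisible(corpus)
}

# Split a MEDLINE flat file into records on blank lines and fold
# continuation lines (leading whitespace) into their tag line.
medline_records <- function(lines) {
  lines <- lines[!grepl("^\\s*$", lines) | TRUE]
  blank <- grepl("^\\s*$", lines)
  rec_id <- cumsum(c(TRUE, blank[-length(blank)])) # new record after blank
  split(lines[!blank], rec_id[!blank])
}

fld <- function(fields, tag) {
  if (tag %in% names(fields)) fields[[tag]] else NA_character_
}

parse_medline_record <- function(rec_lines) {
  tags <- character(0)
  vals <- character(0)
  for (ln in rec_lines) {
    if (grepl("^\\s+", ln) && length(vals) > 0) {
      vals[length(vals)] <- paste(vals[length(vals)], str_trim(ln))
    } else {
      m <- regmatches(ln, regexec("^([A-Z]{1,4})\\s*-\\s?(.*)$", ln))[[1]]
      if (length(m) == 3) {
        tags <- c(tags, m[2])
        vals <- c(vals, m[3])
      }
    }
  }
  setNames(vals, tags)
}

#' Read abstracts from a MEDLINE flat-format file
#'
#' Parses `PMID`, `TI`, `AB`, `DP` and `LA` tags (continuation lines are
#' folded in). Records without an abstract are skipped and counted; the
#' skip count is reported and attached as the `n_skipped` attribute.
#' Abstract and title text are whitespace-normalized on read, so mention
#' offsets produced downstream are valid against the stored text.
#'
#' @param path Path to a MEDLINE flat-format file.
#' @return A tibble with columns `pmid`, `year`, `title`, `text`,
#'   `language`; one row per record with a non-empty abstract.
#' @export
read_medline <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  recs <- medline_records(lines)
  n_skipped <- 0L
  rows <- list()
  for (rec in recs) {
    fields <- parse_medline_record(rec)
    if (length(fields) == 0) next
    if (!"PMID" %in% names(fields)) {
      rlang::warn("skipping malformed MEDLINE record without PMID tag")
      n_skipped <- n_skipped + 1L
      next
    }
    ab <- fld(fields, "AB")
    ab <- if (is.na(ab)) "" else normalize_whitespace(ab)
    if (!nzchar(ab)) {
      n_skipped <- n_skipped + 1L
      next
    }
    dp <- fld(fields, "DP")
    year <- if (is.na(dp)) NA_integer_ else {
      y <- regmatches(dp, regexpr("\\b(19|20)\\d{2}\\b", dp))
      if (length(y) == 1) as.integer(y) else NA_integer_
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pmid = str_trim(fields[["PMID"]]),
      year = year,
      title = normalize_whitespace(fld(fields, "TI")),
      text = ab,
      language = fld(fields, "LA")
    )
  }
  corpus <- if (length(rows) == 0) {
    tibble::tibble(pmid = character(), year = integer(), title = character(),
                   text = character(), language = character())
  } else {
    purrr::list_rbind(rows)
  }
  validate_corpus(corpus)
  if (n_skipped > 0) {
    rlang::inform(sprintf("read_medline: skipped %d record(s) without an abstract",
                          n_skipped))
  }
  attr(corpus, "n_skipped") <- n_skipped
  corpus
}

#' Write a corpus as a MEDLINE flat-format file
#'
#' Emits the same `PMID`/`TI`/`AB`/`DP`/`LA` tags [read_medline()]
#' consumes, enabling round-trip testing through the public interfaces.
#'
#' @param corpus Corpus tibble (`pmid`, `year`, `title`, `text`, `language`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(corpus, path) {
  validate_corpus(corpus)
  blocks <- purrr::pmap(corpus, function(pmid, year, title, text, language, ...) {
    out <- c(paste0("PMID- ", pmid))
    if (!is.na(year)) out <- c(out, paste0("DP  - ", year))
    if (!is.na(title) && nzchar(title)) out <- c(out, paste0("TI  - ", title))
    out <- c(out, paste0("AB  - ", text))
    if (!is.na(language)) out <- c(out, paste0("LA  - ", language))
    c(out, "")
  })
  writeLines(unlist(blocks), path, useBytes = TRUE)
  invisible(path)
}

xml_first_text <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

pubmed_year <- function(article, date_field) {
  if (date_field == "pubdate") {
    pd <- xml2::xml_find_first(article, ".//Journal/JournalIssue/PubDate")
    if (inherits(pd, "xml_missing")) return(NA_integer_)
    y <- xml_first_text(pd, "./Year")
    if (is.na(y)) {
      md <- xml_first_text(pd, "./MedlineDate")
      if (!is.na(md)) {
        hit <- regmatches(md, regexpr("\\b(19|20)\\d{2}\\b", md))
        y <- if (length(hit) == 1) hit else NA_character_
      }
    }
    if (is.na(y)) NA_integer_ else as.integer(y)
  } else {
    yrs <- xml2::xml_text(xml2::xml_find_all(
      article, ".//PubmedData/History/PubMedPubDate/Year | .//Journal/JournalIssue/PubDate/Year"
    ))
    yrs <- suppressWarnings(as.integer(yrs))
    yrs <- yrs[!is.na(yrs)]
    if (length(yrs) == 0) NA_integer_ else min(yrs)
  }
}

#' Read abstracts from a PubMed XML export
#'
#' Structured abstracts (multiple `AbstractText` sections) are concatenated
#' with single spaces. Articles without abstract text are skipped and
#' counted, mirroring [read_medline()].
#'
#' @param path Path to a `PubmedArticleSet` XML file.
#' @param date_field Which date defines the publication year: `"pubdate"`
#'   (the JournalIssue PubDate, default) or `"earliest"` (the earliest
#'   4-digit year across the PubMed history and PubDate elements). The
#'   bibliographic record carries several date fields and the analytic
#'   convention is a configuration choice, so both are exposed.
#' @return Corpus tibble as for [read_medline()].
#' @export
read_pubmed_xml <- function(path, date_field = c("pubdate", "earliest")) {
  date_field <- match.arg(date_field)
  if (!file.exists(path)) rlang::abort(sprintf("cannot read '%s': no such file", path))
  doc <- xml2::read_xml(path) # parse failure -> error with line number
  articles <- xml2::xml_find_all(doc, "//PubmedArticle")
  n_skipped <- 0L
  rows <- list()
  for (article in articles) {
    pmid <- xml_first_text(article, ".//MedlineCitation/PMID")
    sections <- xml2::xml_text(xml2::xml_find_all(article, ".//Abstract/AbstractText"))
    text <- normalize_whitespace(paste(sections, collapse = " "))
    if (is.na(pmid) || !nzchar(text)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pmid = str_trim(pmid),
      year = pubmed_year(article, date_field),
      title = normalize_whitespace(xml_first_text(article, ".//ArticleTitle")),
      text = text,
      language = xml_first_text(article, ".//Language")
    )
  }
  corpus <- if (length(rows) == 0) {
    tibble::tibble(pmid = character(), year = integer(), title = character(),
                   text = character(), language = character())
  } else {
    purrr::list_rbind(rows)
  }
  validate_corpus(corpus)
  if (n_skipped > 0) {
    rlang::inform(sprintf("read_pubmed_xml: skipped %d article(s) without an abstract",
                          n_skipped))
  }
  attr(corpus, "n_skipped") <- n_skipped
  corpus
}

# Alias maps from hand-written gold labels to canonical tokens.
age_label_aliases <- function() {
  c("minor" = "minor", "minors" = "minor", "<18" = "minor",
    "18-24" = "18-24", "25-34" = "25-34", "35-44" = "35-44",
    "45-54" = "45-54", "55-64" = "55-64", "65+" = "65+",
    "unknown_adult" = "unknown_adult", "unknown adult" = "unknown_adult",
    "adult" = "unknown_adult", "adults" = "unknown_adult")
}

canon_gold_value <- function(characteristic, value) {
  v <- str_trim(value)
  if (characteristic == "AGE") {
    unname(age_label_aliases()[tolower(v)]) # NA if unknown
  } else if (characteristic == "SEX") {
    key <- gsub("[ -]+", "_", tolower(v))
    if (key %in% sex_categories()) key else NA_character_
  } else if (characteristic == "OFFENDER_TYPE") {
    key <- gsub("[^a-z]+", "_", tolower(v))
    key <- gsub("_+$", "", key)
    if (key %in% offender_categories()) key else NA_character_
  } else if (characteristic == "NATIONALITY") {
    if (nzchar(v)) v else NA_character_
  } else {
    NA_character_
  }
}

#' Read gold annotations from a tab-separated file
#'
#' One line per standardized value: `pmid<TAB>characteristic<TAB>label`
#' with an optional fourth attribute column (offender types only). Blank
#' lines and `#` comments are ignored. Duplicate `(pmid, value)` lines
#' collapse to one (set semantics). Unknown characteristic kinds or labels
#' raise a validation error naming the offending line.
#'
#' @param path Path to the gold TSV file.
#' @return A standardized-values tibble (`pmid`, `characteristic`, `value`,
#'   `attribute`).
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(str_trim(lines)) & !grepl("^\\s*#", lines))
  rows <- list()
  for (i in keep) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      rlang::abort(sprintf("gold line %d: expected at least 3 tab-separated fields", i))
    }
    characteristic <- toupper(str_trim(parts[2]))
    characteristic <- gsub("[ -]+", "_", characteristic)
    if (!characteristic %in% characteristics()) {
      rlang::abort(sprintf("gold line %d: unknown characteristic '%s'", i, parts[2]))
    }
    value <- canon_gold_value(characteristic, parts[3])
    if (is.na(value)) {
      rlang::abort(sprintf("gold line %d: unknown %s label '%s'",
                           i, characteristic, parts[3]))
    }
    attribute <- if (length(parts) >= 4 && nzchar(str_trim(parts[4]))) {
      str_trim(parts[4])
    } else {
      NA_character_
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pmid = str_trim(parts[1]), characteristic = characteristic,
      value = value, attribute = attribute
    )
  }
  if (length(rows) == 0) return(empty_values())
  dplyr::distinct(purrr::list_rbind(rows))
}

#' Write gold annotations as a tab-separated file
#'
#' @param values Standardized-values tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(values, path) {
  values <- assert_values_frame(values)
  lines <- purrr::pmap_chr(
    values[, c("pmid", "characteristic", "value", "attribute")],
    function(pmid, characteristic, value, attribute) {
      if (is.na(attribute) || !nzchar(attribute)) {
        paste(pmid, characteristic, value, sep = "\t")
      } else {
        paste(pmid, characteristic, value, attribute, sep = "\t")
      }
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write per-abstract extraction results as JSON lines
#'
#' One JSON object per abstract (streamable and diff-friendly): `pmid`,
#' the deduplicated standardized `values`, and optionally the raw
#' `mentions`.
#'
#' @param values Standardized-values tibble.
#' @param path Output file path.
#' @param mentions Optional raw-mentions tibble (as from
#'   [extract_mentions()]) stored alongside the values.
#' @param pmids Optional character vector of all abstract ids; abstracts
#'   with no values still get a line (empty value list), so the corpus
#'   size survives the round trip.
#' @return `path`, invisibly.
#' @export
write_results <- function(values, path, mentions = NULL, pmids = NULL) {
  values <- assert_values_frame(values)
  pmids <- pmids %||% unique(values$pmid)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (id in pmids) {
    v <- values[values$pmid == id, c("characteristic", "value", "attribute")]
    obj <- list(pmid = id, values = v)
    if (!is.null(mentions)) {
      obj$mentions <- mentions[mentions$pmid == id,
                               setdiff(names(mentions), "pmid")]
    }
    writeLines(jsonlite::toJSON(obj, dataframe = "rows", na = "null",
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a JSON-lines results file
#'
#' @param path Path written by [write_results()].
#' @return A standardized-values tibble; the full set of abstract ids in
#'   the file (including those with no values) is attached as the `pmids`
#'   attribute.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(str_trim(lines))]
  pmids <- character(0)
  rows <- list()
  for (ln in lines) {
    obj <- jsonlite::fromJSON(ln)
    pmids <- c(pmids, obj$pmid)
    v <- obj$values
    if (is.data.frame(v) && nrow(v) > 0) {
      v <- tibble::as_tibble(v)
      if (!"attribute" %in% names(v)) v$attribute <- NA_character_
      v$pmid <- obj$pmid
      rows[[length(rows) + 1L]] <- v[, c("pmid", "characteristic", "value", "attribute")]
    }
  }
  out <- if (length(rows) == 0) empty_values() else purrr::list_rbind(rows)
  out$attribute <- as.character(out$attribute)
  attr(out, "pmids") <- pmids
  out
}
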