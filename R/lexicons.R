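# Gazetteer dictionaries: loading, validation and token-boundary-aware
# longest-leftmost matching against abstract text.

# Geo-lexicon precedence when one span is matchable by several
# dictionaries: more specific national identity first; cities last.
geo_lexicons <- function() {
  c("countries", "nationalities", "us_states", "us_counties", "us_cities",
    "world_cities")
}

lexicon_names <- function() {
  c("sex_terms", "offense_terms", geo_lexicons(), "population_terms",
    "age_terms")
}

# Escape regex metacharacters in a surface term, then make every internal
# space or hyphen match either (typographic variation in abstracts:
# "sex-offender" == "sex offender").
term_pattern <- function(term) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term)
  gsub("[-‐‑– ]+", "[-‐‑– ]", esc)
}

# Token boundaries: letters and digits are word characters, and a hyphen
# or apostrophe *between* word characters is internal (so "drug" does not
# match inside "drug-related", nor "rape" inside "grapevine").
boundary_left <- "(?<![A-Za-z0-9])(?<![A-Za-z0-9][-'’])"
boundary_right <- "(?![A-Za-z0-9])(?!['’-][A-Za-z0-9])"

#' Load a gazetteer lexicon from a two-column TSV file
#'
#' File format: `term<TAB>canonical` with an optional third column of
#' comma-separated suffixes to append as explicit inflection expansions
#' (e.g. `s,es` registers the plural variants under the same canonical).
#' No stemming heuristics are applied beyond the listed suffix rules.
#' Blank lines and `#` comments are ignored.
#'
#' @param path Path to the lexicon TSV file.
#' @param name Lexicon identifier (e.g. `"sex_terms"`, `"countries"`).
#' @return A tibble with columns `lexicon`, `term`, `canonical`.
#' @export
load_lexicon <- function(path, name) {
  if (!file.exists(path)) rlang::abort(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(str_trim(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0) {
    rlang::abort(sprintf("lexicon '%s' (%s) is empty", name, path))
  }
  terms <- character(0)
  canon <- character(0)
  for (i in keep) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(str_trim(parts[1])) || !nzchar(str_trim(parts[2]))) {
      rlang::abort(sprintf("lexicon '%s' line %d: expected term<TAB>canonical", name, i))
    }
    term <- str_trim(parts[1])
    label <- str_trim(parts[2])
    terms <- c(terms, term)
    canon <- c(canon, label)
    if (length(parts) >= 3 && nzchar(str_trim(parts[3]))) {
      for (sfx in str_trim(strsplit(parts[3], ",", fixed = TRUE)[[1]])) {
        terms <- c(terms, paste0(term, sfx))
        canon <- c(canon, label)
      }
    }
  }
  lex <- tibble::tibble(lexicon = name, term = terms, canonical = canon)
  lex$key <- fold_term(lex$term)
  conflict <- lex |>
    dplyr::distinct(.data$key, .data$canonical) |>
    dplyr::count(.data$key) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    rlang::abort(sprintf(
      "lexicon '%s': surface term(s) with conflicting canonicals: %s",
      name, paste(conflict$key, collapse = ", ")
    ))
  }
  dplyr::distinct(lex, .data$key, .keep_all = TRUE)[, c("lexicon", "term", "canonical", "key")]
}

#' Load the shipped seed lexicons
#'
#' Reads every lexicon TSV installed with the package (or from `dir`).
#' The seed dictionaries are representative and append-only: coverage is
#' data, not code, and users extend them by adding rows.
#'
#' @param dir Directory holding `<name>.tsv` lexicon files.
#' @return A named list of lexicon tibbles.
#' @export
default_lexicons <- function(dir = system.file("extdata", "lexicons",
                                               package = "jhminer")) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0) rlang::abort(sprintf("no lexicon files found in '%s'", dir))
  names <- sub("\\.tsv$", "", basename(files))
  lex <- purrr::map2(files, names, load_lexicon)
  setNames(lex, names)
}

as_lexicon_frame <- function(lexicons) {
  lex <- if (is.data.frame(lexicons)) {
    tibble::as_tibble(lexicons)
  } else {
    purrr::list_rbind(purrr::map(lexicons, tibble::as_tibble))
  }
  if (!"key" %in% names(lex)) lex$key <- fold_term(lex$term)
  lex
}

# Rank used to break ties among identical spans from different lexicons.
lexicon_rank <- function(lexicon) {
  order_names <- c("countries", "nationalities", "us_states", "us_counties",
                   "us_cities", "world_cities")
  r <- match(lexicon, order_names)
  ifelse(is.na(r), length(order_names) + 1L, r)
}

#' Match lexicon terms against text
#'
#' Case-insensitive, token-boundary-respecting dictionary matching with
#' hyphen/space equivalence. When candidate matches overlap, the longest
#' wins; length ties are broken leftmost, and identical spans matched by
#' several geo lexicons follow the precedence countries > nationalities >
#' US states > counties > cities. Returned spans are mutually
#' non-overlapping and sorted by start.
#'
#' @param text A single whitespace-normalized string.
#' @param lexicons One lexicon tibble, or a (named) list of them.
#' @return A tibble with columns `lexicon`, `surface`, `canonical`,
#'   `start`, `end` (0-based half-open character offsets into `text`).
#' @export
match_terms <- function(text, lexicons) {
  stopifnot(is.character(text), length(text) == 1)
  lex <- as_lexicon_frame(lexicons)
  empty <- tibble::tibble(lexicon = character(), surface = character(),
                          canonical = character(), start = integer(),
                          end = integer())
  if (!nzchar(text) || nrow(lex) == 0) return(empty)
  # Prefilter with a fixed-string scan on folded text; the full regex with
  # boundary lookarounds only runs for terms actually present.
  folded <- fold_term(text)
  present <- stringr::str_detect(paste0(" ", folded, " "),
                                 stringr::fixed(lex$key))
  lex <- lex[present, , drop = FALSE]
  if (nrow(lex) == 0) return(empty)
  cand <- list()
  for (i in seq_len(nrow(lex))) {
    rx <- paste0("(?i)", boundary_left, term_pattern(lex$term[i]), boundary_right)
    m <- gregexpr(rx, text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    cand[[length(cand) + 1L]] <- tibble::tibble(
      lexicon = lex$lexicon[i],
      canonical = lex$canonical[i],
      start = as.integer(m) - 1L,
      end = as.integer(m) - 1L + len
    )
  }
  if (length(cand) == 0) return(empty)
  cand <- purrr::list_rbind(cand)
  cand$len <- cand$end - cand$start
  cand <- cand[order(-cand$len, cand$start, lexicon_rank(cand$lexicon)), ]
  taken <- logical(nchar(text))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):cand$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- cand[keep, ]
  out$surface <- substr(rep(text, nrow(out)), out$start + 1L, out$end)
  out <- out[order(out$start), c("lexicon", "surface", "canonical", "start", "end")]
  tibble::as_tibble(out)
}

# Canonical lookup of a captured slot surface. Returns NA when the surface
# is not (modulo case/hyphen folding) a term of any of the lexicons;
# lexicons are consulted in precedence order (geo precedence).
lookup_canonical <- function(surface, lexicons, precedence = NULL) {
  lex <- as_lexicon_frame(lexicons)
  if (!is.null(precedence)) {
    lex <- lex[order(match(lex$lexicon, precedence,
                           nomatch = length(precedence) + 1L)), ]
  }
  hit <- match(fold_term(surface), lex$key)
  ifelse(is.na(hit), NA_character_, lex$canonical[hit])
}
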