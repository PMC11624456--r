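# The lexical-pattern rule engine: a line-oriented DSL of semifrozen
# patterns (literal anchors, regular-expression anchors, lexicon slots)
# compiled to single regular expressions with named capture groups.

# DSL element grammar, one rule per line:
#   ID <TAB> CHARACTERISTIC <TAB> element;element;...
# element := LIT:"..." | RX:"..." | SLOT:lex1[,lex2,...]
# any element may carry a trailing `!capture`; at least one must.
# `#` starts a comment; `;` is reserved as the element separator and may
# not appear inside patterns.
parse_rule_element <- function(raw, rule_id) {
  el <- str_trim(raw)
  capture <- grepl("!capture$", el)
  el <- sub("!capture$", "", el)
  m <- regmatches(el, regexec('^(LIT|RX):"(.*)"$', el))[[1]]
  if (length(m) == 3) {
    return(list(type = tolower(m[2]), value = m[3], capture = capture))
  }
  m <- regmatches(el, regexec("^SLOT:([A-Za-z0-9_,]+)$", el))[[1]]
  if (length(m) == 2) {
    return(list(type = "slot",
                value = str_trim(strsplit(m[2], ",", fixed = TRUE)[[1]]),
                capture = capture))
  }
  rlang::abort(sprintf("rule '%s': cannot parse element '%s'", rule_id, raw))
}

slot_alternation <- function(lex_names, lexicons, rule_id) {
  missing <- setdiff(lex_names, names(lexicons))
  if (length(missing) > 0) {
    rlang::abort(sprintf("rule '%s': slot names undefined lexicon(s): %s",
                         rule_id, paste(missing, collapse = ", ")))
  }
  terms <- unlist(purrr::map(lexicons[lex_names], function(l) l$term))
  terms <- unique(terms)
  # longest alternative first so the regex prefers the longest match at a
  # given start position
  terms <- terms[order(-nchar(terms))]
  paste0("(?:", paste(vapply(terms, term_pattern, character(1)),
                      collapse = "|"), ")")
}

compile_one_rule <- function(id, characteristic, elements_raw, lexicons) {
  characteristic <- toupper(str_trim(characteristic))
  if (!characteristic %in% characteristics()) {
    rlang::abort(sprintf("rule '%s': unknown characteristic '%s'",
                         id, characteristic))
  }
  raw_els <- strsplit(elements_raw, ";", fixed = TRUE)[[1]]
  raw_els <- raw_els[nzchar(str_trim(raw_els))]
  if (length(raw_els) == 0) {
    rlang::abort(sprintf("rule '%s': no pattern elements", id))
  }
  els <- purrr::map(raw_els, parse_rule_element, rule_id = id)
  n_cap <- sum(vapply(els, function(e) e$capture, logical(1)))
  if (n_cap == 0) {
    rlang::abort(sprintf("rule '%s': empty capture (no element marked !capture)", id))
  }
  cap_i <- 0L
  pieces <- vapply(els, function(e) {
    body <- switch(e$type,
      lit = term_pattern(e$value),
      rx = paste0("(?:", e$value, ")"),
      slot = slot_alternation(e$value, lexicons, id)
    )
    if (e$capture) {
      cap_i <<- cap_i + 1L
      paste0("(?<jhcap", cap_i, ">", body, ")")
    } else {
      body
    }
  }, character(1))
  regex <- paste0("(?i)", boundary_left,
                  paste(pieces, collapse = "[^A-Za-z0-9]+"),
                  boundary_right)
  tibble::tibble(id = id, characteristic = characteristic, regex = regex,
                 n_captures = cap_i, n_elements = length(els))
}

#' Compile a rule file against a set of lexicons
#'
#' Reads the line-oriented rule DSL (see Details), validates every slot
#' against the loaded lexicons, and compiles each rule to a single regular
#' expression with named capture groups. Per-characteristic rule counts
#' are reported.
#'
#' @details One rule per line: `ID<TAB>CHARACTERISTIC<TAB>element;element;...`
#' where an element is `LIT:"literal tokens"`, `RX:"regex"` or
#' `SLOT:lexicon[,lexicon...]`, optionally suffixed `!capture` to mark the
#' element(s) that yield the mention. Literals get hyphen/space
#' equivalence; slot alternations are built longest-first from the named
#' lexicons; elements are joined by one-or-more non-alphanumeric
#' characters; the whole pattern is token-boundary anchored and
#' case-insensitive.
#'
#' @param path A rule file, a directory of `rules_*.tsv` files, or a
#'   character vector of files.
#' @param lexicons Named list of lexicon tibbles (see [default_lexicons()]).
#' @param quiet Suppress the per-characteristic count message.
#' @return A tibble of compiled rules (`id`, `characteristic`, `regex`,
#'   `n_captures`, `n_elements`) with class `jh_rules`.
#' @export
compile_rules <- function(path, lexicons, quiet = FALSE) {
  files <- path
  if (length(path) == 1 && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
  }
  lines <- unlist(purrr::map(files, function(f) {
    if (!file.exists(f)) rlang::abort(sprintf("cannot read '%s': no such file", f))
    readLines(f, warn = FALSE, encoding = "UTF-8")
  }))
  keep <- nzchar(str_trim(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  if (length(lines) == 0) {
    rlang::warn("rule file is empty: compiled an empty rule set")
    out <- tibble::tibble(id = character(), characteristic = character(),
                          regex = character(), n_captures = integer(),
                          n_elements = integer())
    class(out) <- c("jh_rules", class(out))
    return(out)
  }
  rules <- purrr::list_rbind(purrr::map(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      rlang::abort(sprintf("rule line '%s': expected ID<TAB>CHARACTERISTIC<TAB>elements",
                           substr(ln, 1, 40)))
    }
    compile_one_rule(str_trim(parts[1]), parts[2], parts[3], lexicons)
  }))
  dup <- rules$id[duplicated(rules$id)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate rule id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (!quiet) {
    counts <- table(factor(rules$characteristic, levels = characteristics()))
    rlang::inform(sprintf(
      "compiled %d rule(s): %s", nrow(rules),
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")
    ))
  }
  class(rules) <- c("jh_rules", class(rules))
  rules
}

#' Compile the shipped starter rule set
#'
#' @param lexicons Named list of lexicon tibbles.
#' @param dir Directory of rule files (defaults to the installed
#'   `rules_age/sex/nationality/offender` files).
#' @param quiet Suppress the count message.
#' @return A `jh_rules` tibble.
#' @export
default_rules <- function(lexicons,
                          dir = system.file("extdata", "rules", package = "jhminer"),
                          quiet = TRUE) {
  compile_rules(dir, lexicons, quiet = quiet)
}

empty_mentions <- function() {
  tibble::tibble(characteristic = character(), surface = character(),
                 start = integer(), end = integer(), rule_id = character(),
                 age_low = double(), age_high = double())
}

#' Parse a numeric age capture into (low, high) bounds in years
#'
#' Supports the forms seen in abstracts: `"18 to 24 years"`, `"18-24
#' years"`, `"aged 30"`, `"12 and 14-year-old"`, `"65+"`, `"older than
#' 60"`, `"younger than 18"` (plus `over`/`under`/`above`/`below`
#' synonyms). A single age gives a point interval; `"older than X"` means
#' `(X+1, open)`; `"younger than X"` means `(0, X-1)`.
#'
#' @param surface The captured text of a numeric age pattern.
#' @return A named numeric vector `c(low=, high=)` (`high` may be `Inf`),
#'   or `NULL` if the capture cannot be parsed.
#' @export
parse_numeric_age <- function(surface) {
  s <- tolower(str_trim(surface))
  nums <- as.numeric(regmatches(s, gregexpr("\\d+", s))[[1]])
  if (length(nums) == 0) return(NULL)
  if (grepl("older than|over|above", s)) {
    return(c(low = nums[1] + 1, high = Inf))
  }
  if (grepl("\\d\\s*\\+", s)) {
    return(c(low = nums[1], high = Inf))
  }
  if (grepl("younger than|under|below", s)) {
    return(c(low = 0, high = max(nums[1] - 1, 0)))
  }
  if (length(nums) == 1) {
    return(c(low = nums[1], high = nums[1]))
  }
  if (length(nums) == 2) {
    return(c(low = min(nums), high = max(nums)))
  }
  NULL
}

apply_rules_one <- function(text, rules) {
  if (!nzchar(text) || nrow(rules) == 0) return(empty_mentions())
  out <- list()
  for (i in seq_len(nrow(rules))) {
    m <- gregexpr(rules$regex[i], text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    cs <- attr(m, "capture.start")
    cl <- attr(m, "capture.length")
    cap_cols <- grep("^jhcap", colnames(cs))
    for (j in seq_along(m)) {
      for (k in cap_cols) {
        if (cl[j, k] <= 0) next
        start0 <- cs[j, k] - 1L
        end0 <- start0 + cl[j, k]
        out[[length(out) + 1L]] <- tibble::tibble(
          characteristic = rules$characteristic[i],
          surface = substr(text, start0 + 1L, end0),
          start = start0, end = end0, rule_id = rules$id[i],
          age_low = NA_real_, age_high = NA_real_
        )
      }
    }
  }
  if (length(out) == 0) return(empty_mentions())
  mentions <- purrr::list_rbind(out)
  # parse numeric bounds for AGE captures that contain digits; unparseable
  # numeric captures are discarded with a warning, never a crash
  is_num_age <- mentions$characteristic == "AGE" & grepl("\\d", mentions$surface)
  drop <- logical(nrow(mentions))
  for (i in which(is_num_age)) {
    b <- parse_numeric_age(mentions$surface[i])
    if (is.null(b) || b["low"] > b["high"] || b["low"] < 0) {
      rlang::warn(sprintf("dropping unparseable numeric age capture '%s'",
                          mentions$surface[i]))
      drop[i] <- TRUE
    } else {
      mentions$age_low[i] <- b["low"]
      mentions$age_high[i] <- b["high"]
    }
  }
  mentions <- mentions[!drop, ]
  mentions[order(mentions$start, mentions$rule_id), ]
}

#' Apply compiled rules to one abstract
#'
#' Every rule is attempted across the whole (whitespace-normalized) text;
#' all captures are returned, including duplicates and overlaps across
#' rules — deduplication is the standardization step's job. Output order
#' is deterministic: by start offset, then rule id.
#'
#' @param record Either a single string (the abstract text) or a one-row
#'   corpus tibble.
#' @param rules Compiled `jh_rules` tibble.
#' @return A mentions tibble (`characteristic`, `surface`, `start`, `end`,
#'   `rule_id`, `age_low`, `age_high`; offsets 0-based half-open against
#'   the normalized text).
#' @export
apply_rules <- function(record, rules) {
  text <- if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record$text
  } else {
    record
  }
  apply_rules_one(normalize_whitespace(text), rules)
}

#' Apply compiled rules to a whole corpus
#'
#' @param corpus Corpus tibble (`pmid`, `text`, ...).
#' @param rules Compiled `jh_rules` tibble.
#' @return Mentions tibble with a leading `pmid` column.
#' @export
extract_mentions <- function(corpus, rules) {
  validate_corpus(corpus)
  per <- purrr::map(seq_len(nrow(corpus)), function(i) {
    m <- apply_rules_one(normalize_whitespace(corpus$text[i]), rules)
    if (nrow(m) > 0) m$pmid <- corpus$pmid[i]
    m
  })
  out <- purrr::list_rbind(per)
  if (nrow(out) == 0) {
    out <- empty_mentions()
    out$pmid <- character(0)
  }
  out[, c("pmid", setdiff(names(out), "pmid"))]
}
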