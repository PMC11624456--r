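# Abstract-level evaluation: TP/FP/FN per characteristic and the derived
# precision/recall/F1 (per-class, macro, micro), plus absolute annotator
# agreement.

empty_counts <- function() {
  tibble::tibble(characteristic = characteristics(), tp = 0L, fp = 0L, fn = 0L)
}

#' Align gold and predicted values for one abstract
#'
#' The unit of evaluation is the distinct standardized value per
#' characteristic per abstract: several raw mentions that standardize to
#' the same value count once, so detecting any of them is a single TP.
#' Per characteristic: TP = |gold intersect predicted|, FP = |predicted
#' minus gold|, FN = |gold minus predicted|.
#'
#' @param gold,predicted Standardized-values tibbles for a single
#'   abstract (deduplicated; [dedupe_values()] is applied defensively).
#' @return A tibble with one row per characteristic: `characteristic`,
#'   `tp`, `fp`, `fn`.
#' @export
align_abstract <- function(gold, predicted) {
  gold <- dedupe_values(gold)
  predicted <- dedupe_values(predicted)
  ids <- unique(c(gold$pmid, predicted$pmid))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1) {
    rlang::abort(sprintf("gold and predicted refer to different abstracts: %s",
                         paste(ids, collapse = ", ")))
  }
  gk <- value_key(gold$characteristic, gold$value, gold$attribute)
  pk <- value_key(predicted$characteristic, predicted$value, predicted$attribute)
  tally <- function(chars) {
    table(factor(chars, levels = characteristics()))
  }
  tp <- tally(gold$characteristic[gk %in% pk])
  fn <- tally(gold$characteristic[!gk %in% pk])
  fp <- tally(predicted$characteristic[!pk %in% gk])
  tibble::tibble(characteristic = characteristics(),
                 tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Align gold and predicted values across a corpus
#'
#' Sums the per-abstract alignment over all abstracts. The two inputs
#' must cover the same abstract universe; pass `pmids` explicitly when
#' some abstracts legitimately have no values on either side.
#'
#' @param gold,predicted Standardized-values tibbles.
#' @param pmids Abstract universe (default: union of both inputs' pmids).
#' @return Per-characteristic counts tibble (`characteristic`, `tp`,
#'   `fp`, `fn`).
#' @export
align_corpus <- function(gold, predicted, pmids = NULL) {
  gold <- dedupe_values(gold)
  predicted <- dedupe_values(predicted)
  if (is.null(pmids)) {
    pmids <- union(gold$pmid, predicted$pmid)
  } else {
    stray <- c(setdiff(gold$pmid, pmids), setdiff(predicted$pmid, pmids))
    if (length(stray) > 0) {
      rlang::abort(sprintf("values for abstract(s) outside the pmid universe: %s",
                           paste(unique(stray), collapse = ", ")))
    }
  }
  gk <- paste(gold$pmid, value_key(gold$characteristic, gold$value, gold$attribute))
  pk <- paste(predicted$pmid,
              value_key(predicted$characteristic, predicted$value, predicted$attribute))
  tally <- function(chars) {
    as.integer(table(factor(chars, levels = characteristics())))
  }
  tibble::tibble(
    characteristic = characteristics(),
    tp = tally(gold$characteristic[gk %in% pk]),
    fp = tally(predicted$characteristic[!pk %in% gk]),
    fn = tally(gold$characteristic[!gk %in% pk])
  )
}

# Percentage with truncation to one decimal; 0/0 handled by caller.
metric_pct <- function(num, den) {
  ifelse(den == 0, 0, trunc_dec(100 * num / den))
}

#' Precision, recall and F1 from TP/FP/FN counts
#'
#' Percentages are reported to one decimal using truncation, the
#' convention under which the published evaluation-table arithmetic
#' reproduces exactly (see the methods vignette); F1 is the harmonic mean
#' of the reported (one-decimal) precision and recall, again truncated.
#' Zero denominators yield 0.0 with a warning so batch evaluation stays
#' total.
#'
#' @param counts Counts tibble (`characteristic`, `tp`, `fp`, `fn`) as
#'   from [align_corpus()].
#' @return The input with `precision`, `recall`, `f1` columns appended
#'   (percentages in `[0, 100]`).
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn") %in% names(counts)))
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0)) {
    rlang::abort("negative counts")
  }
  if (any(counts$tp + counts$fp == 0) || any(counts$tp + counts$fn == 0)) {
    rlang::warn("zero denominator: reporting 0.0 for the affected metric")
  }
  p <- metric_pct(counts$tp, counts$tp + counts$fp)
  r <- metric_pct(counts$tp, counts$tp + counts$fn)
  f1 <- ifelse(p + r == 0, 0, trunc_dec(2 * p * r / (p + r)))
  dplyr::mutate(tibble::as_tibble(counts), precision = p, recall = r, f1 = f1)
}

#' Micro-averaged metrics
#'
#' Pools TP/FP/FN across characteristics before computing
#' precision/recall/F1 — the weighted view when class sizes differ
#' drastically.
#'
#' @param counts Per-characteristic counts tibble.
#' @return A one-row metrics tibble with `characteristic = "micro"`.
#' @export
micro_metrics <- function(counts) {
  if (nrow(counts) == 0) rlang::abort("micro_metrics: empty counts")
  pooled <- tibble::tibble(characteristic = "micro",
                           tp = sum(counts$tp), fp = sum(counts$fp),
                           fn = sum(counts$fn))
  compute_metrics(pooled)
}

#' Macro-averaged metrics
#'
#' Unweighted arithmetic mean of the per-class percentages, reported to
#' one decimal under the same truncation convention.
#'
#' @param metrics Per-class metrics tibble (from [compute_metrics()]).
#' @return A one-row tibble `precision`/`recall`/`f1`.
#' @export
macro_metrics <- function(metrics) {
  stopifnot(all(c("precision", "recall", "f1") %in% names(metrics)))
  if (nrow(metrics) == 0) rlang::abort("macro_metrics: empty metrics")
  tibble::tibble(
    precision = trunc_dec(mean(metrics$precision)),
    recall = trunc_dec(mean(metrics$recall)),
    f1 = trunc_dec(mean(metrics$f1))
  )
}

#' Absolute annotator agreement at the abstract level
#'
#' The percentage of abstracts on which two annotators produced identical
#' value sets across all four characteristics jointly.
#'
#' @param annotator_a,annotator_b Standardized-values tibbles over the
#'   same pmid universe.
#' @param pmids Abstract universe (default: union of both inputs).
#' @return Agreement percentage (one decimal, half-up).
#' @export
absolute_agreement <- function(annotator_a, annotator_b, pmids = NULL) {
  a <- dedupe_values(annotator_a)
  b <- dedupe_values(annotator_b)
  if (is.null(pmids)) {
    pmids <- union(a$pmid, b$pmid)
  } else {
    stray <- c(setdiff(a$pmid, pmids), setdiff(b$pmid, pmids))
    if (length(stray) > 0) {
      rlang::abort(sprintf("annotations outside the pmid universe: %s",
                           paste(unique(stray), collapse = ", ")))
    }
  }
  if (length(pmids) == 0) rlang::abort("absolute_agreement: empty pmid universe")
  ak <- split(paste(value_key(a$characteristic, a$value, a$attribute)), a$pmid)
  bk <- split(paste(value_key(b$characteristic, b$value, b$attribute)), b$pmid)
  same <- vapply(pmids, function(id) {
    setequal(ak[[id]] %||% character(0), bk[[id]] %||% character(0))
  }, logical(1))
  pct(sum(same), length(pmids))
}

#' Evaluate extraction output against gold annotations
#'
#' Bundles corpus-level alignment, per-characteristic metrics and the
#' macro/micro summaries into one object with [tidy()] and [glance()]
#' methods.
#'
#' @param predicted,gold Standardized-values tibbles.
#' @param pmids Abstract universe (default: union of both inputs).
#' @return An object of class `jh_eval` (list with `counts`, `metrics`,
#'   `macro`, `micro`).
#' @export
evaluate_extraction <- function(predicted, gold, pmids = NULL) {
  counts <- align_corpus(gold, predicted, pmids = pmids)
  metrics <- suppressWarnings(compute_metrics(counts))
  structure(
    list(counts = counts, metrics = metrics,
         macro = macro_metrics(metrics),
         micro = suppressWarnings(micro_metrics(counts))),
    class = "jh_eval"
  )
}

#' @export
print.jh_eval <- function(x, ...) {
  cat("Abstract-level extraction evaluation\n")
  print(x$metrics)
  cat(sprintf("macro: P=%.1f R=%.1f F1=%.1f | micro: P=%.1f R=%.1f F1=%.1f\n",
              x$macro$precision, x$macro$recall, x$macro$f1,
              x$micro$precision, x$micro$recall, x$micro$f1))
  invisible(x)
}

#' Tidy a jh_eval object into per-characteristic metric rows
#' @param x A `jh_eval` object.
#' @param ... Unused.
#' @export
tidy.jh_eval <- function(x, ...) {
  x$metrics
}

#' One-row macro/micro summary of a jh_eval object
#' @param x A `jh_eval` object.
#' @param ... Unused.
#' @export
glance.jh_eval <- function(x, ...) {
  tibble::tibble(
    macro_precision = x$macro$precision, macro_recall = x$macro$recall,
    macro_f1 = x$macro$f1,
    micro_precision = x$micro$precision, micro_recall = x$micro$recall,
    micro_f1 = x$micro$f1
  )
}

#' Bar-chart of per-characteristic precision/recall/F1
#' @param object A `jh_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jh_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              cols = c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$characteristic,
                                     y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal()
}
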