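test_that("abstract alignment counts distinct standardized values", {
  # two surface forms of one value are a single TP
  gold <- values_row("p1", "SEX", "female")
  pred <- values_row("p1", "SEX", "female") # post-dedup regardless of surfaces
  counts <- align_abstract(gold, pred)
  sex <- counts[counts$characteristic == "SEX", ]
  expect_equal(c(sex$tp, sex$fp, sex$fn), c(1L, 0L, 0L))

  empty <- align_abstract(empty_values_for_tests(), empty_values_for_tests())
  expect_true(all(empty$tp == 0 & empty$fp == 0 & empty$fn == 0))

  gold2 <- dplyr::bind_rows(values_row("p2", "NATIONALITY", "Norwegian"),
                            values_row("p2", "NATIONALITY", "Swedish"))
  pred2 <- dplyr::bind_rows(values_row("p2", "NATIONALITY", "Norwegian"),
                            values_row("p2", "NATIONALITY", "American"))
  nat <- align_abstract(gold2, pred2)
  nat <- nat[nat$characteristic == "NATIONALITY", ]
  expect_equal(c(nat$tp, nat$fp, nat$fn), c(1L, 1L, 1L))

  expect_error(align_abstract(gold, pred2), "different abstracts")
})

test_that("offender attributes participate in structural equality", {
  gold <- values_row("p", "OFFENDER_TYPE", "sex", "rape")
  pred_plain <- values_row("p", "OFFENDER_TYPE", "sex")
  counts <- align_abstract(gold, pred_plain)
  off <- counts[counts$characteristic == "OFFENDER_TYPE", ]
  expect_equal(c(off$tp, off$fp, off$fn), c(0L, 1L, 1L))
})

test_that("metric arithmetic reproduces the published evaluation rows", {
  counts <- tibble::tibble(
    characteristic = c("SEX", "NATIONALITY", "OFFENDER_TYPE"),
    tp = c(54L, 40L, 98L), fp = c(0L, 4L, 8L), fn = c(4L, 2L, 19L))
  m <- compute_metrics(counts)
  expect_equal(m$precision, c(100.0, 90.9, 92.4))
  expect_equal(m$recall, c(93.1, 95.2, 83.7))
  expect_equal(m$f1[1:2], c(96.4, 93.0))
})

test_that("the metric reporting convention matches all reproducible rows", {
  tab <- readr::read_tsv(system.file("extdata", "tables", "evaluation_counts.tsv",
                                     package = "jhminer"),
                         show_col_types = FALSE)
  m <- compute_metrics(tab)
  printed <- list( # dataset, characteristic, precision, recall
    c("training", "AGE", 89.4, 83.6), c("development", "AGE", 98.2, 85.0),
    c("training", "SEX", 91.2, 91.2), c("development", "SEX", 90.0, 91.5),
    c("evaluation", "SEX", 100.0, 93.1),
    c("training", "OFFENDER_TYPE", 83.8, 83.8),
    c("development", "OFFENDER_TYPE", 89.5, 92.1),
    c("evaluation", "OFFENDER_TYPE", 92.4, 83.7),
    c("training", "NATIONALITY", 92.3, 92.3),
    c("development", "NATIONALITY", 86.4, 96.9),
    c("evaluation", "NATIONALITY", 90.9, 95.2)
  )
  for (row in printed) {
    hit <- m[m$dataset == row[1] & m$characteristic == row[2], ]
    expect_equal(hit$precision, as.numeric(row[3]),
                 info = paste(row[1], row[2]))
    expect_equal(hit$recall, as.numeric(row[4]), info = paste(row[1], row[2]))
  }
})

test_that("degenerate counts report 0.0 with a warning", {
  expect_warning(
    z <- compute_metrics(tibble::tibble(characteristic = "SEX",
                                        tp = 0L, fp = 0L, fn = 0L)),
    "zero denominator")
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_error(compute_metrics(tibble::tibble(tp = -1L, fp = 0L, fn = 0L)),
               "negative")
})

test_that("metric invariants hold on random counts", {
  set.seed(21)
  for (i in 1:60) {
    counts <- tibble::tibble(characteristic = "SEX", tp = sample(0:80, 1),
                             fp = sample(0:30, 1), fn = sample(0:30, 1))
    m <- suppressWarnings(compute_metrics(counts))
    expect_true(all(c(m$precision, m$recall, m$f1) >= 0))
    expect_true(all(c(m$precision, m$recall, m$f1) <= 100))
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-9)
    expect_equal(m$f1 == 0, m$precision == 0 || m$recall == 0)
    # symmetry: swapping gold and predicted swaps precision and recall
    sw <- suppressWarnings(compute_metrics(
      tibble::tibble(characteristic = "SEX", tp = counts$tp,
                     fp = counts$fn, fn = counts$fp)))
    expect_equal(sw$precision, m$recall)
    expect_equal(sw$recall, m$precision)
  }
})

test_that("micro pools counts; macro averages percentages", {
  one <- tibble::tibble(characteristic = "SEX", tp = 10L, fp = 2L, fn = 1L)
  expect_equal(micro_metrics(one)[, c("precision", "recall", "f1")],
               compute_metrics(one)[, c("precision", "recall", "f1")])
  two <- tibble::tibble(characteristic = c("SEX", "AGE"),
                        tp = c(1L, 0L), fp = c(0L, 1L), fn = c(0L, 1L))
  mi <- suppressWarnings(micro_metrics(two))
  expect_equal(c(mi$tp, mi$fp, mi$fn), c(1L, 1L, 1L))
  expect_equal(c(mi$precision, mi$recall, mi$f1), c(50, 50, 50))
  expect_error(micro_metrics(two[0, ]), "empty")

  metrics <- tibble::tibble(precision = c(97.6, 100.0, 92.4, 90.9),
                            recall = c(1, 2, 3, 4), f1 = c(1, 2, 3, 4))
  expect_equal(macro_metrics(metrics)$precision, 95.2)
  single <- tibble::tibble(precision = 88.8, recall = 70, f1 = 78.3)
  expect_equal(macro_metrics(single)$precision, 88.8)
  expect_equal(macro_metrics(tibble::tibble(precision = c(0, 100),
                                            recall = c(0, 100),
                                            f1 = c(0, 100)))$precision, 50)
  expect_error(macro_metrics(metrics[0, ]), "empty")

  # additivity: pooled counts equal the sum of the parts
  set.seed(5)
  counts <- tibble::tibble(characteristic = characteristics(),
                           tp = sample(1:50, 4), fp = sample(0:20, 4),
                           fn = sample(0:20, 4))
  mi2 <- micro_metrics(counts)
  expect_equal(mi2$tp, sum(counts$tp))
  expect_equal(mi2$fp, sum(counts$fp))
  expect_equal(mi2$fn, sum(counts$fn))
  # micro precision lies between the per-class extremes
  per <- compute_metrics(counts)
  expect_gte(mi2$precision, min(per$precision) - 0.1)
  expect_lte(mi2$precision, max(per$precision) + 0.1)
})

test_that("absolute agreement is the share of identical abstracts", {
  a <- dplyr::bind_rows(values_row("p1", "SEX", "female"),
                        values_row("p2", "SEX", "male"),
                        values_row("p3", "AGE", "minor"),
                        values_row("p4", "NATIONALITY", "Swedish"))
  expect_equal(absolute_agreement(a, a), 100)
  b <- dplyr::bind_rows(values_row("p1", "SEX", "female"),
                        values_row("p2", "SEX", "female"), # differs
                        values_row("p3", "AGE", "18-24"),  # differs
                        values_row("p4", "NATIONALITY", "Swedish"))
  expect_equal(absolute_agreement(a, b), 50)
  # 92 identical of 100
  ids <- sprintf("q%03d", 1:100)
  aa <- dplyr::bind_rows(lapply(ids, function(i) values_row(i, "SEX", "male")))
  bb <- aa
  bb$value[1:8] <- "female"
  expect_equal(absolute_agreement(aa, bb), 92)
  expect_error(absolute_agreement(a, b, pmids = c("p1", "p2")), "universe")
})

test_that("evaluation object exposes tidy/glance and matches the oracle", {
  set.seed(31)
  ids <- sprintf("e%02d", 1:30)
  gold <- random_values(ids)
  pred <- random_values(ids)
  ev <- evaluate_extraction(pred, gold, pmids = ids)
  want <- oracle_align(gold, pred, ids)
  expect_equal(ev$counts$tp, want$tp)
  expect_equal(ev$counts$fp, want$fp)
  expect_equal(ev$counts$fn, want$fn)
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("precision", "recall", "f1") %in% names(td)))
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("macro_precision", "micro_f1") %in% names(gl)))
  expect_s3_class(autoplot(ev), "ggplot")
})
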