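---
title: "Mining population characteristics from justice health abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining population characteristics from justice health abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(jhminer)
library(dplyr)
```

## The problem

Epidemiological criminology (justice health) studies the health of
offending and incarcerated populations. Whether that research effort is
spread equitably across population groups is an empirical question, and
the raw material to answer it — who was studied — sits in free-text
bibliographic abstracts. `jhminer` extracts four population
characteristics from such abstracts (age, sex, nationality, offender
type), standardizes them into closed category systems, evaluates the
extraction at the abstract level, and aggregates the results into the
descriptive tables used for gap analysis: coverage rates, age and
offender-type distributions, sex-proportion time series, and country
rankings adjusted for the size of the incarcerated population.

The method is deliberately simple: gazetteer dictionaries plus
semifrozen lexical patterns. Abstracts are written in a semistructured
epidemiological register ("characteristics of sex offenders in
Norway...", "participants aged 18 to 24 years..."), which rule-based
matching exploits without any training data, and every extraction is
traceable to a rule and a dictionary row.

## The pipeline

Extraction proceeds in four steps, each with a public interface:

1. **Reading** (`read_medline()`, `read_pubmed_xml()`): abstracts come in
   as MEDLINE flat files or PubMed XML. Text is whitespace-normalized on
   read (runs of whitespace collapse to single spaces) because the rules
   anchor on token sequences; all downstream character offsets address
   the normalized text. Records without an abstract are skipped and
   counted, never dropped silently.
2. **Matching** (`match_terms()`, `apply_rules()`): dictionaries map
   surface terms to canonical labels; rules combine literal anchors,
   regular-expression anchors and dictionary slots into single compiled
   patterns. All rules fire everywhere; overlaps and duplicates across
   rules are kept at this stage.
3. **Standardization** (`normalize_mentions()`, `dedupe_values()`): raw
   surfaces become canonical values, and duplicate values collapse per
   abstract — the unit of all downstream analysis is the distinct
   standardized value per characteristic per abstract.
4. **Evaluation and analytics** (`evaluate_extraction()`,
   `summarize_corpus()`, `age_distribution()`, `sex_series()`,
   `offender_rates()`, `country_ranking()`).

```{r pipeline}
corpus <- tibble(pmid = "ex1", year = 2020L, title = NA_character_,
                 text = "Characteristics of sex offenders in Norway: women aged 18 to 25 years.",
                 language = "eng")
extract_characteristics(corpus)
```

## Dictionaries

Ten dictionaries are shipped as append-only TSV files under
`inst/extdata/lexicons/`: sex terms, offense terms, offender-population
descriptors, textual age terms, and six geographic dictionaries
(countries, nationalities, world cities, US states, US counties, US
cities). Coverage is data, not code: the seed sets are representative —
every term the method's documentation relies on is present — and users
extend them by appending rows. The published corpus study used larger
dictionaries (for example 1036 offense terms and 3135 US counties);
reaching those counts is a data-curation task the file format supports,
not a code change, so mention counts on a real corpus depend on how far
the user grows the dictionaries.

Matching is case-insensitive, treats internal hyphens and spaces as
equivalent ("sex-offender" matches "sex offender"), and respects token
boundaries: letters and digits are word characters, and a hyphen or
apostrophe flanked by word characters is internal, so "rape" never
matches inside "grapevine" and "drug" never matches inside
"drug-related". When candidate matches overlap, the longest wins, ties
break leftmost, and identical geographic spans resolve by precedence
countries > nationalities > US states > counties > cities (the more
specific national identity first, mirroring the standardize-to-American
rule).

## Rules

Rules live in a line-oriented DSL, one rule per line:
`ID<TAB>CHARACTERISTIC<TAB>element;element;...` with elements
`LIT:"..."` (literal anchor), `RX:"..."` (regular-expression anchor) and
`SLOT:lexicon[,lexicon]`, any of them flagged `!capture` to yield the
mention. The shipped starter set (11 age, 4 sex, 3 nationality, 4
offender-type rules) realizes the pattern families the method rests on —
bare dictionary rules, anchored patterns like
`characteristics of <offense> in`, and the numeric-age grammar
("18 to 24 years", "aged 30", "12 and 14-year-old", "65+", "older
than 60", "younger than 18"). Users add rules by appending lines.

Two design points matter for correctness:

* **Pooled slots within a characteristic.** Every offender slot pools the
  offense and population dictionaries. Longest-match selection operates
  inside a single rule's alternation; a second rule with only the
  population dictionary would lawfully match "inmates" inside "psychotic
  inmates" and produce a structurally wrong extra value that no
  downstream step could remove.
* **No sentence splitting, no negation or hedge handling, no fuzzy
  matching.** The extraction unit is the whole abstract; misspelled
  mentions are missed (false negatives) and irrelevant contexts
  ("as in the earlier British study") are matched (false positives).
  These are the method's documented error modes and the package
  reproduces them rather than papering over them.

Numeric age captures parse to closed integer bounds: "aged 30" is
(30, 30), "older than 60" is (61, open), "younger than 18" is (0, 17).
Unparseable captures are dropped with a warning, never a crash.

## Standardization

* **Age** uses the Australian Bureau of Statistics groups: minors (<18),
  18-24, 25-34, 35-44, 45-54, 55-64, 65+, plus `unknown_adult` for bare
  "adults". Numeric ranges map to every group their closed interval
  overlaps — ages 18-25 yield {18-24, 25-34}; a range inside one group
  yields a singleton. Textual terms map through the shipped
  classification table ("adolescent" → {minor, 18-24}; "juvenile" →
  {minor}).
* **Sex** is a closed five-category system: male, female, transgender
  (unspecified), transgender man, transgender woman. Conjoined surfaces
  ("boys and girls") fan out to multiple categories.
* **Nationality** standardizes to demonyms; all US subdivisions become
  "American"; defunct identities (Czechoslovakian, Yugoslav) become
  "miscellaneous"; UK variants collapse to "British". The mapping is
  total over the shipped dictionaries.
* **Offender type** is two-level: a category (child crime-related, sex,
  violent, nonviolent, mentally ill, drug-related, miscellaneous) plus an
  optional specific attribute ("serial rapists" → sex offender / rape;
  "psychotic inmates" → mentally ill / psychosis). Generic surfaces like
  "sex offenders" carry no attribute. Canonicals with no category
  mapping — including all generic population descriptors — fall back to
  miscellaneous with the descriptor as attribute, so the mapping is
  total; miscellaneous always carries an attribute. Category
  assignments the source taxonomy leaves open are the package's own:
  domestic-violence orders and stalking are classed violent,
  driving under the influence drug-related, theft/fraud/shoplifting
  nonviolent.

A deliberate ambiguity: "boys"/"girls" are both sex terms and textual
age terms (<18), and "juveniles"/"delinquents" are both age terms and
offender-population descriptors. Rules for both characteristics fire on
such surfaces and both standardized values are kept — the same surface
can carry two kinds of information ("women with borderline personality
disorder" yields a sex and an offender value from overlapping text).

## Evaluation

Evaluation is at the abstract level: the unit is the distinct
standardized value, so an abstract mentioning "females" and "women"
contributes one female value, and detecting either surface is one true
positive. Per characteristic, TP = |gold ∩ predicted|,
FP = |predicted \ gold|, FN = |gold \ predicted|; precision, recall and
F1 follow, plus a macro average (unweighted mean of per-class
percentages) and a micro average (pool counts first — the weighted view
when class sizes differ drastically). Annotator consistency uses the
absolute agreement rate: the share of abstracts where two annotation
sets are identical across all four characteristics jointly.

Two numerical conventions are fixed package-wide:

* **Evaluation metrics truncate to one decimal**, and F1 is the harmonic
  mean of the truncated precision and recall, truncated again. This is
  the convention under which the published evaluation-table arithmetic
  reproduces exactly from its TP/FP/FN counts (half-up rounding fails on
  several rows, e.g. 98/106 = 92.45% which prints as 92.4). The
  shipped `evaluation_counts.tsv` carries those published counts and the
  test suite recomputes every reproducible row.
* **Analytics percentages and per-1000 rates round half-up to one
  decimal** — the convention of the published descriptive tables
  (1000 × 138/3289 = 41.957 prints as 42.0).

Zero denominators report 0.0 with a warning so batch evaluation stays
total.

## Analytics

Denominators follow the reporting conventions of the field's summary
tables: age-group shares divide by age-reporting abstracts (one abstract
can sit in several groups), offender-type shares by
offender-type-reporting abstracts, yearly sex proportions by
sex-reporting abstracts that year ("female-only" means the sex set is
exactly {female}). Abstracts without a publication year are kept for
extraction but excluded from time series, with a reported count.

Country rankings compare a crude rank (ordinal by article count; tied
counts get successive ranks in input order, matching the published
table) with a prisoner-population-adjusted rank: articles per 1000
prisoners, computed half-up to one decimal but ranked on the unrounded
rate with competition ranking; countries whose rounded rates tie share a
rank-range label (e.g. "13/14"). The shipped prisoner table covers the
20 most-published countries (average prisoner population 2000-2020);
countries absent from it are excluded with a warning.
`pearson_correlation()` is provided for the publication-volume versus
prisoner-population association.

```{r ranking}
top <- readr::read_tsv(system.file("extdata", "tables", "top_countries.tsv",
                                   package = "jhminer"),
                       show_col_types = FALSE)
country_ranking(tibble(nationality = top$nationality, n = top$articles)) |>
  select(country, n, crude_rank, rate, rate_rank) |>
  head(5)
```

## The synthetic corpus

Because no annotated corpus ships with the package, `generate_corpus()`
builds abstracts with known gold: template sentences whose slots draw
surfaces from the shipped dictionaries and whose age expressions
instantiate the shipped numeric grammar. Defaults emulate the observed
reporting rates in the justice health literature — each characteristic
is included by an independent Bernoulli draw with probability 0.149
(age), 0.237 (sex), 0.276 (nationality), 0.139 (offender type) — over
publication years 1990-2023. Everything is deterministic under a fixed
seed. Gold is recorded at the standardized level (the evaluation unit),
not the span level.

The generator samples only characteristic-unambiguous surfaces (it never
plants "boys", which is both a sex and an age term), so on noise-free
text the pipeline recovers the gold exactly — precision and recall are
100% for all four characteristics by construction. This is a regression
gate, not a performance claim: synthetic text has none of the
paraphrase variety, unseen syntax, misspellings or irrelevant-context
mentions of real abstracts, so real-corpus performance is strictly
worse and must be measured against human annotation (the published
evaluation of this method ran at 83-95% recall and 91-100% precision
per characteristic on 100 held-out abstracts).

`inject_noise()` emulates the dominant real-text failure mode:
misspellings that do not trigger the rules. Each planted span is
corrupted with a given probability by length-preserving word scrambles —
including rule anchors like "aged" and "years", so no partial numeric
pattern survives to mis-parse — while gold stays fixed. The expected
effect, asserted in the test suite at corruption probability 0.2 on age
mentions over 1000 abstracts, is recall loss with precision intact.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on 1000
synthetic abstracts (seeded), the oracle-equivalence properties on 100
randomized small fixtures, and the published-table arithmetic on the
printed counts directly; the whole suite completes in about a minute on
one core. Character offsets are 0-based half-open throughout.
Truncation and half-up rounding use a 1e-9 epsilon to absorb binary
floating-point artefacts (93.1 stored as 93.0999...). Ties in
dictionary matching break leftmost, then by dictionary precedence;
rule output order is deterministic (start offset, then rule id), so
identical inputs give byte-identical results.

## Known limitations

* Seed dictionaries and ~20 starter rules, not the full engineered
  artifact behind the published corpus study; absolute mention counts on
  real corpora will differ until users grow the data files.
* No negation, hedging or context filtering: ethnicity mentions
  ("Mexican-American") and comparative references ("as in the British
  study") produce false positives by design.
* No misspelling tolerance; no sentence segmentation; no inference
  beyond the dictionaries (e.g. "mothers" does not imply female, and
  generic "offenders" does not imply adults).
* The retrieval query ships as documentation (`pubmed_query()`); live
  PubMed querying is out of scope.
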