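# jhminer

Rule-based extraction of population characteristics — **age, sex,
nationality and offender type** — from bibliographic abstracts in
justice health / epidemiological criminology, with abstract-level
evaluation and research-gap analytics.

Research on offending and incarcerated populations is indexed in
bibliographic databases, but *who* was studied is buried in free-text
abstracts. `jhminer` recovers it with a transparent, trainable-data-free
method: gazetteer dictionaries (offenses, sex terms, nationalities,
geography, population descriptors) combined with semifrozen lexical
patterns — rules that mix literal anchors, regular-expression anchors
and dictionary slots, e.g. `characteristics of <offense> in` matching
"characteristics of **sex offenders** in Norway". Raw mentions are
standardized into closed category systems:

* **Age**: Australian Bureau of Statistics groups — minors (<18), 18-24,
  25-34, 35-44, 45-54, 55-64, 65+, plus *unknown adult*; numeric ranges
  map to every group they overlap ("aged 18-25" → {18-24, 25-34}).
* **Sex**: male, female, transgender, transgender man, transgender woman.
* **Nationality**: canonical demonyms; US subdivisions → "American";
  defunct identities → "miscellaneous".
* **Offender type**: a two-level taxonomy — seven categories (child
  crime-related, sex, violent, nonviolent, mentally ill, drug-related,
  miscellaneous) with an optional specific attribute ("serial rapists" →
  sex offender / rape).

Evaluation is at the abstract level over distinct standardized values:
per characteristic, TP = |gold ∩ predicted|, FP = |predicted \ gold|,
FN = |gold \ predicted|, with precision = 100·TP/(TP+FP),
recall = 100·TP/(TP+FN), F1 their harmonic mean, plus macro (mean of
per-class percentages) and micro (pooled counts) summaries. Analytics
cover characteristic coverage, age/offender distributions, yearly
female-only/male-only proportions, and country rankings both crude and
adjusted as articles per 1000 prisoners.

## Worked example

```r
library(jhminer)
library(dplyr)

corpus <- tibble(pmid = "ex1", year = 2020L, title = NA_character_,
  text = "Characteristics of sex offenders in Norway: women aged 18 to 25 years were interviewed.",
  language = "eng")
extract_characteristics(corpus)
#> # A tibble: 5 × 4
#>   pmid  characteristic value     attribute
#>   <chr> <chr>          <chr>     <chr>
#> 1 ex1   AGE            18-24     <NA>
#> 2 ex1   AGE            25-34     <NA>
#> 3 ex1   NATIONALITY    Norwegian <NA>
#> 4 ex1   OFFENDER_TYPE  sex       <NA>
#> 5 ex1   SEX            female    <NA>
```

One abstract produced five standardized values: the age range 18-25
overlaps two age groups, "Norway" standardizes to the demonym
Norwegian, "sex offenders" is the generic sex-offender category (no
specific attribute), and "women" gives the female sex category.

Metric arithmetic on abstract-level counts (54 true positives, 0 false
positives, 4 false negatives):

```r
compute_metrics(tibble(characteristic = "SEX", tp = 54L, fp = 0L, fn = 4L))
#> # A tibble: 1 × 7
#>   characteristic    tp    fp    fn precision recall    f1
#> 1 SEX               54     0     4       100   93.1  96.4
```

End-to-end self-check on a synthetic corpus with known gold
annotations:

```r
synth <- generate_corpus(200, seed = 1)          # known gold, seeded
pred  <- extract_characteristics(synth$corpus)
evaluate_extraction(pred, synth$gold, pmids = synth$corpus$pmid)
#> Abstract-level extraction evaluation
#> # A tibble: 4 × 7
#>   characteristic    tp    fp    fn precision recall    f1
#> 1 AGE               59     0     0       100    100   100
#> 2 SEX               69     0     0       100    100   100
#> 3 NATIONALITY       52     0     0       100    100   100
#> 4 OFFENDER_TYPE     34     0     0       100    100   100
#> macro: P=100.0 R=100.0 F1=100.0 | micro: P=100.0 R=100.0 F1=100.0
```

Perfect scores here are a recoverability gate of the generator, not a
real-world performance claim — see the methods vignette
(`vignettes/methods.Rmd`) for what synthetic text does and does not
show. Population-adjusted publication rates:

```r
rate_per_1000(c(138, 261), c(3289, 6510))   # Norway, Sweden
#> [1] 42.0 40.1
```

A shell workflow (`simulate` / `extract` / `evaluate` / `aggregate`)
over the same functions is installed at
`system.file("cli", "jhminer.R", package = "jhminer")`.

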