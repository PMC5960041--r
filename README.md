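# termtrends

Temporal terminology-trend analysis for conference abstract corpora.

Scientific language changes: "AIDS carrier" gives way to "person living
with HIV", "prostitute" to "sex worker", "drug addict" to "person who uses
drugs". `termtrends` quantifies such shifts in a recurring conference's
abstract archive. It is written for health-communication researchers,
medical librarians, and anyone text-mining an abstract collection who needs
defensible per-year frequency metrics for a curated vocabulary rather than
ad-hoc keyword greps.

The pipeline:

1. **Ingest** a delimited table of abstracts (id, conference year, text),
   strip markup and HTML entities, and drop exact duplicate abstracts
   within each year.
2. **Normalize** the text: symbol mapping (`HIV+` → "hiv positive") before
   tokenization, diacritic transliteration, lowercasing, hyphen splitting,
   digit-token removal. Two token streams come out: a *matching* stream
   that keeps every word (so "men who have sex with men" stays matchable
   and vocabulary sizes count all words) and a *discovery* stream with stop
   words removed.
3. **Discover** candidate terms: rank unigrams by abstract-level document
   frequency, apply an inclusive threshold (DF ≥ 100 by convention) plus
   curator include/exclude lists, and expand key unigrams into 2–6-word
   n-gram candidates that never cross sentence boundaries.
4. **Count** a validated terminology corpus — canonical terms with
   variants and acronyms in mutually exclusive categories — with a greedy
   longest-match scanner that consumes matched tokens, so nested terms
   ("antiretroviral therapy" inside "highly active antiretroviral
   therapy") never double-count.
5. **Measure** per (term *T*, conference year *Y*):

   - absolute TF: total occurrences of *T* in year *Y*;
   - TF(T, Y) = absolute TF / vocabulary size of *Y* (total words in all
     of the year's abstracts);
   - relTF = TF × 10⁶ (occurrences per million words);
   - abstract-level DF (abstracts of *Y* containing *T*) and
     conference-year DF(T) ∈ {0, …, N} (years containing *T*);
   - IDF(T) = log(1 + N / DF(T)), natural log by default;
   - TF-IDF(T, Y) = TF × IDF, the word-cloud weight;
   - a trailing 3-conference moving average of relTF,
     MA(t) = (X(t−2) + X(t−1) + X(t)) / 3.

6. **Report** tidy trend tables, word-cloud weights, term lifespans
   (first/last/peak year, active spans), ggplot trend lines and a
   deterministic word-cloud rendering.

A synthetic-corpus generator (`synthetic_spec()` / `generate_corpus()`)
plants multiword terms at known per-year counts inside Zipf-distributed
background text and returns the exact ground truth, so every stage of the
pipeline is testable without any proprietary data.

## Worked example

Sixteen synthetic conference years (annual 1989–1994, then biennial
through 2014), 200 abstracts per year, eight planted terms with rising,
falling, late-onset and single-year trajectories:

```r
library(termtrends)
library(dplyr)

corp <- generate_corpus(synthetic_spec(), seed = 42)
fit  <- analyze_terms(corp$abstracts, corp$terms)
fit
#> <term_trend_analysis>
#>   conference years: 16 (1989-2014)
#>   abstracts:        3200
#>   total words:      485236
#>   terms tracked:    8 in 5 categories
#>   most frequent:    aids patient (496), hiv epidemic (496), aids epidemic (320)

tidy(fit) |>
  filter(term == "hiv epidemic", year >= 2008) |>
  select(term, year, absolute_tf, reltf, year_df, idf, tfidf, reltf_ma3)
#> # A tibble: 4 × 8
#>   term          year absolute_tf reltf year_df   idf   tfidf reltf_ma3
#>   <chr>        <int>       <int> <dbl>   <int> <dbl>   <dbl>     <dbl>
#> 1 hiv epidemic  2008          48 1570.      16 0.693 0.00109     1468.
#> 2 hiv epidemic  2010          52 1693.      16 0.693 0.00117     1581.
#> 3 hiv epidemic  2012          56 1855.      16 0.693 0.00129     1706.
#> 4 hiv epidemic  2014          60 1974.      16 0.693 0.00137     1841.
```

Read: in 2014 "hiv epidemic" occurred 60 times, about 1,974 times per
million words; it appears in all 16 years, so its IDF is log 2 ≈ 0.693,
and the moving average smooths the rise to 1,841. Lifespans and word-cloud
weights come from the same table:

```r
term_lifespan(tidy(fit), "drug holiday")
#> # A tibble: 1 × 6
#>   term         first_year last_year peak_year n_active_years active_spans
#> 1 drug holiday       2000      2000      2000              1 <tibble [1 × 2]>

wordcloud_weights(tidy(fit), "living with hiv", 2014)
#> # A tibble: 3 × 4
#>    year category        term                      weight
#> 1  2014 living with hiv people living with hiv 0.00148
#> 2  2014 living with hiv aids carrier           0.0000912
#> 3  2014 living with hiv aids patient           0.0000456

autoplot(fit)                       # trend lines, faceted by category
plot_wordcloud(wordcloud_weights(tidy(fit), "living with hiv", 2014))
```

For real data, start from `read_abstract_table()` and a curated terminology
file (`read_terminology()`; see `default_terminology()` for a small example
corpus of HIV-related terms and the CSV/YAML layout it expects).

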