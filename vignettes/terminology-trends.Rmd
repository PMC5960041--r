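---
title: "Measuring terminology change across conference years"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring terminology change across conference years}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(termtrends)
library(dplyr)
```

## The measurement model

`termtrends` treats each conference year as a document. For a curated term
$T$ and year $Y$ with $N$ conference years in total:

$$\mathrm{TF}(T,Y) = \frac{\text{absolute TF}(T,Y)}{\text{vocabulary size}(Y)},
\qquad \mathrm{relTF} = \mathrm{TF} \times 10^6,$$

where the *vocabulary size* is the total count of all words in all of the
year's abstracts, stop words included. Absolute TF is the exact number of
non-overlapping occurrences of any of $T$'s surface forms (variants,
plurals, acronyms).

$$\mathrm{IDF}(T) = \log\!\left(1 + \frac{N}{\mathrm{DF}(T)}\right),
\qquad \mathrm{TFIDF}(T,Y) = \mathrm{TF}(T,Y)\times\mathrm{IDF}(T),$$

with $\mathrm{DF}(T) \in \{1,\dots,N\}$ the number of conference years in
which $T$ appears in at least one abstract. IDF is bounded between
$\log 2$ (a term present every year) and $\log(1+N)$ (a term confined to
one year): the word-cloud weight TF-IDF therefore favors terms that are
both frequent within a year and specific to few years. Trend lines are
smoothed with a trailing mean over three consecutive conference
*occurrences*,

$$\mathrm{MA}(t) = \tfrac{1}{3}\left(X(t-2) + X(t-1) + X(t)\right),$$

undefined for the first two occurrences. Indexing by occurrence rather
than calendar year matters when a conference moves from annual to biennial
scheduling: the window always spans three meetings, not a fixed number of
calendar years.

Assumptions worth stating plainly: terms are surface strings, not senses —
no disambiguation is attempted, so a term whose meaning drifts is counted
the same throughout; the year is the unit of analysis, so within-year
temporal structure is invisible; and the terminology corpus is an *input*
reflecting curator judgment, not something the package infers.

## Two token streams

Counting and discovery pull in opposite directions. Multiword terms such
as "men who have sex with men" contain function words, and the TF
denominator is defined over *all* words — so matching and vocabulary
counts must keep stop words. Unigram discovery, by contrast, would be
swamped by function words. The package therefore carries two parallel
streams per abstract: the **matching stream** (every word, used by the
scanner and `year_summary()`) and the **discovery stream** (stop words
removed, used by `unigram_stats()`). The discovery stream is by
construction a subsequence of the matching stream.

## The matcher

`count_term_occurrences()` scans the matching stream left to right; at
each position the longest surface form in the terminology wins and its
tokens are consumed. Consumption is the substantive choice: without it, a
single occurrence of "highly active antiretroviral therapy" would also
increment "antiretroviral therapy", and one text span would feed two trend
lines. Equal-length ties cannot arise between *different* canonical terms
because validation rejects any surface form claimed twice (the ambiguous
acronym problem — one abbreviation expanding to two unrelated phrases — is
resolved by the curator, never by the matcher). Acronyms are single
tokens; inside a longer matched phrase they are consumed and cannot fire.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| discovery DF threshold | 100 abstracts | conventional screening cut for "worth a curator's look"; inclusive (`>=`) |
| n-gram `max_n` | 6 words | long enough for "men who have sex with men"; windows stay inside sentences |
| IDF log base | natural | a display choice only — change of base rescales all IDFs by a constant, so ranking and trend shapes are invariant; base 10 available |
| moving-average window | 3 occurrences | short enough to keep turning points, long enough to damp single-meeting noise |
| lifespan activity threshold | relTF > 0 | "appears at all"; raise it to formalize "rarely used" |
| plural expansion | on | term variants gain plural surface forms at load time, so plural mentions are not undercounted |

The preprocessing assets (stop-word list, symbol map, plural exceptions)
ship as a YAML config and are fully overridable; the defaults are a small
English function-word list, mappings such as `HIV+` → "hiv positive", and
s-final exception words (`aids`, `msm`, irregulars like `men`) that a
trailing-s rule must never touch.

## Numerical and degenerate-input choices

- **Singularization rules.** Suffix rules only: `-ies` → `-y`;
  `-sses`/`-xes`/`-ches`/`-shes`/`-zes` drop `es`; otherwise a trailing
  `s` is dropped for words longer than three letters. The trailing-s rule
  is guarded against `-ss`, `-us`, `-is` endings: those are usually not
  plural markers ("virus", "analysis"), and the guard makes every branch
  idempotent — applying the rule to its own output changes nothing, so
  repeated normalization is safe. The cost is an occasional rough form on
  irregular Greek/Latin plurals ("crises" → "crise"); a deliberate
  simplicity-over-coverage trade for a matcher whose variants are curated
  anyway.
- **Digit-bearing tokens** are dropped entirely (not just pure numbers):
  keeping "cd4" would violate the digit-free token contract, and
  truncating it to "cd" would alter a word, which cleaning promises never
  to do.
- **Hyphenated forms** split into constituent tokens and terminology
  surfaces are stored hyphen-free, so "pre-exposure prophylaxis" and "pre
  exposure prophylaxis" are one surface.
- **Duplicate abstracts** are exact normalized-text matches *within* a
  conference year; identical texts in different years are plausible
  resubmissions and are kept. Only exact duplicates are removed —
  near-duplicate detection is out of scope and would need a similarity
  threshold the data cannot justify on its own.
- **Degenerate inputs.** A year with abstracts always has a positive
  vocabulary size, so TF never divides by zero; a term never observed has
  undefined IDF and is reported with `idf = NA`, `tfidf = 0` plus a
  warning, keeping the metrics table complete so trend lines stay
  continuous; series shorter than the smoothing window are all-`NA` with
  a warning; unknown HTML entities are left verbatim and reported rather
  than guessed at.
- **Unknown-category / unknown-term requests** error immediately rather
  than returning empty tables: silently empty trend data is how typos
  become findings.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` builds corpora with the *statistical* shape of a
multi-year conference archive: 16 conference years with annual-then-
biennial spacing, a Zipf-distributed background vocabulary (exponent 1,
the classic rank-frequency law for text), Poisson-length abstracts, and
multiword terms planted either at exact per-year counts or as Poisson
draws per abstract. Planted phrases use a reserved word alphabet disjoint
from the generated background (validated, not assumed), and insertions
happen simultaneously at token gaps, so every planted occurrence is
contiguous and non-overlapping. The ground truth records *realized*
counts — in Poisson mode the draws, not the rates — so it always describes
the emitted corpus.

The default scale is 16 years × 200 abstracts × 150 words (about half a
million words, processed in seconds); `paper_scale_spec()` scales to
thousands of abstracts per year, putting per-year vocabulary sizes in the
10⁵–10⁶ range typical of a large conference archive. These sizes were
chosen as the package's standard study conditions: large enough that
rates and ratios are stable, small enough to iterate on.

Passing tests on this corpus shows that counting, aggregation and every
metric formula are exact, and that the longest-match rule resolves nested
plants correctly. It does *not* show robustness to what real abstracts
contain and the generator deliberately omits: natural-language syntax,
topical correlation between terms and context, OCR noise, British/American
spelling variation, near-duplicate resubmissions with minor edits, and
genuinely ambiguous surface forms. Those must be addressed by curation of
the terminology file and by the configurable cleaning assets, and results
on real data inherit the quality of that curation.

The desk-scale two-term scenario (`table1_scenario()`) deserves a note:
absolute frequencies (7 vs 1, then 1 vs 2) are planted in a *shared* token
pool per year, so the within-year TF ratio equals the count ratio exactly,
whatever the pool size. This denominator cancellation is what makes the
scenario meaningful at desk scale — within-year ratios are invariant to
scaling the corpus down, while raw TF values of course are not.

## Design decisions that were genuinely open

- **Deduplication scope** (per-year, exact match): cross-year repeats are
  legitimate; "duplicate" is otherwise undefined without a similarity
  model.
- **TF denominator** on the matching stream (all words): the definition of
  vocabulary size as "all words" forces this; a stop-word-filtered
  denominator is available as a configuration for sensitivity analysis,
  and within-year TF *ratios* are identical under either choice.
- **Intermediate persistence** as line-delimited JSON: diffable,
  streamable, and a faithful one-record-per-abstract store without a
  database dependency.
- **Expert judgment as data**: the discovery threshold's include/exclude
  lists are inputs, because relevance judgments are the curator's, not
  the code's.
- **No CLI**: the package's users work in R; the exported functions, this
  vignette and `scripts/acceptance.R` are the entry points.
- **Peak ties → earliest year**; candidate ordering by descending
  document frequency then lexicographic — every output ordering is
  deterministic so runs are comparable.

## Known limitations

Exact surface matching only (no fuzzy matching, no sense disambiguation);
Latin-script text only; the shipped HIV terminology file is a small
reconstruction of published category examples, intended as a demonstration
corpus rather than a complete curated instrument; and statistical
significance of trends is out of scope — the package reports frequencies,
not hypothesis tests.

## A compact end-to-end run

```{r example, fig.width = 7, fig.height = 4}
corp <- generate_corpus(synthetic_spec(), seed = 42)
fit <- analyze_terms(corp$abstracts, corp$terms)
glance(fit)

tidy(fit) |>
  filter(year == 2014, absolute_tf > 0) |>
  select(term, category, absolute_tf, reltf, tfidf)

autoplot(fit)
```

Every number above is recomputed at run time; the recovery checks in the
test suite verify that the counts equal the generator's planted ground
truth exactly.
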