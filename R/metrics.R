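#' Per-year vocabulary size and abstract count
#'
#' The vocabulary size of a conference year is the total count of *all*
#' words (matching stream, stop words retained) over all abstracts of that
#' year. It is the denominator of the term-frequency normalization, so terms
#' from verbose years are not overweighted simply because more was written.
#'
#' @param tokens Token tibble from [tokenize_abstracts()].
#' @param stream Which token stream to count: `"matching"` (default, all
#'   words — the standard denominator) or `"discovery"` (stop words
#'   removed), kept as an option for sensitivity analyses. Within-year TF
#'   ratios are identical under either choice.
#' @return Tibble `year`, `n_abstracts`, `vocabulary_size`, sorted by year.
#' @export
year_summary <- function(tokens, stream = c("matching", "discovery")) {
  check_tokens(tokens)
  stream <- match.arg(stream)
  if (nrow(tokens) == 0) abort("empty corpus")
  tokens |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_abstracts = dplyr::n(),
      vocabulary_size = sum(lengths(.data[[stream]])),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year)
}

#' Term frequency and relative term frequency
#'
#' `tf = absolute_tf / vocabulary_size`: the share of a year's words taken
#' by the term. `reltf = tf * 1e6`: the number of occurrences expected in a
#' document of one million words, the unit used for trend lines.
#'
#' @param absolute_tf Non-negative integer vector of per-year term counts.
#' @param vocabulary_size Positive integer vector (recycled) of per-year
#'   total word counts.
#' @return Tibble with columns `tf` and `reltf`.
#' @examples
#' term_frequency(30, 600)  # tf 0.05, reltf 50000
#' @export
term_frequency <- function(absolute_tf, vocabulary_size) {
  if (any(vocabulary_size <= 0)) {
    abort("vocabulary_size must be positive (a year with abstracts has words)")
  }
  if (any(absolute_tf < 0) || any(absolute_tf > vocabulary_size)) {
    abort("absolute_tf must lie in [0, vocabulary_size]")
  }
  tf <- absolute_tf / vocabulary_size
  tibble(tf = tf, reltf = tf * 1e6)
}

#' Conference-year document frequency of each term
#'
#' Counts, for every term, the number of conference years in which it
#' appears in at least one abstract — the input to the inverse document
#' frequency. All abstracts of a year count as a single document here, so
#' the value ranges from 0 (never seen) to the number of conference years.
#'
#' @param agg Tibble from [aggregate_counts()] (zero-filled per term-year).
#' @return Tibble `term`, `year_df`.
#' @export
year_document_frequency <- function(agg) {
  agg |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(year_df = sum(.data$abstract_df >= 1L), .groups = "drop")
}

#' Inverse document frequency over conference years
#'
#' `idf = log(1 + N / df)` with `N` the number of conference years and `df`
#' the term's conference-year document frequency. A term present every year
#' gets `log(2)`; a term confined to a single year gets `log(1 + N)` — rare,
#' year-specific terms are upweighted. The logarithm base is a display
#' choice (natural by default, base 10 available); trends are unaffected
#' because the change of base is a monotone rescaling.
#'
#' @param df Integer vector of conference-year document frequencies, each in
#'   `0..n_years`. Zeros yield `NA` with a warning (a never-seen term has no
#'   meaningful idf; its tf is zero everywhere anyway).
#' @param n_years Number of conference years `N` (scalar, >= 1).
#' @param log_base `"e"` (default) or `"10"`.
#' @return Numeric vector of idf values.
#' @examples
#' inverse_document_frequency(16, 16)  # log(2)
#' inverse_document_frequency(1, 16)   # log(17)
#' @export
inverse_document_frequency <- function(df, n_years, log_base = c("e", "10")) {
  log_base <- match.arg(as.character(log_base), c("e", "10"))
  stopifnot(length(n_years) == 1, n_years >= 1)
  if (any(df < 0 | df > n_years)) {
    abort("df must lie in [0, n_years]")
  }
  out <- rep(NA_real_, length(df))
  pos <- df >= 1
  if (any(!pos)) {
    warn("idf undefined for terms with conference-year df 0; returning NA")
  }
  base_log <- if (log_base == "10") log10 else log
  out[pos] <- base_log(1 + n_years / df[pos])
  out
}

#' TF-IDF per term and conference year
#'
#' The plain product of the year's term frequency and the term's inverse
#' document frequency — the weight used for word clouds, where it surfaces
#' terms that are both frequent in the year and concentrated in few years.
#'
#' @param tf,idf Numeric vectors (recycled to common length).
#' @return Numeric vector `tf * idf`.
#' @export
tf_idf <- function(tf, idf) {
  stopifnot(all(tf >= 0, na.rm = TRUE))
  tf * idf
}

#' Trailing three-point moving average
#'
#' Smooths a series over overlapping windows of three consecutive conference
#' occurrences: `smoothed[t] = (x[t-2] + x[t-1] + x[t]) / 3`. The first two
#' positions have no full window and are reported as `NA`. Positions index
#' conference occurrences, not calendar years, because conference spacing
#' may be uneven (annual meetings moving to biennial ones).
#'
#' @param x Numeric vector ordered by conference occurrence.
#' @param window Window length (default 3).
#' @return Numeric vector of the same length; first `window - 1` values `NA`.
#'   A series shorter than the window is all-`NA` with a warning.
#' @examples
#' moving_average(c(3, 6, 9))  # NA NA 6
#' @export
moving_average <- function(x, window = 3L) {
  stopifnot(window >= 1)
  if (length(x) < window) {
    warn(paste0("series shorter than the smoothing window (", window,
                "); all smoothed values are NA"))
    return(rep(NA_real_, length(x)))
  }
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))
}

#' Assemble the full per term-year metrics table
#'
#' Joins the aggregated counts with the year summaries and computes every
#' frequency metric in one tidy table: one row per (canonical term,
#' conference year), zero-filled so trend lines are continuous.
#'
#' @param agg Tibble from [aggregate_counts()].
#' @param years_summary Tibble from [year_summary()].
#' @param terms The [terminology()] object (supplies categories).
#' @param log_base Passed to [inverse_document_frequency()].
#' @return Tibble with columns `term`, `category`, `year`, `absolute_tf`,
#'   `tf`, `reltf`, `abstract_df`, `year_df`, `idf`, `tfidf`, `reltf_ma3`,
#'   sorted by term then year. Terms never observed get `idf` `NA` and
#'   `tfidf` 0 (with a warning), keeping the table complete.
#' @export
compute_metrics <- function(agg, years_summary, terms, log_base = "e") {
  stopifnot(inherits(terms, "terminology"))
  n_years <- nrow(years_summary)
  ydf <- year_document_frequency(agg)

  out <- agg |>
    dplyr::left_join(years_summary[, c("year", "vocabulary_size")], by = "year") |>
    dplyr::left_join(ydf, by = "term") |>
    dplyr::left_join(terms$entries, by = c("term" = "canonical")) |>
    dplyr::rename(category = "category")
  if (any(is.na(out$vocabulary_size))) {
    abort("aggregate rows reference a year absent from year_summary()")
  }
  freqs <- term_frequency(out$absolute_tf, out$vocabulary_size)
  out$tf <- freqs$tf
  out$reltf <- freqs$reltf
  out$idf <- suppressWarnings(
    inverse_document_frequency(out$year_df, n_years, log_base)
  )
  if (any(out$year_df == 0)) {
    warn("term(s) with conference-year df 0: idf NA, tfidf set to 0")
  }
  out$tfidf <- ifelse(out$year_df == 0, 0, tf_idf(out$tf, out$idf))
  out <- out |>
    dplyr::arrange(.data$term, .data$year) |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(reltf_ma3 = suppressWarnings(moving_average(.data$reltf))) |>
    dplyr::ungroup()
  out[, c("term", "category", "year", "absolute_tf", "tf", "reltf",
          "abstract_df", "year_df", "idf", "tfidf", "reltf_ma3")]
}
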