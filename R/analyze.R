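#' Run the full terminology-trend pipeline
#'
#' One call from a raw abstract table to the complete metrics table:
#' cleaning, per-year deduplication, symbol mapping, tokenization, exact
#' longest-match term counting, aggregation, and every frequency metric
#' (absolute TF, TF, relTF, abstract- and year-level document frequency,
#' IDF, TF-IDF, three-point moving average).
#'
#' @param abstracts Tibble with columns `id`, `year`, `text` (e.g. from
#'   [read_abstract_table()] or [generate_corpus()]).
#' @param terms A [terminology()] object.
#' @param config A [preprocess_config()].
#' @param log_base `"e"` (default) or `"10"` for the IDF logarithm.
#' @param clean,dedupe Apply [clean_abstracts()] / [deduplicate()] first
#'   (defaults `TRUE`).
#'
#' @return An object of class `term_trend_analysis`, a list with
#'   * `metrics`: the tidy per term-year metrics table (see
#'     [compute_metrics()]);
#'   * `year_summary`: per-year abstract counts and vocabulary sizes;
#'   * `counts`: nonzero per-abstract term counts;
#'   * `terms`: the terminology used;
#'   * `context`: `years`, `n_years`, `log_base`.
#'   Use [generics::tidy()] for the metrics table, [generics::glance()] for
#'   a one-row summary, [ggplot2::autoplot()] for trend lines.
#'
#' @examples
#' corp <- table1_scenario(seed = 1)
#' fit <- analyze_terms(corp$abstracts, corp$terms)
#' glance(fit)
#' head(tidy(fit))
#' @export
analyze_terms <- function(abstracts, terms, config = preprocess_config(),
                          log_base = "e", clean = TRUE, dedupe = TRUE) {
  check_abstracts(abstracts)
  stopifnot(inherits(terms, "terminology"))
  if (clean) abstracts <- clean_abstracts(abstracts)
  if (dedupe) abstracts <- deduplicate(abstracts)
  tokens <- tokenize_abstracts(abstracts, config)
  ys <- year_summary(tokens)
  counts <- count_term_occurrences(tokens, terms)
  agg <- aggregate_counts(counts, terms, ys$year)
  metrics <- compute_metrics(agg, ys, terms, log_base = log_base)
  structure(
    list(
      metrics = metrics,
      year_summary = ys,
      counts = counts,
      terms = terms,
      context = list(years = ys$year, n_years = nrow(ys),
                     log_base = log_base)
    ),
    class = "term_trend_analysis"
  )
}

#' @export
print.term_trend_analysis <- function(x, ...) {
  cat("<term_trend_analysis>\n")
  cat("  conference years:", x$context$n_years,
      paste0("(", min(x$context$years), "-", max(x$context$years), ")"), "\n")
  cat("  abstracts:       ", sum(x$year_summary$n_abstracts), "\n")
  cat("  total words:     ", sum(x$year_summary$vocabulary_size), "\n")
  cat("  terms tracked:   ", nrow(x$terms$entries), "in",
      length(x$terms$categories), "categories\n")
  top <- x$metrics |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(total = sum(.data$absolute_tf), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total)) |>
    head(3)
  cat("  most frequent:   ",
      paste(sprintf("%s (%d)", top$term, top$total), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the per term-year metrics of a fitted trend analysis
#'
#' @param x A `term_trend_analysis` from [analyze_terms()].
#' @param ... Unused.
#' @return The tidy metrics tibble, one row per (term, conference year).
#' @exportS3Method generics::tidy
tidy.term_trend_analysis <- function(x, ...) {
  x$metrics
}

#' One-row summary of a fitted trend analysis
#'
#' @param x A `term_trend_analysis` from [analyze_terms()].
#' @param ... Unused.
#' @return A one-row tibble: `n_years`, `n_abstracts`, `total_words`,
#'   `n_terms`, `n_categories`, `n_active_terms` (terms seen at least once),
#'   `log_base`.
#' @exportS3Method generics::glance
glance.term_trend_analysis <- function(x, ...) {
  active <- x$metrics |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(seen = any(.data$absolute_tf > 0), .groups = "drop")
  tibble(
    n_years = x$context$n_years,
    n_abstracts = sum(x$year_summary$n_abstracts),
    total_words = sum(x$year_summary$vocabulary_size),
    n_terms = nrow(x$terms$entries),
    n_categories = length(x$terms$categories),
    n_active_terms = sum(active$seen),
    log_base = x$context$log_base
  )
}

#' Trend-line plot of a fitted trend analysis
#'
#' @param object A `term_trend_analysis` from [analyze_terms()].
#' @param categories,smoothed Passed to [plot_trends()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.term_trend_analysis <- function(object, categories = NULL,
                                         smoothed = FALSE, ...) {
  plot_trends(object$metrics, categories = categories, smoothed = smoothed)
}

#' Write the metrics table as tidy CSV
#'
#' @param x A `term_trend_analysis` or a metrics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  metrics <- if (inherits(x, "term_trend_analysis")) x$metrics else x
  check_metrics(metrics)
  readr::write_csv(metrics, path, progress = FALSE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
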