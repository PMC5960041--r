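#' Plot-ready trend table of relative term frequencies
#'
#' Extracts the line-graph data from a metrics table: one row per (term,
#' conference year) with the relative term frequency and its three-point
#' moving average, zero-filled over every corpus year and sorted canonically
#' by category, term, year — so the output is stable regardless of input row
#' order.
#'
#' @param metrics Metrics tibble from [compute_metrics()].
#' @param categories Optional character vector restricting the table to
#'   specific categories; an unknown category name is an error.
#' @return Tibble `category`, `term`, `year`, `reltf`, `reltf_ma3`.
#' @export
build_trend_table <- function(metrics, categories = NULL) {
  check_metrics(metrics)
  if (!is.null(categories)) {
    unknown <- setdiff(categories, unique(metrics$category))
    if (length(unknown) > 0) {
      abort(paste0("unknown category name(s): ",
                   paste(unknown, collapse = ", ")))
    }
    metrics <- dplyr::filter(metrics, .data$category %in% categories)
  }
  metrics |>
    dplyr::select("category", "term", "year", "reltf", "reltf_ma3") |>
    dplyr::arrange(.data$category, .data$term, .data$year)
}

#' Word-cloud weights for one category and conference year
#'
#' Returns the TF-IDF weights that size the terms of one category in one
#' year's word cloud. Terms with zero TF-IDF (absent that year, or present
#' in every year of a degenerate corpus) are excluded: a weightless word has
#' no place in a cloud.
#'
#' @param metrics Metrics tibble from [compute_metrics()].
#' @param category Single category name.
#' @param year Single conference year; a year absent from the corpus is an
#'   error.
#' @return Tibble `year`, `category`, `term`, `weight` (tfidf, all > 0),
#'   sorted by descending weight then term.
#' @export
wordcloud_weights <- function(metrics, category, year) {
  check_metrics(metrics)
  stopifnot(length(category) == 1, length(year) == 1)
  if (!year %in% metrics$year) {
    abort(paste0("year ", year, " absent from the metrics table"))
  }
  if (!category %in% metrics$category) {
    abort(paste0("unknown category name: ", category))
  }
  metrics |>
    dplyr::filter(.data$category == !!category, .data$year == !!year,
                  .data$tfidf > 0) |>
    dplyr::transmute(year = .data$year, category = .data$category,
                     term = .data$term, weight = .data$tfidf) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$term)
}

#' Write word-cloud weights as JSON
#'
#' Serializes the output of [wordcloud_weights()] as
#' `{"year": ..., "category": ..., "weights": {term: value, ...}}`.
#'
#' @param weights Tibble from [wordcloud_weights()].
#' @param path Output path.
#' @param year,category Required when `weights` has no rows (an all-zero
#'   category-year still serializes, with an empty weights object).
#' @return `path`, invisibly.
#' @export
write_cloud_json <- function(weights, path, year = NULL, category = NULL) {
  yr <- if (nrow(weights) > 0) weights$year[1] else year
  cat_ <- if (nrow(weights) > 0) weights$category[1] else category
  if (is.null(yr) || is.null(cat_)) {
    abort("year and category must be supplied for an empty weights table")
  }
  obj <- list(
    year = as.integer(yr), category = as.character(cat_),
    weights = as.list(stats::setNames(weights$weight, weights$term))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Lifespan of a term across conference years
#'
#' Summarizes when a term was in active use: the first and last conference
#' years with activity, the peak year (maximum relative term frequency,
#' earliest year on ties), and the maximal runs of consecutive conference
#' occurrences with activity. "Active" means `reltf` strictly above
#' `threshold`; the default 0 counts any appearance, and raising the
#' threshold recovers statements like "rarely used before ...".
#'
#' @param metrics Metrics tibble from [compute_metrics()].
#' @param term Single canonical term; unknown terms are an error.
#' @param threshold Activity threshold on `reltf` (default 0).
#' @return One-row tibble `term`, `first_year`, `last_year`, `peak_year`,
#'   `n_active_years`, `active_spans` (list-column: tibble `start_year`,
#'   `end_year` per maximal run). A never-active term gets `NA` years and an
#'   empty span table.
#' @export
term_lifespan <- function(metrics, term, threshold = 0) {
  check_metrics(metrics)
  stopifnot(length(term) == 1)
  series <- metrics |>
    dplyr::filter(.data$term == !!term) |>
    dplyr::arrange(.data$year)
  if (nrow(series) == 0) {
    abort(paste0("unknown term: ", term))
  }
  active <- series$reltf > threshold
  if (!any(active)) {
    return(tibble(
      term = term, first_year = NA_integer_, last_year = NA_integer_,
      peak_year = NA_integer_, n_active_years = 0L,
      active_spans = list(tibble(start_year = integer(0),
                                 end_year = integer(0)))
    ))
  }
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  spans <- tibble(
    start_year = series$year[starts[runs$values]],
    end_year = series$year[ends[runs$values]]
  )
  tibble(
    term = term,
    first_year = series$year[which(active)[1]],
    last_year = series$year[max(which(active))],
    peak_year = series$year[which.max(series$reltf)],
    n_active_years = sum(active),
    active_spans = list(spans)
  )
}

#' Trend-line plot of relative term frequencies
#'
#' One line per term, faceted by category: the standard presentation for
#' watching terminology rise and fall across conference years.
#'
#' @param metrics Metrics tibble from [compute_metrics()].
#' @param categories Optional category filter (see [build_trend_table()]).
#' @param smoothed Plot the three-point moving average instead of the raw
#'   relative term frequency (drops the first two conference occurrences).
#' @return A ggplot object.
#' @export
plot_trends <- function(metrics, categories = NULL, smoothed = FALSE) {
  tab <- build_trend_table(metrics, categories)
  yvar <- if (smoothed) "reltf_ma3" else "reltf"
  ylab <- if (smoothed) {
    "relative term frequency (per million words, 3-conference moving average)"
  } else {
    "relative term frequency (per million words)"
  }
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$year, y = .data[[yvar]], colour = .data$term
  )) +
    ggplot2::geom_line(na.rm = smoothed) +
    ggplot2::geom_point(size = 0.8, na.rm = smoothed) +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::labs(x = "conference year", y = ylab, colour = "term") +
    ggplot2::theme_minimal()
}

#' Static word-cloud rendering of TF-IDF weights
#'
#' A deterministic text plot in which term size encodes the TF-IDF weight.
#' Terms are laid out on a fixed spiral (heaviest at the center), so the
#' same weights always render identically.
#'
#' @param weights Tibble from [wordcloud_weights()].
#' @return A ggplot object.
#' @export
plot_wordcloud <- function(weights) {
  stopifnot(all(c("term", "weight") %in% names(weights)))
  n <- nrow(weights)
  if (n == 0) abort("no positive weights to plot")
  idx <- seq_len(n) - 1L
  lay <- tibble(
    term = weights$term,
    weight = weights$weight,
    x = sqrt(idx) * cos(idx * 2.39996),  # golden-angle spiral
    y = sqrt(idx) * sin(idx * 2.39996)
  )
  ggplot2::ggplot(lay, ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$term,
                                    size = .data$weight)) +
    ggplot2::geom_text(colour = "grey20", na.rm = TRUE) +
    ggplot2::scale_size_continuous(range = c(3, 10), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = if (all(c("category", "year") %in% names(weights)) && n > 0) {
        paste0(weights$category[1], ", ", weights$year[1])
      } else {
        NULL
      }
    )
}

check_metrics <- function(metrics) {
  needed <- c("term", "category", "year", "reltf", "reltf_ma3", "tfidf")
  if (!is.data.frame(metrics) || !all(needed %in% names(metrics))) {
    abort("expected a metrics tibble from compute_metrics()")
  }
  invisible(metrics)
}
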