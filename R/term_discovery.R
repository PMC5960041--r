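#' Per-year unigram counts and abstract-level document frequencies
#'
#' Tallies every distinct discovery-stream token (stop words removed) by
#' conference year: `absolute_count` is the total number of occurrences in
#' the year's abstracts, `abstract_df` the number of the year's abstracts
#' containing the token at least once — the quantity the discovery threshold
#' is applied to.
#'
#' @param tokens Token tibble from [tokenize_abstracts()].
#' @param years Optional integer vector restricting the tally to specific
#'   conference years; a requested year with no abstracts is an error.
#' @return Tibble with columns `year`, `token`, `absolute_count`,
#'   `abstract_df`, sorted by year, then descending `abstract_df`, then token.
#' @export
unigram_stats <- function(tokens, years = NULL) {
  check_tokens(tokens)
  if (!is.null(years)) {
    missing_years <- setdiff(as.integer(years), unique(tokens$year))
    if (length(missing_years) > 0) {
      abort(paste0("year(s) absent from corpus: ",
                   paste(missing_years, collapse = ", ")))
    }
    tokens <- dplyr::filter(tokens, .data$year %in% as.integer(years))
  }
  long <- tibble(
    id = rep(tokens$id, lengths(tokens$discovery)),
    year = rep(tokens$year, lengths(tokens$discovery)),
    token = unlist(tokens$discovery, use.names = FALSE)
  )
  long |>
    dplyr::group_by(.data$year, .data$token) |>
    dplyr::summarise(
      absolute_count = dplyr::n(),
      abstract_df = dplyr::n_distinct(.data$id),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year, dplyr::desc(.data$abstract_df), .data$token)
}

#' Select key unigrams by document-frequency threshold
#'
#' Keeps tokens whose abstract-level document frequency reaches `threshold`
#' in at least one conference year, then removes the `exclude` list and adds
#' the `include` list. The include/exclude lists model the subject-matter
#' expert's judgment — terms judged relevant despite low frequency (e.g.
#' `"holiday"` from "drug holiday") go on `include`; frequent but irrelevant
#' tokens go on `exclude`.
#'
#' @param stats Tibble from [unigram_stats()].
#' @param threshold Minimum abstract-level document frequency (default 100).
#' @param include,exclude Character vectors of tokens to force in / out.
#' @return Character vector of key unigrams in deterministic order:
#'   descending maximum document frequency across years, ties broken
#'   lexicographically; included tokens unseen in the corpus sort last.
#' @export
select_key_unigrams <- function(stats, threshold = 100,
                                include = character(0),
                                exclude = character(0)) {
  stopifnot(is.numeric(threshold), threshold >= 1)
  maxdf <- stats |>
    dplyr::group_by(.data$token) |>
    dplyr::summarise(max_df = max(.data$abstract_df), .groups = "drop")
  selected <- maxdf$token[maxdf$max_df >= threshold]
  selected <- setdiff(selected, exclude)
  selected <- union(selected, include)
  df_of <- stats::setNames(maxdf$max_df, maxdf$token)
  key_df <- ifelse(is.na(df_of[selected]), 0L, df_of[selected])
  selected[order(-key_df, selected)]
}

#' Expand key unigrams into n-gram candidates
#'
#' Enumerates every contiguous matching-stream window of 2 to `max_n` words
#' containing at least one key unigram, aggregating abstract-level document
#' frequency per conference year. Windows never cross sentence boundaries
#' (recorded during tokenization) or abstract boundaries: an n-gram spanning
#' two sentences is an artifact, not a term. This reproduces the move from
#' single key words like "therapy" to candidate phrases like "antiretroviral
#' therapy" and "combination antiretroviral therapy" that a reviewer then
#' curates into the terminology corpus.
#'
#' @param tokens Token tibble from [tokenize_abstracts()].
#' @param key_unigrams Character vector of seed words.
#' @param max_n Longest window, 2–6 (default 6, so phrases like
#'   "men who have sex with men" are representable).
#' @param min_df Reporting floor on per-year abstract document frequency
#'   (default 1 = report everything).
#' @return Tibble with columns `surface` (space-joined window), `seed`
#'   (first key unigram in the window), `n_words`, `year`, `abstract_df`,
#'   sorted by descending `abstract_df`, then surface, then year. Empty
#'   `key_unigrams` yields an empty result.
#' @export
expand_ngrams <- function(tokens, key_unigrams, max_n = 6, min_df = 1) {
  check_tokens(tokens)
  stopifnot(max_n >= 2, max_n <= 6, min_df >= 1)
  empty <- tibble(surface = character(0), seed = character(0),
                  n_words = integer(0), year = integer(0),
                  abstract_df = integer(0))
  if (length(key_unigrams) == 0) return(empty)
  key_set <- unique(key_unigrams)

  rows <- vector("list", nrow(tokens))
  for (i in seq_len(nrow(tokens))) {
    toks <- tokens$matching[[i]]
    if (length(toks) < 2 || !any(toks %in% key_set)) next
    ends <- tokens$sentence_breaks[[i]]
    if (length(ends) == 0) ends <- length(toks)
    starts <- c(1L, head(ends, -1L) + 1L)
    surfaces <- character(0)
    for (s in seq_along(starts)) {
      seg <- toks[starts[s]:ends[s]]
      L <- length(seg)
      if (L < 2) next
      iskey <- seg %in% key_set
      if (!any(iskey)) next
      for (n in 2:min(max_n, L)) {
        for (j in seq_len(L - n + 1L)) {
          if (any(iskey[j:(j + n - 1L)])) {
            surfaces <- c(surfaces, paste(seg[j:(j + n - 1L)], collapse = " "))
          }
        }
      }
    }
    if (length(surfaces) > 0) {
      rows[[i]] <- tibble(surface = unique(surfaces), year = tokens$year[i])
    }
  }
  per_abstract <- dplyr::bind_rows(rows)
  if (nrow(per_abstract) == 0) return(empty)

  out <- per_abstract |>
    dplyr::group_by(.data$surface, .data$year) |>
    dplyr::summarise(abstract_df = dplyr::n(), .groups = "drop")
  words <- stringr::str_split(out$surface, " ")
  out$n_words <- lengths(words)
  out$seed <- vapply(words, function(w) w[w %in% key_set][1], character(1))
  out |>
    dplyr::filter(.data$abstract_df >= min_df) |>
    dplyr::select("surface", "seed", "n_words", "year", "abstract_df") |>
    dplyr::arrange(dplyr::desc(.data$abstract_df), .data$surface, .data$year)
}

check_tokens <- function(tokens) {
  needed <- c("id", "year", "matching", "discovery", "sentence_breaks")
  if (!is.data.frame(tokens) || !all(needed %in% names(tokens))) {
    abort("expected a token tibble from tokenize_abstracts()")
  }
  invisible(tokens)
}
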