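#' Build a terminology corpus from a tibble
#'
#' A terminology corpus is the curated set of 1–6 word canonical terms, each
#' with optional surface variants (spelling variants, symbol-normalized
#' forms) and single-token acronyms, grouped into mutually exclusive
#' categories. Every surface form is normalized through the same pipeline as
#' the abstracts (symbol map, diacritic transliteration, lowercase,
#' hyphen splitting), so `"pre-exposure prophylaxis"` and
#' `"pre exposure prophylaxis"` collapse to one surface.
#'
#' @param entries Tibble (or data frame) with columns `canonical`,
#'   `category`, and optionally `variants` and `acronyms` (each a
#'   `|`-separated string or a list-column of character vectors).
#' @param config A [preprocess_config()] used to normalize surface forms.
#' @param expand_plurals Auto-generate plural surface variants for every
#'   variant via [pluralize()] on the final word (default `TRUE`), so the
#'   frequency metrics do not undercount plural mentions.
#'
#' @return An object of class `terminology`: a list with `entries` (tibble
#'   `canonical`, `category`), `surfaces` (tibble `surface`, `canonical`,
#'   `n_words`, `is_acronym`) and `categories` (character vector).
#'
#' @details Validation is strict and mirrors the corpus-curation rules:
#'   a canonical term listed under two categories is an error; a surface
#'   form (variant or acronym) claimed by two different canonical terms is
#'   an error naming both claimants — ambiguous acronyms (the classic case:
#'   one acronym expanding to two unrelated phrases) must be resolved by the
#'   curator, not guessed at by the matcher; purely numeric acronyms and
#'   empty variants are rejected.
#' @export
terminology <- function(entries, config = preprocess_config(),
                        expand_plurals = TRUE) {
  entries <- as_tibble(entries)
  if (!all(c("canonical", "category") %in% names(entries))) {
    abort("terminology entries need columns canonical and category")
  }
  split_bar <- function(col) {
    if (is.null(col)) return(rep(list(character(0)), nrow(entries)))
    if (is.list(col)) return(lapply(col, function(x) as.character(x[nzchar(x)])))
    lapply(stringr::str_split(dplyr::coalesce(as.character(col), ""), "\\|"),
           function(x) stringr::str_trim(x[nzchar(stringr::str_trim(x))]))
  }
  variants <- split_bar(entries[["variants"]])
  acronyms <- split_bar(entries[["acronyms"]])

  norm <- function(x) {
    toks <- tokenize_one(apply_symbol_map(x, config), character(0))$matching
    paste(toks, collapse = " ")
  }

  canon_raw <- as.character(entries$canonical)
  if (any(!nzchar(canon_raw))) abort("empty canonical term")
  canon <- vapply(canon_raw, norm, character(1), USE.NAMES = FALSE)
  nw <- lengths(stringr::str_split(canon, " "))
  if (any(nw < 1 | nw > 6)) {
    abort(paste0("canonical terms must be 1-6 words: ",
                 paste(canon[nw < 1 | nw > 6], collapse = "; ")))
  }

  dup_cat <- unique(canon[duplicated(canon)])
  if (length(dup_cat) > 0) {
    cats <- unique(entries$category[canon %in% dup_cat])
    abort(paste0(
      "canonical term(s) listed more than once (each term belongs to ",
      "exactly one category): ", paste(dup_cat, collapse = ", "),
      " [categories: ", paste(cats, collapse = ", "), "]"
    ))
  }

  surf_rows <- vector("list", length(canon))
  for (i in seq_along(canon)) {
    var_norm <- vapply(c(canon_raw[i], variants[[i]]), norm, character(1),
                       USE.NAMES = FALSE)
    if (any(!nzchar(var_norm))) {
      abort(paste0("empty variant for canonical term '", canon[i], "'"))
    }
    if (expand_plurals) {
      var_norm <- unique(c(var_norm, vapply(var_norm, function(v) {
        w <- stringr::str_split(v, " ")[[1]]
        w[length(w)] <- pluralize(w[length(w)], config)
        paste(w, collapse = " ")
      }, character(1), USE.NAMES = FALSE)))
    }
    acr_norm <- vapply(acronyms[[i]], norm, character(1), USE.NAMES = FALSE)
    if (any(stringr::str_detect(acronyms[[i]], "^[0-9]+$"))) {
      abort(paste0("purely numeric acronym for '", canon[i], "'"))
    }
    if (any(lengths(stringr::str_split(acr_norm, " ")) != 1)) {
      abort(paste0("acronyms must be single tokens: '", canon[i], "'"))
    }
    surf_rows[[i]] <- tibble(
      surface = c(unique(var_norm), unique(acr_norm)),
      canonical = canon[i],
      is_acronym = c(rep(FALSE, length(unique(var_norm))),
                     rep(TRUE, length(unique(acr_norm))))
    )
  }
  surfaces <- dplyr::bind_rows(surf_rows)
  if (nrow(surfaces) == 0) {
    surfaces <- tibble(surface = character(0), canonical = character(0),
                       is_acronym = logical(0))
  }
  surfaces$n_words <- lengths(stringr::str_split(surfaces$surface, " "))

  clash <- surfaces |>
    dplyr::distinct(.data$surface, .data$canonical) |>
    dplyr::count(.data$surface) |>
    dplyr::filter(.data$n > 1)
  if (nrow(clash) > 0) {
    claimants <- surfaces |>
      dplyr::filter(.data$surface %in% clash$surface) |>
      dplyr::distinct(.data$surface, .data$canonical)
    abort(paste0(
      "ambiguous surface form(s) claimed by multiple canonical terms: ",
      paste(unique(sprintf("'%s' -> %s", claimants$surface,
                           claimants$canonical)), collapse = "; "),
      ". Remove the ambiguous form from all but one entry."
    ))
  }
  # one row per surface; file order preserved for deterministic tie-breaks
  surfaces <- dplyr::distinct(surfaces, .data$surface, .keep_all = TRUE)

  structure(
    list(
      entries = tibble(canonical = canon,
                       category = as.character(entries$category)),
      surfaces = surfaces[, c("surface", "canonical", "n_words", "is_acronym")],
      categories = unique(as.character(entries$category))
    ),
    class = "terminology"
  )
}

#' @export
print.terminology <- function(x, ...) {
  cat("<terminology>", nrow(x$entries), "terms,",
      nrow(x$surfaces), "surface forms,",
      length(x$categories), "categories\n")
  invisible(x)
}

#' Read / write a terminology corpus file
#'
#' The on-disk format is CSV (columns `canonical`, `variants`, `acronyms`,
#' `category`; variants and acronyms `|`-separated) or YAML (a list of
#' entries with those fields), chosen by file extension. Loading validates
#' the corpus via [terminology()]; a well-formed file round-trips through
#' `write_terminology()` and back unchanged.
#'
#' @param path File path ending in `.csv`, `.yml` or `.yaml`.
#' @param config,expand_plurals Passed to [terminology()].
#' @param terms A `terminology` object (for writing).
#' @return `read_terminology()` returns a `terminology` object;
#'   `write_terminology()` returns `path` invisibly.
#' @export
read_terminology <- function(path, config = preprocess_config(),
                             expand_plurals = TRUE) {
  if (!file.exists(path)) abort(paste0("terminology file not found: ", path))
  ext <- stringr::str_to_lower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    raw <- yaml::read_yaml(path)
    entries <- tibble(
      canonical = vapply(raw, function(e) as.character(e$canonical), character(1)),
      variants = lapply(raw, function(e) as.character(e$variants %||% character(0))),
      acronyms = lapply(raw, function(e) as.character(e$acronyms %||% character(0))),
      category = vapply(raw, function(e) as.character(e$category), character(1))
    )
  } else {
    entries <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)
  }
  terminology(entries, config = config, expand_plurals = expand_plurals)
}

#' @rdname read_terminology
#' @export
write_terminology <- function(terms, path) {
  stopifnot(inherits(terms, "terminology"))
  per_canon <- terms$surfaces |>
    dplyr::group_by(.data$canonical) |>
    dplyr::summarise(
      variants = paste(setdiff(.data$surface[!.data$is_acronym],
                               .data$canonical[1]), collapse = "|"),
      acronyms = paste(.data$surface[.data$is_acronym], collapse = "|"),
      .groups = "drop"
    )
  out <- dplyr::left_join(terms$entries, per_canon, by = "canonical")
  readr::write_csv(out[, c("canonical", "variants", "acronyms", "category")],
                   path, progress = FALSE)
  invisible(path)
}

#' The reconstructed HIV terminology corpus shipped with the package
#'
#' Loads the package's default terminology file, a *reconstruction* limited
#' to the terms and categories named in the published trend analysis of
#' International AIDS Conference abstracts (the full curated corpus was
#' supplementary material and is not redistributed here). Useful as a
#' realistic worked-example input; real analyses should supply their own
#' curated file.
#'
#' @inheritParams read_terminology
#' @return A `terminology` object.
#' @export
default_terminology <- function(config = preprocess_config(),
                                expand_plurals = TRUE) {
  read_terminology(
    system.file("extdata", "hiv_terminology_reconstructed.csv",
                package = "termtrends", mustWork = TRUE),
    config = config, expand_plurals = expand_plurals
  )
}

# Compile a terminology object into fast lookup structures for the scanner.
compile_terms <- function(terms) {
  surf_tokens <- stringr::str_split(terms$surfaces$surface, " ")
  dict <- new.env(parent = emptyenv(), size = max(64L, nrow(terms$surfaces)))
  for (i in seq_len(nrow(terms$surfaces))) {
    assign(terms$surfaces$surface[i], terms$surfaces$canonical[i], envir = dict)
  }
  list(
    dict = dict,
    first_words = unique(vapply(surf_tokens, `[`, character(1), 1L)),
    max_len = max(terms$surfaces$n_words)
  )
}

#' Count terminology occurrences in token streams
#'
#' The exact multiword matcher: a greedy left-to-right scan over each
#' abstract's matching-token stream. At every position the *longest* surface
#' form in the terminology corpus that matches wins; its tokens are consumed,
#' so nested terms never double-count ("antiretroviral therapy" inside
#' "highly active antiretroviral therapy" is credited only to the longer
#' term) and one text span never feeds two trend lines. Acronyms are matched
#' as standalone tokens; a token inside a longer matched phrase is already
#' consumed and cannot fire an acronym match.
#'
#' @param tokens Token tibble from [tokenize_abstracts()].
#' @param terms A validated [terminology()] object.
#' @return Tibble `id`, `year`, `term` (canonical), `count`, containing only
#'   nonzero counts; abstracts matching nothing contribute no rows. Zero
#'   filling happens in [aggregate_counts()].
#' @export
count_term_occurrences <- function(tokens, terms) {
  check_tokens(tokens)
  stopifnot(inherits(terms, "terminology"))
  if (nrow(terms$surfaces) == 0) {
    return(tibble(id = character(0), year = integer(0),
                  term = character(0), count = integer(0)))
  }
  cmp <- compile_terms(terms)
  rows <- vector("list", nrow(tokens))
  for (a in seq_len(nrow(tokens))) {
    toks <- tokens$matching[[a]]
    n <- length(toks)
    if (n == 0) next
    hits <- which(toks %in% cmp$first_words)
    if (length(hits) == 0) next
    counts <- new.env(parent = emptyenv())
    consumed_until <- 0L  # last token index consumed by a previous match
    for (i in hits) {
      if (i <= consumed_until) next
      for (len in min(cmp$max_len, n - i + 1L):1L) {
        key <- paste(toks[i:(i + len - 1L)], collapse = " ")
        canon <- get0(key, envir = cmp$dict, inherits = FALSE)
        if (!is.null(canon)) {
          prev <- get0(canon, envir = counts, inherits = FALSE) %||% 0L
          assign(canon, prev + 1L, envir = counts)
          consumed_until <- i + len - 1L
          break
        }
      }
    }
    found <- ls(counts)
    if (length(found) > 0) {
      rows[[a]] <- tibble(
        id = tokens$id[a], year = tokens$year[a], term = found,
        count = vapply(found, get, integer(1), envir = counts,
                       USE.NAMES = FALSE)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(id = character(0), year = integer(0),
                  term = character(0), count = integer(0)))
  }
  dplyr::arrange(out, .data$year, .data$id, .data$term)
}

#' Aggregate per-abstract term counts to (term, year) totals
#'
#' Sums counts to the absolute term frequency per conference year and counts
#' the abstracts containing each term (abstract-level document frequency).
#' The result is complete: every (canonical term, corpus year) pair gets a
#' row, zero-filled where a term never occurs, so downstream trend lines are
#' continuous.
#'
#' @param counts Tibble from [count_term_occurrences()].
#' @param terms The [terminology()] object (defines the term universe).
#' @param years Integer vector of all corpus years (defines the year
#'   universe; pass the full set even if some years matched nothing).
#' @return Tibble `term`, `year`, `absolute_tf`, `abstract_df`, sorted by
#'   term then year.
#' @export
aggregate_counts <- function(counts, terms, years) {
  stopifnot(inherits(terms, "terminology"))
  years <- sort(unique(as.integer(years)))
  agg <- counts |>
    dplyr::group_by(.data$term, .data$year) |>
    dplyr::summarise(
      absolute_tf = sum(.data$count),
      abstract_df = dplyr::n(),
      .groups = "drop"
    )
  tidyr::expand_grid(term = terms$entries$canonical, year = years) |>
    dplyr::left_join(agg, by = c("term", "year")) |>
    dplyr::mutate(
      absolute_tf = dplyr::coalesce(.data$absolute_tf, 0L),
      abstract_df = dplyr::coalesce(.data$abstract_df, 0L)
    ) |>
    dplyr::arrange(.data$term, .data$year)
}
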