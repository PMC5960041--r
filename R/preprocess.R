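#' Preprocessing configuration
#'
#' Bundles the three tunable text-normalization assets: the stop-word list
#' (used only when building the discovery token stream), the symbol map
#' (surface forms carrying symbols, rewritten to word phrases before
#' tokenization, e.g. `HIV+` to `"hiv positive"`), and the plural-exception
#' list (words such as `"aids"` that a trailing-s rule must never touch).
#' Defaults are read from the YAML asset shipped with the package;
#' any component can be overridden.
#'
#' @param stopwords Character vector of lowercase stop words, or `NULL` for
#'   the shipped default list.
#' @param symbol_map Named character vector mapping symbol-bearing surface
#'   forms to replacement phrases (matched case-insensitively, longest key
#'   first), or `NULL` for the default.
#' @param plural_exceptions Character vector of words exempt from plural
#'   handling, or `NULL` for the default.
#' @param path Optional path to a YAML file with keys `stopwords`,
#'   `symbol_map`, `plural_exceptions`; explicit arguments still win.
#'
#' @return An object of class `preprocess_config`.
#' @examples
#' cfg <- preprocess_config()
#' head(cfg$stopwords)
#' @export
preprocess_config <- function(stopwords = NULL, symbol_map = NULL,
                              plural_exceptions = NULL, path = NULL) {
  defaults <- yaml::read_yaml(
    path %||% system.file("extdata", "default_config.yaml",
                          package = "termtrends", mustWork = TRUE)
  )
  sw <- stringr::str_to_lower(stopwords %||% unlist(defaults$stopwords))
  sm <- symbol_map %||% unlist(defaults$symbol_map)
  pe <- stringr::str_to_lower(plural_exceptions %||%
                                unlist(defaults$plural_exceptions))
  if (length(sm) > 0) {
    if (is.null(names(sm)) || any(!nzchar(names(sm)))) {
      abort("symbol_map must be a fully named character vector")
    }
    names(sm) <- stringr::str_to_lower(names(sm))
    sm <- sm[order(-nchar(names(sm)), names(sm))]  # longest key first
  }
  structure(
    list(stopwords = unique(sw), symbol_map = sm,
         plural_exceptions = unique(pe)),
    class = "preprocess_config"
  )
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat("<preprocess_config>\n")
  cat("  stopwords:        ", length(x$stopwords), "words\n")
  cat("  symbol_map:       ", length(x$symbol_map), "entries\n")
  cat("  plural_exceptions:", length(x$plural_exceptions), "words\n")
  invisible(x)
}

#' Rewrite symbol-bearing surface forms as word phrases
#'
#' Applies the configuration's symbol map to free text: every occurrence of a
#' map key, delimited by word boundaries and matched case-insensitively, is
#' replaced by its phrase. Must run before tokenization, otherwise the symbol
#' (`+`, `/`, ...) is lost to punctuation stripping and `HIV+` becomes
#' indistinguishable from `HIV`.
#'
#' @param text Character vector.
#' @param config A [preprocess_config()].
#' @return Character vector with all mapped symbols rewritten.
#' @examples
#' apply_symbol_map("HIV+ patients", preprocess_config())
#' @export
apply_symbol_map <- function(text, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  out <- text
  for (key in names(config$symbol_map)) {
    pat <- paste0(
      "(?<![[:alnum:]])",
      stringr::str_replace_all(key, "([\\\\.^$|()\\[\\]{}*+?/])", "\\\\\\1"),
      "(?![[:alnum:]])"
    )
    out <- stringr::str_replace_all(
      out, stringr::regex(pat, ignore_case = TRUE),
      config$symbol_map[[key]]
    )
  }
  out
}

# Tokenize one text: transliterate diacritics, lowercase, split into
# sentences on terminal punctuation, split sentences on non-alphanumeric
# runs, drop tokens containing digits. Returns the matching stream (all
# words), the discovery stream (stop words removed) and the matching-stream
# indices after which a sentence boundary falls.
tokenize_one <- function(text, stopwords) {
  ascii <- stringi::stri_trans_general(text, "Latin-ASCII")
  lower <- stringr::str_to_lower(ascii)
  sentences <- stringr::str_split(lower, "[.!?]+")[[1]]
  matching <- character(0)
  breaks <- integer(0)
  for (s in sentences) {
    toks <- stringr::str_split(s, "[^a-z0-9]+")[[1]]
    toks <- toks[nzchar(toks)]
    toks <- toks[!stringr::str_detect(toks, "[0-9]")]
    if (length(toks) == 0) next
    matching <- c(matching, toks)
    breaks <- c(breaks, length(matching))
  }
  list(
    matching = matching,
    discovery = matching[!matching %in% stopwords],
    breaks = breaks
  )
}

#' Tokenize abstracts into matching and discovery streams
#'
#' Converts cleaned (and symbol-mapped) abstract text into two parallel
#' ordered token streams per abstract: the *matching* stream keeps every
#' word and is used for term counting and vocabulary size; the *discovery*
#' stream drops stop words and feeds unigram ranking. Tokens are lowercase,
#' diacritics are transliterated to ASCII base letters (`naïve` to `naive`),
#' hyphenated forms split into their constituent words, and tokens containing
#' digits are dropped.
#'
#' @param abstracts Abstract tibble (`id`, `year`, `text`), cleaned.
#' @param config A [preprocess_config()].
#' @param map_symbols Apply the symbol map first (default `TRUE`).
#'
#' @return A tibble with one row per abstract: `id`, `year`,
#'   `matching` and `discovery` (list-columns of character vectors),
#'   `n_tokens` (matching-stream length) and `sentence_breaks` (list-column
#'   of matching-stream indices after which a sentence ends; n-gram windows
#'   never cross these).
#' @examples
#' ab <- tibble::tibble(id = "a1", year = 1989L,
#'                      text = "The AIDS epidemic, 1989.")
#' tokenize_abstracts(ab)$matching[[1]]
#' @export
tokenize_abstracts <- function(abstracts, config = preprocess_config(),
                               map_symbols = TRUE) {
  check_abstracts(abstracts)
  stopifnot(inherits(config, "preprocess_config"))
  text <- if (map_symbols) apply_symbol_map(abstracts$text, config) else abstracts$text
  streams <- lapply(text, tokenize_one, stopwords = config$stopwords)
  tibble(
    id = abstracts$id,
    year = as.integer(abstracts$year),
    matching = lapply(streams, `[[`, "matching"),
    discovery = lapply(streams, `[[`, "discovery"),
    n_tokens = vapply(streams, function(s) length(s$matching), integer(1)),
    sentence_breaks = lapply(streams, `[[`, "breaks")
  )
}

#' Rule-based singular and plural forms
#'
#' `singularize()` maps plural surface forms onto singulars with ordinary
#' English suffix rules: `-ies` to `-y`, `-sses`/`-xes`/`-ches`/`-shes` drop
#' `es`, otherwise a trailing `s` is dropped for words longer than three
#' letters unless the word ends in `ss`, `us` or `is` (those endings are
#' usually not plural markers, and guarding them keeps the rule idempotent).
#' Words on the plural-exception list (e.g. `"aids"`) are never touched.
#' `pluralize()` runs the rules in reverse to expand term variants to their
#' plural surface forms at terminology-load time.
#'
#' @param tokens Character vector of lowercase words.
#' @param config A [preprocess_config()] supplying `plural_exceptions`.
#' @return Character vector of the same length.
#' @examples
#' singularize(c("epidemics", "babies", "aids"), preprocess_config())
#' pluralize(c("epidemic", "baby", "aids"), preprocess_config())
#' @export
singularize <- function(tokens, config = preprocess_config()) {
  out <- tokens
  exempt <- tokens %in% config$plural_exceptions
  ies <- !exempt & stringr::str_detect(tokens, "[a-z]ies$") & nchar(tokens) > 4
  out[ies] <- stringr::str_replace(out[ies], "ies$", "y")
  es <- !exempt & !ies & stringr::str_detect(tokens, "(sses|xes|ches|shes|zes)$")
  out[es] <- stringr::str_remove(out[es], "es$")
  plain <- !exempt & !ies & !es & nchar(tokens) > 3 &
    stringr::str_detect(tokens, "[a-z]s$") &
    !stringr::str_detect(tokens, "(ss|us|is)$")
  out[plain] <- stringr::str_remove(out[plain], "s$")
  out
}

#' @rdname singularize
#' @export
pluralize <- function(tokens, config = preprocess_config()) {
  out <- tokens
  exempt <- tokens %in% config$plural_exceptions |
    stringr::str_detect(tokens, "s$")
  y <- !exempt & stringr::str_detect(tokens, "[^aeiou]y$")
  out[y] <- stringr::str_replace(out[y], "y$", "ies")
  es <- !exempt & !y & stringr::str_detect(tokens, "(s|x|z|ch|sh)$")
  out[es] <- paste0(out[es], "es")
  plain <- !exempt & !y & !es
  out[plain] <- paste0(out[plain], "s")
  out
}
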