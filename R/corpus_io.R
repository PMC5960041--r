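#' Read a delimited table of conference abstracts
#'
#' Ingests one record per abstract from a delimited text file (CSV by
#' default). Columns holding the abstract identifier, the conference year and
#' the abstract text are named explicitly, so arbitrary export schemas can be
#' mapped onto the canonical `id`/`year`/`text` layout. Text cleaning is *not*
#' applied here; see [clean_abstracts()].
#'
#' @param path Path to the delimited file.
#' @param id_col,year_col,text_col Names of the columns holding the abstract
#'   identifier, conference year and abstract text.
#' @param delim Field delimiter (default `","`).
#' @param quote Quoting character (default `"\""`).
#'
#' @return A tibble with columns `id` (character), `year` (integer) and
#'   `text` (character), one row per abstract, in file order.
#'
#' @details Malformed years (anything that does not parse as an integer) and
#'   duplicated identifiers are hard errors that name the offending rows: a
#'   corrupted export should fail loudly at the door rather than surface as a
#'   miscounted trend line downstream. An input with a header but no data
#'   rows is also an error.
#'
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,year,text", "a1,1989,the aids epidemic", "a2,1990,hiv care"), tf)
#' read_abstract_table(tf)
#' @export
read_abstract_table <- function(path, id_col = "id", year_col = "year",
                                text_col = "text", delim = ",", quote = "\"") {
  if (!file.exists(path)) {
    abort(paste0("abstract table not found: ", path))
  }
  raw <- readr::read_delim(
    path,
    delim = delim, quote = quote,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(c(id_col, year_col, text_col), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "column(s) not found in ", path, ": ",
      paste(missing_cols, collapse = ", "),
      " (available: ", paste(names(raw), collapse = ", "), ")"
    ))
  }
  if (nrow(raw) == 0) {
    abort(paste0("empty input: ", path, " has a header but no data rows"))
  }

  year_chr <- raw[[year_col]]
  year_int <- suppressWarnings(as.integer(year_chr))
  bad <- which(is.na(year_int) | as.character(year_int) != trimws(year_chr))
  if (length(bad) > 0) {
    abort(paste0(
      "unparsable year value(s) in row(s) ",
      paste(head(bad, 10L), collapse = ", "),
      ": ", paste(unique(head(year_chr[bad], 10L)), collapse = ", ")
    ))
  }

  id <- as.character(raw[[id_col]])
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    abort(paste0(
      "duplicate abstract id(s): ", paste(head(dup, 10L), collapse = ", ")
    ))
  }

  tibble(
    id = id,
    year = year_int,
    text = dplyr::coalesce(as.character(raw[[text_col]]), "")
  )
}

# Named HTML entities that occur in practice in abstract exports. Unknown
# named entities are left verbatim (and reported) rather than guessed at.
.named_entities <- c(
  amp = "&", lt = "<", gt = ">", quot = "\"", apos = "'",
  nbsp = " ", ndash = "–", mdash = "—", hellip = "…",
  lsquo = "‘", rsquo = "’", ldquo = "“", rdquo = "”",
  plusmn = "±", deg = "°", micro = "µ", middot = "·",
  times = "×", divide = "÷", frac12 = "½",
  alpha = "α", beta = "β", gamma = "γ", delta = "δ",
  eacute = "é", egrave = "è", agrave = "à", ccedil = "ç",
  uuml = "ü", ouml = "ö", auml = "ä", ntilde = "ñ",
  copy = "©", reg = "®", sect = "§", para = "¶"
)

decode_entities_once <- function(x) {
  # numeric references, decimal and hex
  x <- stringr::str_replace_all(x, "&#[xX]([0-9a-fA-F]{1,6});", function(m) {
    code <- strtoi(stringr::str_match(m, "&#[xX]([0-9a-fA-F]+);")[, 2], 16L)
    intToUtf8(code)
  })
  x <- stringr::str_replace_all(x, "&#([0-9]{1,7});", function(m) {
    code <- strtoi(stringr::str_match(m, "&#([0-9]+);")[, 2], 10L)
    intToUtf8(code)
  })
  # named references
  stringr::str_replace_all(x, "&([a-zA-Z][a-zA-Z0-9]{1,30});", function(m) {
    name <- stringr::str_match(m, "&([a-zA-Z][a-zA-Z0-9]+);")[, 2]
    known <- !is.na(.named_entities[name])
    out <- m
    out[known] <- unname(.named_entities[name[known]])
    out
  })
}

#' Clean markup out of abstract text
#'
#' Strips markup tags, decodes HTML character entities (named and numeric,
#' including double-encoded forms such as `&amp;lt;`), collapses runs of
#' whitespace to single spaces and trims the ends. No word is altered or
#' removed: only markup artifacts disappear.
#'
#' @param x Character vector of raw abstract texts.
#' @return Character vector of the same length, cleaned.
#'
#' @details Decoding and tag stripping are iterated to a fixed point (bounded)
#'   so that double-encoded markup (`&amp;lt;b&amp;gt;` and friends) is fully
#'   resolved. Entities that are not recognized are left verbatim and reported
#'   once per call via a message, per the principle that silent mangling is
#'   worse than visible residue.
#'
#' @examples
#' clean_text("<b>HIV</b> care &amp; support")
#' clean_text("a  b\tc")
#' @export
clean_text <- function(x) {
  stopifnot(is.character(x))
  out <- x
  for (i in 1:5) {
    prev <- out
    out <- stringr::str_remove_all(out, "<[^<>]+>")
    out <- decode_entities_once(out)
    if (identical(out, prev)) break
  }
  leftover <- unique(unlist(stringr::str_extract_all(
    out, "&[a-zA-Z][a-zA-Z0-9]{1,30};"
  )))
  if (length(leftover) > 0) {
    inform(paste0(
      "clean_text: unrecognized entities left verbatim: ",
      paste(head(leftover, 10L), collapse = " ")
    ))
  }
  out <- stringr::str_replace_all(out, "[\\s ]+", " ")
  stringr::str_trim(out)
}

#' Clean the text column of an abstract table
#'
#' Convenience wrapper applying [clean_text()] to the `text` column.
#'
#' @param abstracts Tibble from [read_abstract_table()].
#' @return The same tibble with `text` cleaned.
#' @export
clean_abstracts <- function(abstracts) {
  check_abstracts(abstracts)
  dplyr::mutate(abstracts, text = clean_text(.data$text))
}

#' Drop duplicate abstracts within each conference year
#'
#' Two abstracts are duplicates when their case-folded, whitespace-collapsed
#' texts are identical *and* they belong to the same conference year; the
#' first occurrence is kept. Identical texts submitted in different years are
#' legitimate resubmissions and are retained. The number of records removed
#' is reported via a message.
#'
#' @param abstracts Tibble with columns `id`, `year`, `text` (cleaned).
#' @return Deduplicated tibble, original row order preserved. Idempotent.
#' @export
deduplicate <- function(abstracts) {
  check_abstracts(abstracts)
  key <- stringr::str_squish(stringr::str_to_lower(abstracts$text))
  keep <- !duplicated(paste(abstracts$year, key, sep = "\r"))
  removed <- sum(!keep)
  if (removed > 0) {
    inform(paste0("deduplicate: removed ", removed, " duplicate abstract(s)"))
  }
  abstracts[keep, , drop = FALSE]
}

#' Conference years present in an abstract table
#'
#' @param abstracts Abstract tibble.
#' @return Sorted integer vector of distinct conference years.
#' @export
corpus_years <- function(abstracts) {
  check_abstracts(abstracts)
  sort(unique(as.integer(abstracts$year)))
}

#' Persist / restore an abstract table as line-delimited JSON
#'
#' One JSON object per line with fields `id`, `year`, `text` — a diffable,
#' streamable intermediate store. `read_abstracts_jsonl()` inverts
#' `write_abstracts_jsonl()` exactly (round-trip identity).
#'
#' @param abstracts Abstract tibble.
#' @param path File path for the JSONL store.
#' @return `write_abstracts_jsonl()` returns `path` invisibly;
#'   `read_abstracts_jsonl()` returns the abstract tibble.
#' @export
write_abstracts_jsonl <- function(abstracts, path) {
  check_abstracts(abstracts)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(abstracts))) {
    writeLines(jsonlite::toJSON(
      list(id = abstracts$id[i], year = abstracts$year[i],
           text = abstracts$text[i]),
      auto_unbox = TRUE
    ), con)
  }
  invisible(path)
}

#' @rdname write_abstracts_jsonl
#' @export
read_abstracts_jsonl <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(paste0("empty input: ", path))
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    year = vapply(recs, function(r) as.integer(r$year), integer(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1))
  )
}

check_abstracts <- function(abstracts) {
  if (!is.data.frame(abstracts) ||
      !all(c("id", "year", "text") %in% names(abstracts))) {
    abort("expected a data frame with columns id, year, text")
  }
  invisible(abstracts)
}
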