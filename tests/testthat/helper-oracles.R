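# Independent brute-force oracles. These deliberately avoid the package's
# internal tokenizer/scanner code paths: iconv instead of stringi, gregexpr
# scans instead of the hash-dictionary matcher, plain nested loops instead
# of the vectorized pipelines.

# Full-scan word counter over raw (symbol-free) text: transliterate,
# lowercase, extract alphanumeric runs, drop runs containing digits.
oracle_word_count <- function(texts) {
  total <- 0L
  for (x in texts) {
    x <- iconv(x, "UTF-8", "ASCII//TRANSLIT", sub = "")
    x <- tolower(x)
    runs <- regmatches(x, gregexpr("[a-z0-9]+", x))[[1]]
    runs <- runs[!grepl("[0-9]", runs)]
    total <- total + length(runs)
  }
  total
}

# Naive unigram tally over discovery token streams of one year.
oracle_unigram_stats <- function(tokens, yr) {
  rows <- tokens[tokens$year == yr, ]
  counts <- list()
  dfs <- list()
  for (i in seq_len(nrow(rows))) {
    toks <- rows$discovery[[i]]
    for (tok in unique(toks)) {
      counts[[tok]] <- (counts[[tok]] %||% 0L) + sum(toks == tok)
      dfs[[tok]] <- (dfs[[tok]] %||% 0L) + 1L
    }
  }
  toks <- sort(names(counts))
  tibble::tibble(
    year = yr, token = toks,
    absolute_count = vapply(counts[toks], identity, integer(1)),
    abstract_df = vapply(dfs[toks], identity, integer(1))
  )
}

# Non-overlapping phrase counter on the space-joined matching stream of one
# abstract, via fixed-string gregexpr on a padded string.
oracle_phrase_count <- function(matching_tokens, phrase) {
  hay <- paste0(" ", paste(matching_tokens, collapse = " "), " ")
  needle <- paste0(" ", phrase, " ")
  n <- 0L
  from <- 1L
  repeat {
    hit <- regexpr(needle, substring(hay, from), fixed = TRUE)
    if (hit < 0) break
    n <- n + 1L
    # overlap needles share the delimiting space: advance past the phrase only
    from <- from + hit + attr(hit, "match.length") - 2L
  }
  n
}

# Brute-force n-gram candidate enumeration: every window of 2..max_n words
# within each sentence segment that contains a key unigram, with per-year
# abstract document frequency.
oracle_ngrams <- function(tokens, keys, max_n) {
  seen <- list()  # surface|year -> set of abstract ids
  for (i in seq_len(nrow(tokens))) {
    toks <- tokens$matching[[i]]
    ends <- tokens$sentence_breaks[[i]]
    if (length(ends) == 0) ends <- length(toks)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (s in seq_along(starts)) {
      seg <- toks[starts[s]:ends[s]]
      if (length(seg) < 2) next
      for (n in 2:max_n) {
        if (n > length(seg)) break
        for (j in 1:(length(seg) - n + 1L)) {
          win <- seg[j:(j + n - 1L)]
          if (any(win %in% keys)) {
            key <- paste(paste(win, collapse = " "), tokens$year[i], sep = "|")
            seen[[key]] <- union(seen[[key]] %||% character(0), tokens$id[i])
          }
        }
      }
    }
  }
  if (length(seen) == 0) {
    return(tibble::tibble(surface = character(0), year = integer(0),
                          abstract_df = integer(0)))
  }
  parts <- strsplit(names(seen), "|", fixed = TRUE)
  out <- tibble::tibble(
    surface = vapply(parts, `[`, character(1), 1L),
    year = as.integer(vapply(parts, `[`, character(1), 2L)),
    abstract_df = lengths(seen)
  )
  out[order(out$surface, out$year), ]
}

`%||%` <- rlang::`%||%`
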