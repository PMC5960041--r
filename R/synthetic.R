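# The 16 conference years the generator emulates: annual meetings 1989-1994,
# then biennial meetings 1996-2014 (uneven calendar spacing, even
# conference-sequence spacing).
iac_conference_years <- function() {
  as.integer(c(1989:1994, seq(1996L, 2014L, 2L)))
}

default_planted_terms <- function(n_years = 16L) {
  ramp_down <- function(hi, lo) as.integer(round(seq(hi, lo, length.out = n_years)))
  ramp_up <- function(lo, hi) as.integer(round(seq(lo, hi, length.out = n_years)))
  late <- function(hi, start) {
    out <- integer(n_years)
    out[start:n_years] <- as.integer(round(seq(1, hi, length.out = n_years - start + 1L)))
    out
  }
  one_year <- function(k, count) {
    out <- integer(n_years)
    out[k] <- count
    out
  }
  list(
    list(phrase = "aids patient", category = "living with hiv",
         counts = ramp_down(60, 2)),
    list(phrase = "aids carrier", category = "living with hiv",
         counts = rep(4L, n_years)),
    list(phrase = "people living with hiv", category = "living with hiv",
         counts = late(50, 6L)),
    list(phrase = "hiv epidemic", category = "epidemic",
         counts = ramp_up(2, 60)),
    list(phrase = "aids epidemic", category = "epidemic",
         counts = ramp_down(40, 0)),
    list(phrase = "men who have sex with men", category = "msm",
         counts = late(45, 7L)),
    list(phrase = "sex worker", category = "sex worker",
         counts = ramp_up(3, 30)),
    list(phrase = "drug holiday", category = "treatment interruption",
         counts = one_year(9L, 12L))
  )
}

#' Specification of a synthetic abstract corpus
#'
#' Describes a corpus with known statistical structure: a list of conference
#' years, per-year abstract counts, Zipf-distributed background vocabulary,
#' and multiword terms planted at known per-year counts (exact mode) or at a
#' Poisson rate per abstract (stochastic mode). Planted phrases use a word
#' alphabet disjoint from the generated background vocabulary, so every
#' pipeline stage has an exact oracle: whatever the matcher reports must
#' equal what was planted.
#'
#' The defaults emulate the shape of a 25-year international conference
#' abstract archive at a scale that processes in seconds: 16 conference
#' years (annual then biennial spacing), 200 abstracts per year of 150 words
#' on average (~half a million words in total), and planted terms whose
#' per-year counts rise, fall, appear late, or occur in a single year.
#'
#' @param years Integer vector of conference years.
#' @param abstracts_per_year Single integer, or integer vector the length of
#'   `years`.
#' @param mean_abstract_length Mean background tokens per abstract (Poisson,
#'   floored at 10).
#' @param background_vocab_size Number of distinct background word types.
#' @param zipf_exponent Exponent `s` of the background rank-frequency law
#'   (`p(r)` proportional to `r^-s`); 1 is the classic Zipf value.
#' @param planted_terms List of term plans. Each element is a list with
#'   `phrase` (1–6 lowercase words), `category`, and either `counts` (integer
#'   vector per year, exact mode) or `rate` (Poisson mean per abstract,
#'   stochastic mode).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(years = iac_conference_years(),
                           abstracts_per_year = 200L,
                           mean_abstract_length = 150,
                           background_vocab_size = 2000L,
                           zipf_exponent = 1,
                           planted_terms = default_planted_terms(length(years))) {
  years <- as.integer(years)
  stopifnot(length(years) >= 1, !anyDuplicated(years))
  if (length(abstracts_per_year) == 1) {
    abstracts_per_year <- rep(as.integer(abstracts_per_year), length(years))
  }
  stopifnot(length(abstracts_per_year) == length(years),
            all(abstracts_per_year >= 1),
            mean_abstract_length >= 10,
            background_vocab_size >= 10,
            zipf_exponent > 0)
  for (pt in planted_terms) {
    if (is.null(pt$phrase) || is.null(pt$category)) {
      abort("each planted term needs a phrase and a category")
    }
    nw <- length(strsplit(pt$phrase, " ")[[1]])
    if (nw < 1 || nw > 6) abort(paste0("planted phrase must be 1-6 words: ", pt$phrase))
    has_counts <- !is.null(pt$counts)
    has_rate <- !is.null(pt$rate)
    if (has_counts == has_rate) {
      abort(paste0("planted term '", pt$phrase,
                   "' needs exactly one of counts or rate"))
    }
    if (has_counts && (length(pt$counts) != length(years) || any(pt$counts < 0))) {
      abort(paste0("counts for '", pt$phrase, "' must be ", length(years),
                   " non-negative integers"))
    }
    if (has_rate && (length(pt$rate) != 1 || pt$rate < 0)) {
      abort(paste0("rate for '", pt$phrase, "' must be a single non-negative number"))
    }
  }
  structure(
    list(years = sort(years), abstracts_per_year = abstracts_per_year,
         mean_abstract_length = mean_abstract_length,
         background_vocab_size = as.integer(background_vocab_size),
         zipf_exponent = zipf_exponent, planted_terms = planted_terms),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>", length(x$years), "years,",
      sum(x$abstracts_per_year), "abstracts,",
      length(x$planted_terms), "planted terms\n")
  invisible(x)
}

#' Read a synthetic corpus specification from YAML
#'
#' YAML keys mirror the [synthetic_spec()] arguments; `planted_terms` is a
#' list of maps with `phrase`, `category` and `counts` or `rate`.
#'
#' @param path YAML file path.
#' @return A `synthetic_spec` object.
#' @export
read_synthetic_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("years", "abstracts_per_year",
                          "mean_abstract_length", "background_vocab_size",
                          "zipf_exponent", "planted_terms"))]
  do.call(synthetic_spec, args)
}

# Deterministic digit-free background vocabulary: base-26 words prefixed
# "bk", e.g. "bkaaa", "bkaab", ... The prefix keeps the alphabet disjoint
# from any realistic planted phrase; disjointness is still validated.
background_vocabulary <- function(n) {
  width <- max(3L, ceiling(log(n + 1) / log(26)))
  idx <- seq_len(n) - 1L
  chars <- matrix("", nrow = n, ncol = width)
  for (p in seq_len(width)) {
    chars[, width - p + 1L] <- letters[(idx %/% 26L^(p - 1L)) %% 26L + 1L]
  }
  paste0("bk", apply(chars, 1, paste, collapse = ""))
}

# Insert phrases (list of token vectors) into a background token vector at
# the given gap positions (0 = before the first token). All insertions are
# resolved simultaneously, so every planted phrase stays contiguous.
insert_at_gaps <- function(bg, phrases, gaps) {
  ord <- order(gaps, seq_along(gaps))
  phrases <- phrases[ord]
  gaps <- gaps[ord]
  pieces <- vector("list", 2L * length(phrases) + 1L)
  prev <- 0L
  for (j in seq_along(phrases)) {
    pieces[[2L * j - 1L]] <- if (gaps[j] > prev) bg[(prev + 1L):gaps[j]] else character(0)
    pieces[[2L * j]] <- phrases[[j]]
    prev <- gaps[j]
  }
  pieces[[2L * length(phrases) + 1L]] <-
    if (prev < length(bg)) bg[(prev + 1L):length(bg)] else character(0)
  unlist(pieces, use.names = FALSE)
}

# Join tokens into sentence-like text: a period after every 8-15 tokens.
tokens_to_text <- function(toks, sentence_len) {
  breaks <- cumsum(sentence_len)
  breaks <- breaks[breaks < length(toks)]
  if (length(breaks) > 0) {
    toks[breaks] <- paste0(toks[breaks], ".")
  }
  paste0(paste(toks, collapse = " "), ".")
}

#' Generate a synthetic abstract corpus with known ground truth
#'
#' Draws Zipf-distributed background tokens, plants each term's occurrences
#' at uniformly random positions of uniformly chosen abstracts (never
#' overlapping: insertions happen at token gaps and stay contiguous), and
#' records exactly what was planted. In exact mode the realized counts equal
#' the plan; in Poisson mode the per-abstract draws are recorded, so the
#' ground truth always describes the emitted corpus, not the request.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the same seed yields a bit-identical corpus.
#' @return A list with class `synthetic_corpus`:
#'   * `abstracts`: tibble `id`, `year`, `text` ready for the pipeline;
#'   * `truth`: list of `term_year` (tibble `term`, `category`, `year`,
#'     `planted_count`, `planted_abstract_df`) and `year_totals` (tibble
#'     `year`, `n_abstracts`, `total_tokens`);
#'   * `terms`: a [terminology()] covering the planted phrases (plural
#'     expansion off — planted surfaces are exact).
#' @export
generate_corpus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))
  vocab <- background_vocabulary(spec$background_vocab_size)
  planted_words <- unique(unlist(strsplit(
    vapply(spec$planted_terms, `[[`, character(1), "phrase"), " "
  )))
  clash <- intersect(planted_words, vocab)
  if (length(clash) > 0) {
    abort(paste0("planted phrase word(s) collide with background vocabulary: ",
                 paste(clash, collapse = ", ")))
  }
  ranks <- seq_len(spec$background_vocab_size)
  zipf_p <- ranks^(-spec$zipf_exponent)
  zipf_p <- zipf_p / sum(zipf_p)

  phrases <- lapply(spec$planted_terms, function(pt) strsplit(pt$phrase, " ")[[1]])
  term_names <- vapply(spec$planted_terms, `[[`, character(1), "phrase")
  categories <- vapply(spec$planted_terms, `[[`, character(1), "category")

  ab_rows <- list()
  truth_rows <- list()
  total_rows <- list()
  for (k in seq_along(spec$years)) {
    yr <- spec$years[k]
    m <- spec$abstracts_per_year[k]
    lens <- pmax(10L, rpois(m, spec$mean_abstract_length))
    bg <- lapply(lens, function(L) sample(vocab, L, replace = TRUE, prob = zipf_p))

    # decide per-abstract occurrence counts for every planted term
    occ <- matrix(0L, nrow = m, ncol = length(spec$planted_terms))
    for (t in seq_along(spec$planted_terms)) {
      pt <- spec$planted_terms[[t]]
      if (!is.null(pt$counts)) {
        ct <- pt$counts[k]
        if (ct > 0) {
          chosen <- sample.int(m, ct, replace = TRUE)
          tab <- tabulate(chosen, nbins = m)
          occ[, t] <- as.integer(tab)
        }
      } else {
        occ[, t] <- rpois(m, pt$rate)
      }
    }

    toks <- vector("list", m)
    for (i in seq_len(m)) {
      ins_terms <- rep(seq_along(spec$planted_terms), occ[i, ])
      if (length(ins_terms) > 0) {
        gaps <- sample(0:lens[i], length(ins_terms), replace = TRUE)
        toks[[i]] <- insert_at_gaps(bg[[i]], phrases[ins_terms], gaps)
      } else {
        toks[[i]] <- bg[[i]]
      }
    }

    sent_lens <- lapply(toks, function(tk) {
      sample(8:15, ceiling(length(tk) / 8), replace = TRUE)
    })
    texts <- mapply(tokens_to_text, toks, sent_lens,
                    SIMPLIFY = TRUE, USE.NAMES = FALSE)
    # background draws make duplicate texts vanishingly unlikely; guarantee
    # it anyway (re-inserting the same planted occurrences, so the ground
    # truth still describes the emitted corpus)
    while (anyDuplicated(texts) > 0) {
      for (i in which(duplicated(texts))) {
        bg_i <- sample(vocab, lens[i], replace = TRUE, prob = zipf_p)
        ins_terms <- rep(seq_along(spec$planted_terms), occ[i, ])
        if (length(ins_terms) > 0) {
          gaps <- sample(0:lens[i], length(ins_terms), replace = TRUE)
          toks[[i]] <- insert_at_gaps(bg_i, phrases[ins_terms], gaps)
        } else {
          toks[[i]] <- bg_i
        }
        texts[i] <- tokens_to_text(toks[[i]], sent_lens[[i]])
      }
    }

    ab_rows[[k]] <- tibble(
      id = sprintf("y%d_a%04d", yr, seq_len(m)),
      year = yr,
      text = texts
    )
    truth_rows[[k]] <- tibble(
      term = term_names,
      category = categories,
      year = yr,
      planted_count = as.integer(colSums(occ)),
      planted_abstract_df = as.integer(colSums(occ > 0L))
    )
    total_rows[[k]] <- tibble(
      year = yr, n_abstracts = m,
      total_tokens = sum(lengths(toks))
    )
  }

  terms <- terminology(
    tibble(canonical = term_names, category = categories),
    expand_plurals = FALSE
  )
  structure(
    list(
      abstracts = dplyr::bind_rows(ab_rows),
      truth = list(term_year = dplyr::bind_rows(truth_rows),
                   year_totals = dplyr::bind_rows(total_rows)),
      terms = terms
    ),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus>", nrow(x$abstracts), "abstracts,",
      length(unique(x$abstracts$year)), "years,",
      nrow(x$terms$entries), "planted terms\n")
  invisible(x)
}

#' Desk-scale scenario reproducing the published two-term frequency contrast
#'
#' Builds a two-year corpus in which, mirroring the published absolute
#' frequencies for the pair of example terms, "aids carrier" is planted 7
#' times and "affected communities" once in the 1989 slice, and 1 and 2
#' times respectively in the 1990 slice. Within a year the two terms share
#' one vocabulary-size denominator, so their term-frequency *ratio* equals
#' the ratio of their absolute frequencies (7 and 2) regardless of the total
#' token count — the property that survives scaling the corpus down.
#'
#' @param seed Integer seed.
#' @return A `synthetic_corpus` (see [generate_corpus()]).
#' @export
table1_scenario <- function(seed = 1L) {
  spec <- synthetic_spec(
    years = c(1989L, 1990L),
    abstracts_per_year = 40L,
    mean_abstract_length = 80,
    background_vocab_size = 500L,
    planted_terms = list(
      list(phrase = "aids carrier", category = "living with hiv",
           counts = c(7L, 1L)),
      list(phrase = "affected communities", category = "affected communities",
           counts = c(1L, 2L))
    )
  )
  generate_corpus(spec, seed = seed)
}

#' Adversarial nested-term scenario for the longest-match rule
#'
#' Plants "highly active antiretroviral therapy" (5 times), the standalone
#' "antiretroviral therapy" (3 times) and the standalone unigram "therapy"
#' (2 times) in a single year. Because planted occurrences never overlap and
#' the matcher consumes the longest surface first, the expected counts are
#' exactly the planted counts: the nested shorter terms must not be credited
#' for spans inside longer ones.
#'
#' @param seed Integer seed.
#' @return A `synthetic_corpus` whose `truth$term_year` doubles as the
#'   hand-computed expected longest-match counts.
#' @export
nested_scenario <- function(seed = 1L) {
  spec <- synthetic_spec(
    years = 2000L,
    abstracts_per_year = 30L,
    mean_abstract_length = 60,
    background_vocab_size = 300L,
    planted_terms = list(
      list(phrase = "highly active antiretroviral therapy",
           category = "antiretroviral therapy", counts = 5L),
      list(phrase = "antiretroviral therapy",
           category = "antiretroviral therapy", counts = 3L),
      list(phrase = "therapy",
           category = "antiretroviral therapy", counts = 2L)
    )
  )
  generate_corpus(spec, seed = seed)
}

#' Paper-scale corpus specification
#'
#' The default [synthetic_spec()] is sized to run in seconds. This profile
#' matches the published archive's order of magnitude instead — thousands of
#' abstracts per year, per-year vocabulary sizes in the 1e5–1e6 range — for
#' local benchmarking and for checking scale properties on a year or two.
#'
#' @param years Conference years to include (default all 16).
#' @return A `synthetic_spec`.
#' @export
paper_scale_spec <- function(years = iac_conference_years()) {
  n <- length(iac_conference_years())
  keep <- match(as.integer(years), iac_conference_years())
  if (any(is.na(keep))) abort("years must be among the 16 emulated conference years")
  planted <- lapply(default_planted_terms(n), function(pt) {
    if (!is.null(pt$counts)) pt$counts <- (pt$counts * 15L)[keep]
    pt
  })
  synthetic_spec(
    years = as.integer(years),
    abstracts_per_year = 3000L,
    mean_abstract_length = 150,
    background_vocab_size = 20000L,
    planted_terms = planted
  )
}
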