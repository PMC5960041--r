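test_that("a terminology validates, and acronyms resolve to their canonical term", {
  terms <- terminology(tibble::tibble(
    canonical = "antiretroviral therapy",
    acronyms = "art",
    category = "antiretroviral therapy"
  ))
  expect_s3_class(terms, "terminology")
  art_row <- terms$surfaces[terms$surfaces$surface == "art", ]
  expect_equal(art_row$canonical, "antiretroviral therapy")
  expect_true(art_row$is_acronym)
})

test_that("a surface form claimed by two canonical terms is rejected, naming both", {
  bad <- tibble::tibble(
    canonical = c("structured treatment interruption", "sexually transmitted infection"),
    acronyms = c("sti", "sti"),
    category = c("treatment interruption", "prevention")
  )
  expect_error(terminology(bad), "ambiguous.*sti", ignore.case = TRUE)
  err <- tryCatch(terminology(bad), error = conditionMessage)
  expect_match(err, "structured treatment interruption")
  expect_match(err, "sexually transmitted infection")
})

test_that("a canonical term in two categories, numeric acronyms and empty variants are rejected", {
  expect_error(terminology(tibble::tibble(
    canonical = c("gay", "gay"), category = c("homosexual", "msm")
  )), "exactly one category")
  expect_error(terminology(tibble::tibble(
    canonical = "therapy", acronyms = "2020", category = "x"
  )), "numeric")
})

test_that("terminology files round-trip through save and load", {
  terms <- default_terminology()
  tf <- withr::local_tempfile(fileext = ".csv")
  write_terminology(terms, tf)
  again <- read_terminology(tf)
  expect_equal(again$entries, terms$entries)
  expect_setequal(again$surfaces$surface, terms$surfaces$surface)
  expect_equal(again$categories, terms$categories)
})

test_that("YAML terminology files load equivalently to CSV", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "- canonical: antiretroviral therapy",
    "  acronyms: [art]",
    "  category: antiretroviral therapy",
    "- canonical: sex worker",
    "  category: sex worker"
  ), tf)
  terms <- read_terminology(tf)
  expect_equal(nrow(terms$entries), 2L)
  expect_true("art" %in% terms$surfaces$surface)
})

test_that("plural variants are generated automatically unless disabled", {
  terms <- terminology(tibble::tibble(canonical = "aids patient", category = "x"))
  expect_true("aids patients" %in% terms$surfaces$surface)
  bare <- terminology(tibble::tibble(canonical = "aids patient", category = "x"),
                      expand_plurals = FALSE)
  expect_false("aids patients" %in% bare$surfaces$surface)
})

test_that("the longest matching surface wins and its tokens are consumed", {
  cfg <- tiny_config()
  terms <- terminology(tibble::tibble(
    canonical = c("antiretroviral therapy", "highly active antiretroviral therapy"),
    category = "art"
  ), config = cfg)
  tk <- tokenize_abstracts(make_abstracts(
    "highly active antiretroviral therapy works", 2000
  ), cfg)
  counts <- count_term_occurrences(tk, terms)
  expect_equal(counts$term, "highly active antiretroviral therapy")
  expect_equal(counts$count, 1L)  # the nested shorter term gets nothing
})

test_that("symbol-mapped surfaces match their canonical form", {
  cfg <- tiny_config()
  terms <- terminology(tibble::tibble(canonical = "hiv positive", category = "x"),
                       config = cfg)
  tk <- tokenize_abstracts(make_abstracts("HIV+ adults enrolled", 2000), cfg)
  counts <- count_term_occurrences(tk, terms)
  expect_equal(counts$term, "hiv positive")
  expect_equal(counts$count, 1L)
})

test_that("an empty terminology yields no counts", {
  cfg <- tiny_config()
  terms <- terminology(tibble::tibble(canonical = character(0),
                                      category = character(0)), config = cfg)
  tk <- tokenize_abstracts(make_abstracts("any text at all", 2000), cfg)
  expect_equal(nrow(count_term_occurrences(tk, terms)), 0L)
})

test_that("matched spans never exceed the token budget (no double counting)", {
  corp <- nested_scenario(seed = 5)
  tk <- tokenize_abstracts(corp$abstracts, preprocess_config())
  counts <- count_term_occurrences(tk, corp$terms)
  span <- setNames(corp$terms$surfaces$n_words[
    match(corp$terms$entries$canonical, corp$terms$surfaces$canonical)
  ], corp$terms$entries$canonical)
  total_matched <- sum(counts$count * span[counts$term])
  expect_lte(total_matched, sum(tk$n_tokens))
})

test_that("counting is invariant to abstract processing order", {
  corp <- random_small_corpus(9)
  cfg <- preprocess_config()
  tk <- tokenize_abstracts(corp$abstracts, cfg)
  shuffled <- tk[rev(seq_len(nrow(tk))), ]
  a <- count_term_occurrences(tk, corp$terms)
  b <- count_term_occurrences(shuffled, corp$terms)
  expect_equal(dplyr::arrange(a, id, term), dplyr::arrange(b, id, term))
})

test_that("for single-word terms, counts equal plain token tallies", {
  cfg <- tiny_config()
  terms <- terminology(tibble::tibble(
    canonical = c("hiv", "prevention"), category = "x"
  ), config = cfg, expand_plurals = FALSE)
  tk <- tokenize_abstracts(make_abstracts(
    c("hiv prevention hiv care", "prevention of hiv"), c(1989, 1989)
  ), cfg)
  counts <- count_term_occurrences(tk, terms)
  for (i in seq_len(nrow(counts))) {
    expect_equal(
      counts$count[i],
      sum(tk$matching[[match(counts$id[i], tk$id)]] == counts$term[i])
    )
  }
})

test_that("aggregation reproduces the worked example: 5, 10 and 15 occurrences give absolute TF 30 and DF 3", {
  cfg <- tiny_config()
  terms <- terminology(tibble::tibble(canonical = "aids patient",
                                      category = "living with hiv"),
                       config = cfg)
  rep_phrase <- function(n) paste(rep("aids patient outcome", n), collapse = " ")
  tk <- tokenize_abstracts(make_abstracts(
    c(rep_phrase(5), rep_phrase(10), rep_phrase(15)), c(1989, 1989, 1989)
  ), cfg)
  agg <- aggregate_counts(count_term_occurrences(tk, terms), terms, 1989L)
  expect_equal(agg$absolute_tf, 30L)
  expect_equal(agg$abstract_df, 3L)
})

test_that("aggregation zero-fills terms absent everywhere", {
  cfg <- tiny_config()
  terms <- terminology(tibble::tibble(
    canonical = c("present term", "ghost term"), category = "x"
  ), config = cfg)
  tk <- tokenize_abstracts(make_abstracts("a present term here", 1989), cfg)
  agg <- aggregate_counts(count_term_occurrences(tk, terms), terms, c(1989L, 1990L))
  ghost <- agg[agg$term == "ghost term", ]
  expect_equal(ghost$absolute_tf, c(0L, 0L))
  expect_equal(ghost$abstract_df, c(0L, 0L))
  expect_equal(nrow(agg), 4L)  # complete term x year grid
})

test_that("aggregated counts equal an independent full-text scan on random corpora", {
  cfg <- preprocess_config()
  for (seed in 21:25) {
    corp <- random_small_corpus(seed)
    tk <- tokenize_abstracts(corp$abstracts, cfg)
    agg <- aggregate_counts(count_term_occurrences(tk, corp$terms),
                            corp$terms, unique(tk$year))
    for (r in seq_len(nrow(agg))) {
      rows <- which(tk$year == agg$year[r])
      brute <- vapply(rows, function(i) {
        oracle_phrase_count(tk$matching[[i]], agg$term[r])
      }, integer(1))
      expect_equal(agg$absolute_tf[r], sum(brute))
      expect_equal(agg$abstract_df[r], sum(brute > 0))
    }
  }
})
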