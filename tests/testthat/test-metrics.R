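test_that("vocabulary size is the total matching-stream word count per year", {
  cfg <- tiny_config()
  tk <- tokenize_abstracts(make_abstracts(
    c(paste(rep("word", 10), collapse = " "), paste(rep("token", 10), collapse = " ")),
    c(1989, 1989)
  ), cfg)
  ys <- year_summary(tk)
  expect_equal(ys$vocabulary_size, 20L)
  expect_equal(ys$n_abstracts, 2L)
})

test_that("the denominator can switch to the stop-word-filtered stream", {
  cfg <- tiny_config()
  tk <- tokenize_abstracts(make_abstracts("the epidemic of the decade", 1989), cfg)
  expect_equal(year_summary(tk)$vocabulary_size, 5L)
  expect_equal(year_summary(tk, stream = "discovery")$vocabulary_size, 2L)
})

test_that("vocabulary size equals a brute-force scan of the raw text", {
  cfg <- preprocess_config()
  for (seed in 31:33) {
    corp <- random_small_corpus(seed)
    tk <- tokenize_abstracts(corp$abstracts, cfg)
    ys <- year_summary(tk)
    for (r in seq_len(nrow(ys))) {
      texts <- corp$abstracts$text[corp$abstracts$year == ys$year[r]]
      expect_equal(ys$vocabulary_size[r], oracle_word_count(texts))
    }
  }
})

test_that("a paper-scale year lands vocabulary size in the hundreds of thousands", {
  spec <- paper_scale_spec(years = 1989L)
  corp <- generate_corpus(spec, seed = 11L)
  tk <- tokenize_abstracts(corp$abstracts, preprocess_config())
  ys <- year_summary(tk)
  expect_gte(ys$vocabulary_size, 1e5)
  expect_lte(ys$vocabulary_size, 1e6)
})

test_that("term frequency is the absolute count over the vocabulary size, relTF a million times that", {
  f <- term_frequency(30L, 600L)
  expect_equal(f$tf, 0.05)
  expect_equal(f$reltf, 50000)
  zero <- term_frequency(0L, 600L)
  expect_equal(zero$tf, 0)
  expect_equal(zero$reltf, 0)
  expect_error(term_frequency(1L, 0L), "positive")
  expect_error(term_frequency(-1L, 10L), "absolute_tf")
  expect_error(term_frequency(11L, 10L), "absolute_tf")
})

test_that("planted counts over planted totals reproduce tf exactly", {
  fx <- recovery_fixture()
  joined <- dplyr::inner_join(
    fx$fit$metrics,
    dplyr::inner_join(fx$corp$truth$term_year, fx$corp$truth$year_totals,
                      by = "year"),
    by = c("term", "year")
  )
  expect_identical(joined$tf, joined$planted_count / joined$total_tokens)
})

test_that("conference-year document frequency counts years of presence", {
  agg <- tibble::tibble(
    term = rep(c("always", "once", "thrice", "never"), each = 16),
    year = rep(1:16, times = 4),
    absolute_tf = 0L,
    abstract_df = c(rep(1L, 16),
                    c(1L, rep(0L, 15)),
                    as.integer(rep(1:16, 1) %in% c(1, 6, 16)),
                    rep(0L, 16))
  )
  ydf <- year_document_frequency(agg)
  expect_equal(ydf$year_df[ydf$term == "always"], 16L)
  expect_equal(ydf$year_df[ydf$term == "once"], 1L)
  expect_equal(ydf$year_df[ydf$term == "thrice"], 3L)
  expect_equal(ydf$year_df[ydf$term == "never"], 0L)
})

test_that("idf endpoints match the closed form: log 2 at full presence, log(1+N) at one year", {
  expect_equal(inverse_document_frequency(16, 16), log(2))
  expect_equal(inverse_document_frequency(1, 16), log(17))
  expect_equal(inverse_document_frequency(8, 16), log(3))
  expect_equal(inverse_document_frequency(16, 16, log_base = "10"), log10(2))
})

test_that("idf of a never-seen term is NA with a warning", {
  expect_warning(v <- inverse_document_frequency(c(0, 4), 16), "df 0")
  expect_true(is.na(v[1]))
  expect_equal(v[2], log(5))
})

test_that("idf decreases strictly in df and stays within its closed-form range", {
  for (n in c(1, 5, 16)) {
    v <- inverse_document_frequency(seq_len(n), n)
    if (n > 1) expect_true(all(diff(v) < 0))
    expect_true(all(v >= log(2) - 1e-12 & v <= log(1 + n) + 1e-12))
  }
})

test_that("tf-idf is the elementwise product", {
  expect_equal(tf_idf(0.05, log(2)), 0.05 * log(2))
  expect_equal(tf_idf(0, 3), 0)
  set.seed(1)
  tf <- runif(50)
  idf <- runif(50, 0.5, 3)
  expect_identical(tf_idf(tf, idf), tf * idf)
})

test_that("the trailing three-point mean matches hand arithmetic and leaves the head undefined", {
  expect_equal(moving_average(c(3, 6, 9)), c(NA, NA, 6))
  x <- c(5, 1, 9, 3, 7)
  got <- moving_average(x)
  expect_equal(got[3:5], c(mean(x[1:3]), mean(x[2:4]), mean(x[3:5])))
  expect_true(all(is.na(got[1:2])))
})

test_that("a constant series is invariant under smoothing, and short series warn", {
  expect_equal(moving_average(rep(4.2, 10))[3:10], rep(4.2, 8))
  expect_warning(out <- moving_average(c(1, 2)), "shorter")
  expect_true(all(is.na(out)))
})

test_that("smoothed values stay within the bounds of their window", {
  set.seed(99)
  for (rep in 1:10) {
    x <- runif(sample(3:12, 1), 0, 100)
    sm <- moving_average(x)
    for (t in 3:length(x)) {
      expect_gte(sm[t], min(x[(t - 2):t]) - 1e-12)
      expect_lte(sm[t], max(x[(t - 2):t]) + 1e-12)
    }
  }
})

test_that("the assembled metrics table is internally consistent on a planted corpus", {
  fx <- recovery_fixture()
  m <- fx$fit$metrics
  # relTF is exactly a million times tf
  expect_identical(m$reltf, m$tf * 1e6)
  # tfidf is exactly tf * idf wherever idf is defined
  def <- !is.na(m$idf)
  expect_identical(m$tfidf[def], m$tf[def] * m$idf[def])
  # tf summed over planted (non-overlapping) terms never exceeds 1
  per_year <- tapply(m$tf, m$year, sum)
  expect_true(all(per_year <= 1))
  # within one year, tf ratios equal absolute count ratios (denominator cancels)
  y1 <- m[m$year == m$year[1] & m$absolute_tf > 0, ]
  if (nrow(y1) >= 2) {
    expect_equal(y1$tf / y1$tf[1], y1$absolute_tf / y1$absolute_tf[1])
  }
  # moving average column is the per-term smoothing of the reltf column
  for (tm in unique(m$term)[1:3]) {
    series <- m[m$term == tm, ]
    series <- series[order(series$year), ]
    expect_equal(series$reltf_ma3, moving_average(series$reltf))
  }
})

test_that("terms never observed get idf NA and tfidf zero, with a warning", {
  cfg <- tiny_config()
  terms <- terminology(tibble::tibble(
    canonical = c("seen term", "ghost term"), category = "x"
  ), config = cfg)
  tk <- tokenize_abstracts(make_abstracts(
    c("the seen term today", "more filler text"), c(1989, 1990)
  ), cfg)
  agg <- aggregate_counts(count_term_occurrences(tk, terms), terms,
                          c(1989L, 1990L))
  expect_warning(m <- compute_metrics(agg, year_summary(tk), terms), "df 0")
  ghost <- m[m$term == "ghost term", ]
  expect_true(all(is.na(ghost$idf)))
  expect_equal(ghost$tfidf, c(0, 0))
  expect_equal(nrow(m), 4L)  # zero rows keep trend lines continuous
})
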