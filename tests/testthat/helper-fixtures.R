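# Shared fixtures, built in code. The larger ones are generated once per
# test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

make_abstracts <- function(texts, years, ids = NULL) {
  tibble::tibble(
    id = ids %||% sprintf("a%02d", seq_along(texts)),
    year = as.integer(years),
    text = texts
  )
}

# Config with a tiny fixed stoplist so examples are easy to reason about.
tiny_config <- function() {
  preprocess_config(
    stopwords = c("the", "a", "an", "of", "who", "have", "with"),
    symbol_map = c("hiv+" = "hiv positive"),
    plural_exceptions = c("aids", "msm", "men")
  )
}

# Small random corpus for property tests: a few years, a few abstracts,
# terms drawn from a reserved pool disjoint from the background alphabet
# and from each other (no nesting, so single-phrase oracles apply).
random_small_corpus <- function(seed) {
  pool <- list(
    list(phrase = "alpha omega", category = "c1"),
    list(phrase = "delta ray burst", category = "c1"),
    list(phrase = "quiet storm", category = "c2"),
    list(phrase = "lone word", category = "c2"),
    list(phrase = "redwood", category = "c3")
  )
  set.seed(seed * 1000L + 17L)
  n_years <- sample(2:3, 1)
  n_terms <- sample(2:5, 1)
  picked <- sample(pool, n_terms)
  planted <- lapply(picked, function(p) {
    p$counts <- sample(0:6, n_years, replace = TRUE)
    p
  })
  spec <- synthetic_spec(
    years = 2000L + seq_len(n_years),
    abstracts_per_year = sample(4:8, 1),
    mean_abstract_length = 30,
    background_vocab_size = 40L,
    planted_terms = planted
  )
  generate_corpus(spec, seed = seed)
}

# The default-scale exact-plant corpus used by the recovery checks.
recovery_fixture <- function() {
  cached("recovery", function() {
    corp <- generate_corpus(synthetic_spec(), seed = 424243L)
    fit <- suppressMessages(analyze_terms(corp$abstracts, corp$terms))
    list(corp = corp, fit = fit)
  })
}
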