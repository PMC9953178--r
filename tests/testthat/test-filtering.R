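test_that("a first-page hit passes at depth 1 on the bare-term variant", {
  be <- scripted_search_backend(list(
    zannies = list(rank = 1L, text = "alprazolam street names explained")))
  out <- google_filter("zannies", "alprazolam", be)
  expect_true(out$passed)
  expect_equal(out$first_hit_depth, 1L)
  expect_equal(out$matching_variant, "")
  expect_equal(be$n_calls(), 1L)  # early termination: later variants unsearched
})

test_that("variant order, per-variant depth, and the search budget are honored", {
  be <- scripted_search_backend(list(
    "zannies slang" = list(rank = 3L, text = "slang for alprazolam pills")))
  out <- google_filter("zannies", "alprazolam", be)
  expect_true(out$passed)
  expect_equal(out$first_hit_depth, 3L)  # depth within the matching variant
  expect_equal(out$matching_variant, "slang")
  expect_equal(be$n_calls(), 4L)  # "", pill, drug, then slang

  miss <- scripted_search_backend(list())
  out2 <- google_filter("nonsense", "alprazolam", miss)
  expect_false(out2$passed)
  expect_true(is.na(out2$first_hit_depth))
  expect_true(is.na(out2$matching_variant))
  expect_equal(miss$n_calls(), 4L)  # bound: one search per variant
})

test_that("hits beyond max_depth do not count; matching is case-insensitive substring", {
  be <- scripted_search_backend(list(
    deep = list(rank = 5L, text = "Alprazolam-based medication guide")))
  shallow <- google_filter("deep", "alprazolam", be,
                           google_filter_config(max_depth = 3L))
  expect_false(shallow$passed)
  deep <- google_filter("deep", "alprazolam",
                        scripted_search_backend(list(
                          deep = list(rank = 5L, text = "Alprazolam-based medication guide"))),
                        google_filter_config(max_depth = 10L))
  expect_true(deep$passed)   # substring match tolerates suffixes and case
  expect_equal(deep$first_hit_depth, 5L)

  ww <- google_filter("deep", "alprazolam",
                      scripted_search_backend(list(
                        deep = list(rank = 5L, text = "Alprazolam-based medication guide"))),
                      google_filter_config(match_mode = "whole-word"))
  expect_true(ww$passed)     # hyphen is a word boundary
})

test_that("memoization makes warm-cache runs traffic-free and outcome-identical", {
  pages <- list("term1 drug" = list(rank = 2L, text = "about alprazolam"))
  cold_be <- scripted_search_backend(pages)
  cache <- new_search_cache()
  cold <- google_filter("term1", "alprazolam", cold_be, cache = cache)
  calls_cold <- cold_be$n_calls()
  expect_equal(calls_cold, 3L)  # "", pill, then drug hits

  warm_be <- scripted_search_backend(pages)
  warm <- google_filter("term1", "alprazolam", warm_be, cache = cache)
  expect_identical(warm, cold)
  expect_equal(warm_be$n_calls(), 0L)  # zero backend calls when warm
})

test_that("the cache file round-trips bit-exactly, including misses and bare variant", {
  cache <- new_search_cache()
  be <- scripted_search_backend(list(
    hit = list(rank = 4L, text = "alprazolam info")))
  google_filter("hit", "alprazolam", be, cache = cache)
  google_filter("missy", "alprazolam", scripted_search_backend(list()),
                cache = cache)
  p1 <- tempfile(); p2 <- tempfile()
  write_search_cache(cache, p1)
  write_search_cache(read_search_cache(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # misses are recorded as "-"
  expect_true(any(grepl("\t-$", readLines(p1))))
})

test_that("the drug-name filter removes other drugs' generic names only", {
  idx <- c("alprazolam", "lorazepam", "heroin")
  expect_false(drug_name_filter("lorazepam", "alprazolam", idx))
  expect_true(drug_name_filter("alprazolam", "alprazolam", idx))  # self passes
  expect_true(drug_name_filter("zannies", "alprazolam", idx))
})

test_that("the frequency filter is strictly greater-than", {
  expect_false(frequency_filter(1L, 1L))  # generated only once: removed
  expect_true(frequency_filter(2L, 1L))
  expect_true(frequency_filter(17L, 15L))
  expect_false(frequency_filter(15L, 15L))
  expect_error(frequency_filter(1L, 0L), class = "slanglex_precondition_error")
})

test_that("schemes intersect predicates and shrink monotonically", {
  w <- get_world("tiny")
  lex <- load_seed_lexicon(w$paths$seed_lexicon)
  sel <- term_selection(lex, lex$index_terms[1L])
  gen <- run_iterations(sel, mock_completion_backend(w),
                        n_iterations = 60L, rng_seed = 3L)
  sb <- mock_search_backend(w)
  cache <- new_search_cache()
  pos <- function(scheme) {
    f <- apply_scheme(gen$tallies, scheme, lex$index_terms, sb,
                      cache = cache)
    f$term[f$positive]
  }
  all_terms <- pos(character())          # empty scheme: everything positive
  expect_setequal(all_terms, gen$tallies$term)
  p_dn <- pos("drug_name")
  p_dng <- pos(c("drug_name", "google"))
  p_all <- pos(c("drug_name", "google", "frequency"))
  expect_true(all(p_dn %in% all_terms))
  expect_true(all(p_dng %in% p_dn))
  expect_true(all(p_all %in% p_dng))
})

test_that("requesting the search filter without a backend is a configuration error", {
  t <- data.frame(index_term = "a", term = "b", frequency = 2L,
                  token_count = 1L, stringsAsFactors = FALSE)
  expect_error(apply_scheme(t, c("drug_name", "google")),
               class = "slanglex_config_error")
  expect_error(apply_scheme(t, "bogus"), class = "slanglex_config_error")
  # no backend, no google in scheme: allowed, google columns NA
  f <- apply_scheme(t, "drug_name")
  expect_true(is.na(f$passes_google))
  expect_true(f$positive)
})

test_that("filter reports round-trip through TSV including the bare variant", {
  be <- scripted_search_backend(list(zan = list(rank = 1L, text = "alpha info")))
  t <- data.frame(index_term = c("alpha", "alpha"), term = c("zan", "nix"),
                  frequency = c(3L, 1L), token_count = c(1L, 1L),
                  stringsAsFactors = FALSE)
  f <- apply_scheme(t, c("drug_name", "google"), "alpha", be)
  path <- tempfile(fileext = ".tsv")
  write_filter_report(f, path)
  f2 <- read_filter_report(path)
  expect_equal(f2$matching_variant, f$matching_variant)
  expect_equal(f2$passes_google, f$passes_google)
  expect_equal(f2$first_hit_depth, f$first_hit_depth)
})
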