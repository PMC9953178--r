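# Reference values for the worked examples below are the published
# evaluation numbers for the two manually labeled drugs (alprazolam and
# fentanyl): the all-generated baseline counts and the seed-membership
# baseline recall.

test_that("the all-generated baseline reproduces the printed metric values", {
  cm_alp <- structure(list(tp = 269L, fp = 750L, fn = 0L, tn = 0L),
                      class = "slanglex_confusion")
  m <- metrics(cm_alp)
  expect_equal(round(m$precision, 3), 0.264)
  expect_equal(m$recall, 1.000)
  expect_equal(m$f1, 0.418, tolerance = 0.002 / 0.418)
  expect_equal(m$f2, 0.642, tolerance = 0.002 / 0.642)

  cm_fen <- structure(list(tp = 314L, fp = 1114L, fn = 0L, tn = 0L),
                      class = "slanglex_confusion")
  m2 <- metrics(cm_fen)
  expect_equal(round(m2$precision, 3), 0.220)
  expect_equal(m2$recall, 1.000)
  expect_equal(m2$f1, 0.361, tolerance = 0.002 / 0.361)
  expect_equal(m2$f2, 0.585, tolerance = 0.002 / 0.585)
})

test_that("the seed-membership baseline trades recall for perfect precision", {
  # 269 labeled synonyms of which 221 were novel: only 48 already known
  cm <- structure(list(tp = 48L, fp = 0L, fn = 221L, tn = 0L),
                  class = "slanglex_confusion")
  m <- metrics(cm)
  expect_equal(m$precision, 1.000)
  expect_equal(round(m$recall, 3), 0.178)
})

test_that("confusion matrices handle identity and degenerate cases", {
  labs <- data.frame(term = c("a", "b", "c", "d"),
                     label = c("synonym", "synonym", "non-synonym", "non-synonym"),
                     stringsAsFactors = FALSE)
  # predict exactly the labeled synonyms: perfect
  cm <- confusion(c("a", "b"), labs)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(2L, 0L, 0L, 2L))
  # all-positive predictor: recall 1, FN 0
  cm2 <- confusion(labs$term, labs)
  expect_equal(cm2$fn, 0L)
  expect_equal(metrics(cm2)$recall, 1.0)
  # empty prediction against empty labels: all-zero matrix
  cm3 <- confusion(character(), labs[0, ])
  expect_equal(c(cm3$tp, cm3$fp, cm3$fn, cm3$tn), rep(0L, 4L))
  # unlabeled evaluated terms are a data error naming them
  expect_error(confusion(c("a", "zzz"), labs), "zzz",
               class = "slanglex_data_error")
})

test_that("metrics are absent (NA) when a denominator is zero", {
  cm <- structure(list(tp = 0L, fp = 0L, fn = 3L, tn = 5L),
                  class = "slanglex_confusion")
  m <- metrics(cm)
  expect_true(is.na(m$precision))
  expect_equal(m$recall, 0)
  expect_true(is.na(m$f1))

  cm2 <- structure(list(tp = 1L, fp = 1L, fn = 1L, tn = 0L),
                   class = "slanglex_confusion")
  m2 <- metrics(cm2)
  expect_equal(c(m2$precision, m2$recall, m2$f1, m2$f2), rep(0.5, 4L))
})

test_that("F2 outweighs recall: ordering follows precision vs recall", {
  set.seed(42)
  for (i in 1:200) {
    tp <- sample(0:50, 1L); fp <- sample(0:50, 1L); fn <- sample(0:50, 1L)
    cm <- structure(list(tp = tp, fp = fp, fn = fn, tn = 0L),
                    class = "slanglex_confusion")
    m <- metrics(cm)
    if (any(is.na(c(m$precision, m$recall, m$f1, m$f2)))) next
    if (m$recall > m$precision) expect_gt(m$f2, m$f1)
    if (m$recall < m$precision) expect_lt(m$f2, m$f1)
    if (m$recall == m$precision) {
      expect_equal(m$f1, m$precision)
      expect_equal(m$f2, m$precision)
    }
  }
})

test_that("scheme comparison matches a brute-force oracle on a synthetic run", {
  w <- get_world("tiny")
  lex <- load_seed_lexicon(w$paths$seed_lexicon)
  lex_full <- load_seed_lexicon(w$paths$seed_lexicon, seed_categories(),
                                drop_multiword_known = FALSE)
  it <- lex$index_terms[2L]
  sel <- term_selection(lex, it)
  gen <- run_iterations(sel, mock_completion_backend(w),
                        n_iterations = 80L, rng_seed = 21L)
  flags <- apply_scheme(gen$tallies, c("drug_name", "google"),
                        lex$index_terms, mock_search_backend(w))
  labels <- read_labels(w$paths$labels)
  labels <- labels[labels$index_term == it, ]

  tab <- scheme_comparison(gen$tallies, flags, labels, lex_full)
  expect_equal(tab$scheme,
               c("all_generated", "seed_membership", "drug_name",
                 "drug_name+frequency", "drug_name+google",
                 "drug_name+frequency+google"))

  # independent recomputation from raw sets
  evaluated <- unique(gen$tallies$term)
  syn <- intersect(evaluated, labels$term[labels$label == "synonym"])
  f <- flags[match(evaluated, flags$term), ]
  oracle_preds <- list(
    evaluated,
    evaluated[seed_membership(lex_full, evaluated)],
    evaluated[f$passes_drug_name],
    evaluated[f$passes_drug_name & f$passes_frequency],
    evaluated[f$passes_drug_name & f$passes_google],
    evaluated[f$passes_drug_name & f$passes_frequency & f$passes_google])
  for (i in seq_along(oracle_preds)) {
    pred <- oracle_preds[[i]]
    tp <- length(intersect(pred, syn))
    expect_equal(tab$tp[i], tp)
    expect_equal(tab$fp[i], length(pred) - tp)
    expect_equal(tab$fn[i], length(syn) - tp)
    if (length(pred) > 0L)
      expect_equal(tab$precision[i], tp / length(pred))
    expect_equal(tab$recall[i], tp / length(syn))
  }
  # all-positive row: recall 1 by construction
  expect_equal(tab$recall[1L], 1.0)
  expect_error(scheme_comparison(gen$tallies, flags, labels[0, ], lex_full),
               class = "slanglex_data_error")
})

test_that("depth and frequency histograms match direct counting", {
  w <- get_world("tiny")
  lex <- load_seed_lexicon(w$paths$seed_lexicon)
  it <- lex$index_terms[1L]
  gen <- run_iterations(term_selection(lex, it), mock_completion_backend(w),
                        n_iterations = 60L, rng_seed = 8L)
  flags <- apply_scheme(gen$tallies, c("drug_name", "google"),
                        lex$index_terms, mock_search_backend(w))
  labels <- read_labels(w$paths$labels)
  labels <- labels[labels$index_term == it, ]

  dh <- depth_histogram(flags, labels)
  hit <- flags[!is.na(flags$first_hit_depth), ]
  lab <- labels$label[match(hit$term, labels$term)]
  for (j in seq_len(nrow(dh))) {
    d <- dh$depth[j]
    expect_equal(dh$count_synonym[j],
                 sum(hit$first_hit_depth == d & lab == "synonym"))
    expect_equal(dh$count_nonsynonym[j],
                 sum(hit$first_hit_depth == d & lab == "non-synonym"))
  }
  expect_equal(sum(dh$count_synonym) + sum(dh$count_nonsynonym), nrow(hit))

  # unlabeled mode: single count per depth
  dh2 <- depth_histogram(flags)
  expect_equal(sum(dh2$count), nrow(hit))
  expect_equal(depth_histogram(flags[0, ]),
               data.frame(depth = integer(), count = integer()))

  fh <- frequency_histogram(gen$tallies, labels, flags)
  fh_g <- frequency_histogram(gen$tallies, labels, flags, with_google = TRUE)
  # restriction can only shrink counts
  common <- intersect(fh$frequency, fh_g$frequency)
  expect_true(all(fh_g$count_synonym[match(common, fh_g$frequency)] <=
                    fh$count_synonym[match(common, fh$frequency)]))
  kept <- flags$passes_drug_name
  expect_equal(sum(fh$count_synonym) + sum(fh$count_nonsynonym), sum(kept))

  one <- frequency_histogram(
    data.frame(index_term = "x", term = "solo", frequency = 5L,
               token_count = 1L, stringsAsFactors = FALSE))
  expect_equal(one, data.frame(frequency = 5L, count = 1L))
})

test_that("novelty accounts obey the chain inequality and exclude known terms", {
  w <- get_world("tiny")
  lex <- load_seed_lexicon(w$paths$seed_lexicon)
  lex_full <- load_seed_lexicon(w$paths$seed_lexicon, seed_categories(),
                                drop_multiword_known = FALSE)
  it <- lex$index_terms[3L]
  gen <- run_iterations(term_selection(lex, it), mock_completion_backend(w),
                        n_iterations = 50L, rng_seed = 13L)
  flags <- apply_scheme(gen$tallies, c("drug_name", "google"),
                        lex$index_terms, mock_search_backend(w))
  acc <- novelty_account(gen$tallies, flags$term[flags$positive], lex_full)
  expect_lte(acc$ungs, acc$gpt3_synonyms)
  expect_lte(acc$gpt3_synonyms, acc$unique_generated)
  expect_lte(acc$unique_generated, acc$total_generated)
  # novel = positive and absent from the full seed lexicon (any category,
  # any index term); the queried index term itself can never be novel
  pos <- flags$term[flags$positive]
  expect_equal(acc$ungs, sum(!seed_membership(lex_full, pos)))
  expect_false(it %in% pos[!seed_membership(lex_full, pos)])
})

test_that("sweep summaries conserve totals across marginals", {
  accounts <- list(
    list(params = list(temperature = 0, template = "plain"),
         account = data.frame(index_term = "x", total_generated = 10L,
                              unique_generated = 5L, gpt3_synonyms = 4L,
                              ungs = 2L)),
    list(params = list(temperature = 1, template = "plain"),
         account = data.frame(index_term = "x", total_generated = 10L,
                              unique_generated = 8L, gpt3_synonyms = 6L,
                              ungs = 5L)),
    list(params = list(temperature = 0, template = "counterexample"),
         account = data.frame(index_term = "x", total_generated = 10L,
                              unique_generated = 4L, gpt3_synonyms = 3L,
                              ungs = 1L)),
    list(params = list(temperature = 1, template = "counterexample"),
         account = data.frame(index_term = "x", total_generated = 10L,
                              unique_generated = 7L, gpt3_synonyms = 5L,
                              ungs = 4L)))
  tab <- sweep_summary(accounts)
  expect_equal(nrow(tab), 4L)
  marg <- sweep_marginal(tab, "temperature")
  expect_equal(sum(marg$ungs), sum(tab$ungs))
  expect_equal(marg$ungs[marg$level == 1], 5L + 4L)
  expect_error(sweep_marginal(tab, "nope"),
               class = "slanglex_precondition_error")
})
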