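# Synthetic worlds: a self-contained seed lexicon, controlled list, planted
# ground truth, and deterministic mock completion/search backends, so the
# whole pipeline runs and is testable with no credential or network access.

#' Specification of a synthetic world
#'
#' A world has `n_index_terms` drugs, each with `n_planted` true synonyms
#' (the first `n_seed` of which are in the seed lexicon's usable categories,
#' plus one extra in the slang-dictionary category when available), a shared
#' pool of `n_distractors` non-synonym terms, and the other drugs' generic
#' names. The mock model generates from a Zipf-skewed categorical
#' distribution per index term, ranked synonyms-first so that true synonyms
#' are generated more often than distractors — the skewed-frequency structure
#' real generations show. Each planted synonym gets a search hit on one
#' query variant at a geometrically decaying depth (truncated at
#' `max_depth`); distractors hit only at the false-positive rate.
#'
#' @param n_index_terms Number of drugs (default 5).
#' @param n_planted True synonyms per drug (default 30).
#' @param n_seed How many planted synonyms are seed-lexicon usable entries
#'   (default 6; must be at least 3 for prompt eligibility).
#' @param n_distractors Shared distractor vocabulary size (default 200).
#' @param zipf_s Zipf skew exponent of the generation distribution (default
#'   1.0).
#' @param items_per_completion List items per completion (default 7: three
#'   seeds prompt a ten-item list).
#' @param max_depth Search depth budget (default 10).
#' @param depth_p Geometric parameter for planted hit depths (default 0.5).
#' @param fp_rate Probability a distractor gets a spurious search hit
#'   (default 0).
#' @param malformed_rate Probability a completion trails off into prose
#'   (default 0), exercising the parser's stop rule.
#' @param rng_seed Integer seed fixing the entire world (default 17).
#' @return List of class `slanglex_world_spec`.
#' @export
world_spec <- function(n_index_terms = 5L, n_planted = 30L, n_seed = 6L,
                       n_distractors = 200L, zipf_s = 1.0,
                       items_per_completion = 7L, max_depth = 10L,
                       depth_p = 0.5, fp_rate = 0, malformed_rate = 0,
                       rng_seed = 17L) {
  if (n_seed < 3L)
    stop_precondition("n_seed must be >= 3 so index terms are prompt-eligible")
  if (n_planted < n_seed)
    stop_precondition("n_planted (%d) must be >= n_seed (%d)", n_planted, n_seed)
  vocab <- n_planted + (n_index_terms - 1L) + n_distractors
  if (items_per_completion > vocab)
    stop_precondition("items_per_completion (%d) exceeds vocabulary size (%d)",
                      items_per_completion, vocab)
  if (fp_rate < 0 || fp_rate > 1)
    stop_precondition("fp_rate must be in [0, 1]")
  structure(list(n_index_terms = as.integer(n_index_terms),
                 n_planted = as.integer(n_planted),
                 n_seed = as.integer(n_seed),
                 n_distractors = as.integer(n_distractors),
                 zipf_s = as.numeric(zipf_s),
                 items_per_completion = as.integer(items_per_completion),
                 max_depth = as.integer(max_depth),
                 depth_p = as.numeric(depth_p),
                 fp_rate = as.numeric(fp_rate),
                 malformed_rate = as.numeric(malformed_rate),
                 rng_seed = as.integer(rng_seed)),
            class = "slanglex_world_spec")
}

# pronounceable unique names from consonant-vowel syllables; deterministic
# under the caller's RNG state
make_names <- function(n, n_syl, taken = character()) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    m <- (n - length(out)) * 2L + 10L
    cand <- vapply(seq_len(m), function(i) {
      paste0(paste0(sample(cons, n_syl, replace = TRUE),
                    sample(vow, n_syl, replace = TRUE)), collapse = "")
    }, character(1L))
    cand <- setdiff(unique(cand), c(taken, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

world_files <- function(dir) {
  list(spec = file.path(dir, "world.yaml"),
       seed_lexicon = file.path(dir, "seed_lexicon.csv"),
       controlled = file.path(dir, "controlled_substances.txt"),
       hit_counts = file.path(dir, "hit_counts.tsv"),
       labels = file.path(dir, "truth_labels.csv"),
       gen_table = file.path(dir, "gen_table.tsv"),
       search_index = file.path(dir, "search_index.tsv"))
}

#' Build a synthetic world on disk
#'
#' Writes the seed lexicon, controlled-substance list, hit-count table,
#' truth labels (planted synonyms labeled `synonym`, everything else
#' `non-synonym`), the per-drug generation distribution, and the search
#' index. The same spec (including its seed) always produces identical
#' files.
#'
#' @param spec A [world_spec()].
#' @param dir Output directory (created if needed).
#' @return The loaded world (see [load_world()]), invisibly.
#' @export
build_world <- function(spec, dir) {
  stopifnot(inherits(spec, "slanglex_world_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- world_files(dir)
  set.seed(spec$rng_seed)

  index_terms <- sort(make_names(spec$n_index_terms, 3L))
  taken <- index_terms
  planted <- list()
  for (it in index_terms) {
    planted[[it]] <- make_names(spec$n_planted, 2L, taken)
    taken <- c(taken, planted[[it]])
  }
  distractors <- make_names(spec$n_distractors, 2L, taken)

  # seed lexicon: first n_seed planted synonyms across the usable categories,
  # one extra in ud_slang when available, and a multi-word known phrase that
  # the single-word rule must drop
  usable <- usable_seed_categories()
  lex <- data.frame(index_term = index_terms, stringsAsFactors = FALSE)
  for (cat in seed_categories()) lex[[cat]] <- ""
  for (i in seq_along(index_terms)) {
    it <- index_terms[i]
    seeds <- planted[[it]][seq_len(spec$n_seed)]
    cats <- rep_len(usable, spec$n_seed)
    for (cat in usable) {
      cell <- seeds[cats == cat]
      if (cat == "known")
        cell <- c(cell, paste(seeds[1L], "works great"))
      lex[[cat]][i] <- paste(cell, collapse = "|")
    }
    if (spec$n_planted > spec$n_seed)
      lex$ud_slang[i] <- planted[[it]][spec$n_seed + 1L]
  }
  utils::write.table(lex, paths$seed_lexicon, sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")

  extra <- make_names(2L, 3L, c(taken, distractors))
  writeLines(c("# synthetic controlled-substance list", index_terms, extra),
             paths$controlled, useBytes = TRUE)

  n_wide <- max(1L, ceiling(0.25 * spec$n_index_terms))
  hits <- integer(spec$n_index_terms)
  for (i in seq_len(spec$n_index_terms)) {
    hits[i] <- if (i <= n_wide) 12000L + 5000L * (n_wide - i + 1L)
    else as.integer(8000 %/% (i - n_wide + 1L))
  }
  write_tsv(data.frame(index_term = index_terms, hits = hits), paths$hit_counts)

  labels <- do.call(rbind, lapply(index_terms, function(it) {
    terms <- c(planted[[it]], setdiff(index_terms, it), distractors)
    data.frame(index_term = it, term = terms,
               label = c(rep("synonym", spec$n_planted),
                         rep("non-synonym", length(terms) - spec$n_planted)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(labels, paths$labels, sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")

  # generation distribution: synonyms ranked first (the common street names),
  # then the other drugs' generic names, then the long distractor tail
  gen <- do.call(rbind, lapply(index_terms, function(it) {
    vocab <- c(planted[[it]][seq_len(min(3L, spec$n_planted))],
               setdiff(index_terms, it),
               if (spec$n_planted > 3L) planted[[it]][4:spec$n_planted],
               distractors)
    data.frame(index_term = it, term = vocab, rank = seq_along(vocab),
               stringsAsFactors = FALSE)
  }))
  write_tsv(gen, paths$gen_table)

  variants <- c("", "pill", "drug", "slang")
  depth_w <- spec$depth_p * (1 - spec$depth_p)^(0:(spec$max_depth - 1L))
  plant_rows <- do.call(rbind, lapply(index_terms, function(it) {
    data.frame(term = planted[[it]],
               variant = sample(variants, spec$n_planted, replace = TRUE),
               depth = sample.int(spec$max_depth, spec$n_planted,
                                  replace = TRUE, prob = depth_w),
               mentions = it, stringsAsFactors = FALSE)
  }))
  fp <- stats::runif(spec$n_distractors) < spec$fp_rate
  fp_rows <- if (any(fp)) {
    data.frame(term = distractors[fp],
               variant = sample(variants, sum(fp), replace = TRUE),
               depth = sample.int(spec$max_depth, sum(fp), replace = TRUE,
                                  prob = depth_w),
               mentions = paste(index_terms, collapse = "|"),
               stringsAsFactors = FALSE)
  } else NULL
  search_index <- rbind(plant_rows, fp_rows)
  search_index <- search_index[order(search_index$term, search_index$variant), ,
                               drop = FALSE]
  write_tsv(search_index, paths$search_index)

  yaml::write_yaml(unclass(spec), paths$spec)
  invisible(load_world(dir))
}

#' Load a synthetic world from disk
#'
#' @param dir Directory written by [build_world()].
#' @return Object of class `slanglex_world`: the spec, file paths, the
#'   per-drug generation tables (with Zipf probabilities attached), and the
#'   search index.
#' @export
load_world <- function(dir) {
  paths <- world_files(dir)
  if (!file.exists(paths$spec)) stop_format("no world.yaml under %s", dir)
  sp <- yaml::read_yaml(paths$spec)
  spec <- do.call(world_spec, sp)
  gen <- read_tsv(paths$gen_table, colClasses = c(index_term = "character",
                                                 term = "character",
                                                 rank = "integer"))
  gen_tables <- split(gen, gen$index_term)
  gen_tables <- lapply(gen_tables, function(g) {
    g <- g[order(g$rank), , drop = FALSE]
    w <- g$rank^(-spec$zipf_s)
    g$prob <- w / sum(w)
    rownames(g) <- NULL
    g
  })
  search_index <- read_tsv(paths$search_index,
                           colClasses = c(term = "character",
                                          variant = "character",
                                          depth = "integer",
                                          mentions = "character"))
  search_index$variant[is.na(search_index$variant)] <- ""
  structure(list(spec = spec, dir = dir, paths = paths, gen = gen_tables,
                 search = search_index),
            class = "slanglex_world")
}

extract_prompt_index_term <- function(prompt) {
  for (pat in c("but these are synonyms for (.+?):",
                "ways to say (.+?):",
                "these are not synonyms for (.+?):")) {
    m <- regmatches(prompt, regexec(pat, prompt))[[1L]]
    if (length(m) == 2L) return(m[2L])
  }
  NA_character_
}

#' Deterministic mock completion backend over a world
#'
#' Continues the prompt's numbered list with `items_per_completion` draws
#' from the prompted drug's generation distribution. Temperature is honored
#' qualitatively: at 0 the top-ranked items are returned deterministically;
#' above 0, items are sampled with weights `p^(1/temperature)`, so higher
#' temperature disperses generation over the tail — the monotone diversity
#' knob the sweep harness needs, not a faithful model mechanism. Frequency
#' and presence penalties are accepted but have no behavioral effect.
#' Draws consume the caller's RNG stream, so runs seeded per iteration are
#' reproducible and resumable.
#'
#' @param world A `slanglex_world`.
#' @param quota Number of completions before the backend signals
#'   [quota_error()] (default unlimited); used to exercise checkpoint/resume.
#' @param malformed_rate Override the world's prose-trailing rate.
#' @return A completion backend whose `n_calls()` reports usage.
#' @export
mock_completion_backend <- function(world, quota = Inf, malformed_rate = NULL) {
  stopifnot(inherits(world, "slanglex_world"))
  rate <- malformed_rate %||% world$spec$malformed_rate
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  complete <- function(prompt, params) {
    env$calls <- env$calls + 1L
    if (env$calls > quota) quota_error("mock completion quota exhausted")
    it <- extract_prompt_index_term(prompt)
    if (is.na(it) || is.null(world$gen[[it]])) return("")
    g <- world$gen[[it]]
    m <- regmatches(prompt, regexec("([0-9]+)[.)][ \t]*$", prompt))[[1L]]
    next_index <- if (length(m) == 2L) as.integer(m[2L]) else 4L
    k <- min(world$spec$items_per_completion, nrow(g))
    items <- if (params$temperature <= 0) {
      g$term[seq_len(k)]
    } else {
      g$term[sample.int(nrow(g), k, prob = g$prob^(1 / params$temperature))]
    }
    prose <- rate > 0 && stats::runif(1L) < rate
    if (prose) items <- items[seq_len(max(1L, k %/% 3L))]
    lines <- c(paste0(" ", items[1L]),
               if (length(items) > 1L)
                 sprintf("%d. %s", next_index + seq_len(length(items) - 1L),
                         items[-1L]))
    out <- paste(lines, collapse = "\n")
    if (prose)
      out <- paste0(out, "\n\nHope this list of street names is useful!")
    out
  }
  backend <- new_completion_backend(complete, name = "mock")
  backend$n_calls <- function() env$calls
  backend
}

#' Deterministic mock search backend over a world
#'
#' For a query (term, or term plus an appended keyword), returns
#' `max_results` synthetic results. A planted synonym's designated variant
#' carries its index term in the snippet at the drawn depth; every other
#' result (and every other query) mentions no drug name, apart from
#' distractors planted as false positives. Query-time behavior uses no RNG,
#' so result order is stable.
#'
#' @param world A `slanglex_world`.
#' @param quota Searches before [quota_error()] (default unlimited).
#' @return A search backend whose `n_calls()` reports usage.
#' @export
mock_search_backend <- function(world, quota = Inf) {
  stopifnot(inherits(world, "slanglex_world"))
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  idx <- world$search
  search <- function(query, max_results) {
    env$calls <- env$calls + 1L
    if (env$calls > quota) quota_error("mock search quota exhausted")
    m <- regmatches(query, regexec("^(.*) (pill|drug|slang)$", query))[[1L]]
    if (length(m) == 3L) {
      term <- m[2L]; variant <- m[3L]
    } else {
      term <- query; variant <- ""
    }
    titles <- sprintf("Page %d matching '%s'", seq_len(max_results), query)
    snippets <- sprintf("— nothing of note here, item %d —", seq_len(max_results))
    row <- idx[idx$term == term & idx$variant == variant, , drop = FALSE]
    if (nrow(row) >= 1L && row$depth[1L] <= max_results) {
      who <- gsub("|", ", ", row$mentions[1L], fixed = TRUE)
      snippets[row$depth[1L]] <-
        sprintf("Glossary of street names covering %s among other entries.", who)
    }
    data.frame(title = titles, snippet = snippets, stringsAsFactors = FALSE)
  }
  backend <- new_search_backend(search, name = "mock")
  backend$n_calls <- function() env$calls
  backend
}

#' @export
print.slanglex_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d index terms x %d planted synonyms, %d distractors (fp rate %.2f) at %s\n",
              x$spec$n_index_terms, x$spec$n_planted, x$spec$n_distractors,
              x$spec$fp_rate, x$dir))
  invisible(x)
}
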