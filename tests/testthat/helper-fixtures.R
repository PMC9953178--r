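# Shared fixtures: worlds are built once per test run and memoized by name.

.worlds <- new.env(parent = emptyenv())

# small world for unit tests; spec-default world for end-to-end checks
get_world <- function(name = "tiny") {
  if (!is.null(.worlds[[name]])) return(.worlds[[name]])
  spec <- switch(name,
    tiny = world_spec(n_index_terms = 3L, n_planted = 8L, n_seed = 4L,
                      n_distractors = 40L, rng_seed = 17L),
    default = world_spec(),
    fp = world_spec(fp_rate = 0.2, rng_seed = 17L),
    minimal = world_spec(n_index_terms = 1L, n_planted = 3L, n_seed = 3L,
                         n_distractors = 0L, items_per_completion = 3L,
                         rng_seed = 17L),
    stop("unknown fixture world: ", name))
  dir <- file.path(tempdir(), paste0("slanglex_world_", name))
  .worlds[[name]] <- build_world(spec, dir)
  .worlds[[name]]
}

world_config <- function(world, out_dir, n_iterations = 50L, rng_seed = 42L,
                         ...) {
  pipeline_config(seed_lexicon = world$paths$seed_lexicon,
                  controlled = world$paths$controlled,
                  hit_counts = world$paths$hit_counts,
                  labels = world$paths$labels,
                  world = world$dir, out_dir = out_dir,
                  n_iterations = n_iterations, rng_seed = rng_seed, ...)
}

# minimal RedMed-style seed table written as plain CSV
write_seed_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

seed_csv_header <- paste("index_term", "known", "edOne", "edTwo",
                         "misspellingPhon", "pillMark", "google_ms",
                         "google_title", "google_snippet", "ud_slang",
                         sep = ",")

# scripted search backend: `pages` maps query -> list of (rank, text) hits;
# every other result slot is inert filler
scripted_search_backend <- function(pages) {
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  backend <- new_search_backend(function(query, max_results) {
    env$calls <- env$calls + 1L
    titles <- sprintf("title %d", seq_len(max_results))
    snippets <- sprintf("filler %d", seq_len(max_results))
    hit <- pages[[query]]
    if (!is.null(hit) && hit$rank <= max_results) snippets[hit$rank] <- hit$text
    data.frame(title = titles, snippet = snippets, stringsAsFactors = FALSE)
  }, name = "scripted")
  backend$n_calls <- function() env$calls
  backend
}

constant_completion_backend <- function(text) {
  new_completion_backend(function(prompt, params) text, name = "constant")
}

# pooled confusion over the generated (evaluated) terms of a run
pooled_confusion <- function(flags, labels) {
  tp <- fp <- fn <- 0L
  for (it in unique(flags$index_term)) {
    f <- flags[flags$index_term == it, , drop = FALSE]
    lab <- labels[labels$index_term == it & labels$term %in% f$term, ,
                  drop = FALSE]
    cm <- confusion(f$term[f$positive], lab)
    tp <- tp + cm$tp; fp <- fp + cm$fp; fn <- fn + cm$fn
  }
  list(tp = tp, fp = fp, fn = fn,
       precision = tp / (tp + fp), recall = tp / (tp + fn))
}
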