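# Pipeline orchestration: configuration, end-to-end runs (generate -> filter
# -> lexicon), checkpoint/resume, the run manifest, and the parameter sweep.

#' Pipeline configuration
#'
#' Collects every knob of an end-to-end run. Mock backends are built from a
#' synthetic world directory (`world`); live backends are out of band — they
#' must be constructed by the caller (credentials via environment variables,
#' never via the config file) and passed to [run_pipeline()] directly.
#'
#' @param seed_lexicon Path to the seed lexicon table.
#' @param controlled Path to the controlled-substance name list.
#' @param out_dir Output directory for logs, reports, lexicon and manifest.
#' @param hit_counts Optional path to the hit-count TSV.
#' @param labels Optional path to a manual-label CSV.
#' @param world Optional synthetic-world directory providing mock backends.
#' @param backend `"mock"` or `"live"`.
#' @param n_iterations Iterations per index term (default 1000, the
#'   final-run setting; scale down for experiments).
#' @param params [query_params()] or a plain list of its arguments.
#' @param google [google_filter_config()] or a plain list of its arguments.
#' @param scheme Filter scheme (default `c("drug_name", "google")`, the
#'   final-lexicon scheme).
#' @param freq_threshold Frequency-filter threshold (default 1).
#' @param rng_seed Integer seed for all sampling (default 1).
#' @param k_seeds Seeds per prompt (default 3).
#' @param counterexamples Optional 4 counterexample terms (selects the
#'   counterexample template).
#' @param cutoff Widely-discussed hit cutoff (default 10000).
#' @param delim Within-cell delimiter of the seed lexicon (default `"|"`).
#' @param cache_file Search-cache path (default
#'   `file.path(out_dir, "search_cache.tsv")`).
#' @return List of class `slanglex_config`.
#' @export
pipeline_config <- function(seed_lexicon, controlled, out_dir,
                            hit_counts = NULL, labels = NULL, world = NULL,
                            backend = c("mock", "live"),
                            n_iterations = 1000L, params = query_params(),
                            google = google_filter_config(),
                            scheme = c("drug_name", "google"),
                            freq_threshold = 1L, rng_seed = 1L, k_seeds = 3L,
                            counterexamples = NULL, cutoff = 10000L,
                            delim = "|", cache_file = NULL) {
  backend <- match.arg(backend)
  if (!inherits(params, "slanglex_params"))
    params <- do.call(query_params, as.list(params))
  if (!inherits(google, "slanglex_google_config"))
    google <- do.call(google_filter_config, as.list(google))
  if (backend == "mock" && is.null(world))
    stop_config("mock backends require a synthetic world directory ('world')")
  if (!is.null(counterexamples) && length(counterexamples) != 4L)
    stop_config("counterexamples must be exactly 4 terms")
  if (is.null(scheme)) scheme <- character()
  structure(list(seed_lexicon = seed_lexicon, controlled = controlled,
                 out_dir = out_dir, hit_counts = hit_counts, labels = labels,
                 world = world, backend = backend,
                 n_iterations = as.integer(n_iterations), params = params,
                 google = google, scheme = as.character(scheme),
                 freq_threshold = as.integer(freq_threshold),
                 rng_seed = as.integer(rng_seed), k_seeds = as.integer(k_seeds),
                 counterexamples = counterexamples,
                 cutoff = as.integer(cutoff), delim = delim,
                 cache_file = cache_file %||% file.path(out_dir, "search_cache.tsv")),
            class = "slanglex_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors the arguments of [pipeline_config()]; `params` and
#' `google` are nested mappings. Unknown keys are an error so typos surface.
#'
#' @param path Path to the YAML file.
#' @param ... Overrides applied on top of the file's values.
#' @return A `slanglex_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop_config("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

resolve_backends <- function(cfg, completion_backend, search_backend) {
  if (is.null(completion_backend) || is.null(search_backend)) {
    if (cfg$backend == "live")
      stop_config(paste("live backends must be constructed by the caller",
                        "(credentials via environment) and passed to run_pipeline()"))
    world <- load_world(cfg$world)
    if (is.null(completion_backend))
      completion_backend <- mock_completion_backend(world)
    if (is.null(search_backend))
      search_backend <- mock_search_backend(world)
  }
  list(completion = completion_backend, search = search_backend)
}

checkpoint_paths <- function(out_dir, index_term) {
  dir <- file.path(out_dir, "checkpoints")
  list(dir = dir,
       records = file.path(dir, paste0(index_term, "_records.tsv")),
       meta = file.path(dir, paste0(index_term, "_meta.yaml")))
}

write_checkpoint <- function(out_dir, index_term, gen) {
  ck <- checkpoint_paths(out_dir, index_term)
  dir.create(ck$dir, recursive = TRUE, showWarnings = FALSE)
  write_generation_log(gen, ck$records)
  nxt <- if (gen$status == "complete") gen$n_iterations + 1L else gen$next_iteration
  yaml::write_yaml(list(index_term = index_term, status = gen$status,
                        next_iteration = nxt,
                        n_iterations = gen$n_iterations), ck$meta)
  invisible(ck)
}

config_echo <- function(cfg) {
  list(seed_lexicon = cfg$seed_lexicon, controlled = cfg$controlled,
       out_dir = cfg$out_dir, hit_counts = cfg$hit_counts,
       labels = cfg$labels, world = cfg$world, backend = cfg$backend,
       n_iterations = cfg$n_iterations, params = unclass(cfg$params),
       google = unclass(cfg$google), scheme = as.list(cfg$scheme),
       freq_threshold = cfg$freq_threshold, rng_seed = cfg$rng_seed,
       k_seeds = cfg$k_seeds, counterexamples = cfg$counterexamples,
       cutoff = cfg$cutoff, delim = cfg$delim, cache_file = cfg$cache_file)
}

#' Rebuild a configuration from a run manifest
#'
#' The manifest fully determines a run on deterministic backends: replaying
#' it reproduces the outputs byte-identically.
#'
#' @param path Path to a `manifest.yaml` written by [run_pipeline()].
#' @param out_dir Optional replacement output directory for the replay.
#' @return A `slanglex_config`.
#' @export
manifest_config <- function(path, out_dir = NULL) {
  man <- yaml::read_yaml(path)
  vals <- man$config
  vals$scheme <- as.character(unlist(vals$scheme))
  if (!is.null(out_dir)) {
    vals$out_dir <- out_dir
    vals$cache_file <- file.path(out_dir, basename(vals$cache_file))
  }
  do.call(pipeline_config, vals)
}

#' Run the end-to-end lexicon pipeline
#'
#' For every eligible controlled index term: `n_iterations` of
#' prompt-generate-parse, frequency tallies, the filter scheme, and novelty
#' accounting. Writes, under `cfg$out_dir`: `generation_log.tsv` (every
#' parsed item), `filter_report.tsv` (per-term flags), `lexicon.tsv` (the
#' positive terms with their filter evidence), `novelty.tsv`,
#' `search_cache.tsv`, and `manifest.yaml` (config echo + seed + counts).
#' All outputs are deterministic given the seed and deterministic backends.
#'
#' Backend quota exhaustion checkpoints per-term generation records and the
#' search cache, then returns with `status = "interrupted"`; rerunning with
#' `resume = TRUE` continues where it stopped and yields the same outputs as
#' an uninterrupted run.
#'
#' @param cfg A [pipeline_config()].
#' @param completion_backend,search_backend Optional backend objects; when
#'   `NULL`, mocks are built from `cfg$world`.
#' @param resume Continue from checkpoints and a persisted cache.
#' @param index_terms Optional subset of index terms to run.
#' @param verbose Print per-term progress to stderr.
#' @return Object of class `slanglex_run`: selection table, lexicon, flags,
#'   novelty accounts, generation records, status, and output paths.
#' @export
run_pipeline <- function(cfg, completion_backend = NULL, search_backend = NULL,
                         resume = FALSE, index_terms = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "slanglex_config"))
  lex <- load_seed_lexicon(cfg$seed_lexicon, delim = cfg$delim)
  lex_full <- load_seed_lexicon(cfg$seed_lexicon, seed_categories(),
                                delim = cfg$delim, drop_multiword_known = FALSE)
  controlled <- read_controlled_names(cfg$controlled)
  hits <- if (!is.null(cfg$hit_counts)) read_hit_counts(cfg$hit_counts)
  selection <- select_index_terms(lex, controlled, hits, cfg$cutoff)
  terms <- selection$index_term[selection$eligible]
  if (!is.null(index_terms)) terms <- intersect(terms, trim_lower(index_terms))
  if (length(terms) == 0L) stop_config("no eligible index terms to run")

  be <- resolve_backends(cfg, completion_backend, search_backend)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cache <- if (resume && file.exists(cfg$cache_file))
    read_search_cache(cfg$cache_file) else new_search_cache()

  records <- list(); flags <- list(); accounts <- list()
  interrupted_at <- NULL
  for (it in terms) {
    if (verbose) message("index term: ", it)
    sel <- term_selection(lex, it, selection)
    start <- 1L; prior <- NULL
    ck <- checkpoint_paths(cfg$out_dir, it)
    if (resume && file.exists(ck$meta)) {
      meta <- yaml::read_yaml(ck$meta)
      prior <- read_generation_log(ck$records)
      start <- as.integer(meta$next_iteration)
    }
    gen <- run_iterations(sel, be$completion, cfg$params, cfg$n_iterations,
                          cfg$rng_seed, counterexamples = cfg$counterexamples,
                          k = cfg$k_seeds, start_iteration = start,
                          prior_records = prior)
    write_checkpoint(cfg$out_dir, it, gen)
    if (gen$status == "interrupted") {
      interrupted_at <- list(index_term = it, next_iteration = gen$next_iteration)
      break
    }
    fl <- tryCatch(
      apply_scheme(gen$tallies, cfg$scheme, lex$index_terms, be$search,
                   cfg$google, cache, cfg$freq_threshold),
      slanglex_quota_error = function(e) e)
    if (inherits(fl, "error")) {
      interrupted_at <- list(index_term = it, next_iteration = NA_integer_,
                             phase = "filtering")
      break
    }
    records[[it]] <- gen$records
    flags[[it]] <- fl
    accounts[[it]] <- novelty_account(gen$tallies, fl$term[fl$positive], lex_full)
  }

  write_search_cache(cache, cfg$cache_file)
  status <- if (is.null(interrupted_at)) "complete" else "interrupted"

  paths <- list(lexicon = file.path(cfg$out_dir, "lexicon.tsv"),
                filter_report = file.path(cfg$out_dir, "filter_report.tsv"),
                generation_log = file.path(cfg$out_dir, "generation_log.tsv"),
                novelty = file.path(cfg$out_dir, "novelty.tsv"),
                manifest = file.path(cfg$out_dir, "manifest.yaml"),
                cache = cfg$cache_file)

  rbind_all <- function(lst) {
    if (length(lst) == 0L) NULL
    else do.call(rbind, c(lst, list(make.row.names = FALSE)))
  }
  all_records <- rbind_all(records)
  all_flags <- rbind_all(flags)
  all_accounts <- rbind_all(accounts)
  lexicon <- NULL

  if (status == "complete") {
    in_seed <- seed_membership(lex_full, all_flags$term)
    lexicon <- all_flags[all_flags$positive,
                         c("index_term", "term", "frequency", "first_hit_depth",
                           "matching_variant", "passes_drug_name",
                           "passes_google"), drop = FALSE]
    lexicon$in_seed_lexicon <- in_seed[all_flags$positive]
    lexicon$is_ungs <- !lexicon$in_seed_lexicon
    lexicon$token_count <- token_count(lexicon$term)
    lexicon <- lexicon[order(lexicon$index_term, lexicon$term), , drop = FALSE]
    rownames(lexicon) <- NULL
    write_tsv(lexicon, paths$lexicon)
    write_filter_report(all_flags, paths$filter_report)
    write_generation_log(all_records, paths$generation_log)
    write_tsv(all_accounts, paths$novelty)
  }

  manifest <- list(config = config_echo(cfg), status = status,
                   backends = list(completion = be$completion$name,
                                   search = be$search$name),
                   counts = list(
                     index_terms_selected = nrow(selection),
                     index_terms_eligible = sum(selection$eligible),
                     index_terms_widely_discussed = sum(selection$widely_discussed),
                     index_terms_run = length(records),
                     generation_events = if (is.null(all_records)) 0L else nrow(all_records),
                     lexicon_rows = if (is.null(lexicon)) 0L else nrow(lexicon)),
                   interrupted_at = interrupted_at)
  yaml::write_yaml(manifest, paths$manifest)

  structure(list(selection = selection, lexicon = lexicon, flags = all_flags,
                 accounts = all_accounts, records = all_records,
                 status = status, interrupted_at = interrupted_at,
                 out_dir = cfg$out_dir, paths = paths),
            class = "slanglex_run")
}

#' @export
print.slanglex_run <- function(x, ...) {
  cat(sprintf("Pipeline run (%s): %d index terms, %d lexicon rows -> %s\n",
              x$status,
              if (is.null(x$accounts)) 0L else nrow(x$accounts),
              if (is.null(x$lexicon)) 0L else nrow(x$lexicon),
              x$out_dir))
  invisible(x)
}

#' Default parameter-sweep grid
#'
#' The grid explored when tuning: temperatures 0.0/0.3/0.6/1.0, frequency
#' and presence penalties 0.0/0.5/1.0, and both prompt templates.
#'
#' @return Data frame with columns `temperature`, `frequency_penalty`,
#'   `presence_penalty`, `template`.
#' @export
default_sweep_grid <- function() {
  expand.grid(temperature = c(0, 0.3, 0.6, 1.0),
              frequency_penalty = c(0, 0.5, 1.0),
              presence_penalty = c(0, 0.5, 1.0),
              template = c("plain", "counterexample"),
              stringsAsFactors = FALSE)
}

#' Run a parameter sweep
#'
#' One generation-filter-novelty run per grid point (at the configuration's
#' iteration count, typically reduced) on a single index term, summarized as
#' unique-novel-synonym yield per parameter combination. The search cache is
#' shared across grid points, so repeated candidate terms cost no extra
#' backend traffic.
#'
#' @param cfg A [pipeline_config()].
#' @param grid Data frame with any subset of the columns `temperature`,
#'   `frequency_penalty`, `presence_penalty`, `template`; defaults to
#'   [default_sweep_grid()]. Missing axes take the configuration's values.
#' @param completion_backend,search_backend Optional backend objects.
#' @param index_term Index term to sweep on (default: first eligible).
#' @param n_iterations Override of the per-point iteration count.
#' @return Data frame: the grid columns plus the novelty-account columns.
#' @export
run_sweep <- function(cfg, grid = default_sweep_grid(),
                      completion_backend = NULL, search_backend = NULL,
                      index_term = NULL, n_iterations = NULL) {
  stopifnot(inherits(cfg, "slanglex_config"))
  allowed <- c("temperature", "frequency_penalty", "presence_penalty", "template")
  if (!all(names(grid) %in% allowed))
    stop_config("sweep grid axes must be among: %s", paste(allowed, collapse = ", "))
  n_it <- as.integer(n_iterations %||% cfg$n_iterations)

  lex <- load_seed_lexicon(cfg$seed_lexicon, delim = cfg$delim)
  lex_full <- load_seed_lexicon(cfg$seed_lexicon, seed_categories(),
                                delim = cfg$delim, drop_multiword_known = FALSE)
  controlled <- read_controlled_names(cfg$controlled)
  selection <- select_index_terms(lex, controlled, cutoff = cfg$cutoff)
  eligible <- selection$index_term[selection$eligible]
  if (length(eligible) == 0L) stop_config("no eligible index terms")
  it <- trim_lower(index_term %||% eligible[1L])
  if (!it %in% eligible) stop_config("index term '%s' is not eligible", it)
  sel <- term_selection(lex, it, selection)

  be <- resolve_backends(cfg, completion_backend, search_backend)
  cache <- new_search_cache()

  results <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, , drop = FALSE]
    params <- query_params(
      temperature = row$temperature %||% cfg$params$temperature,
      frequency_penalty = row$frequency_penalty %||% cfg$params$frequency_penalty,
      presence_penalty = row$presence_penalty %||% cfg$params$presence_penalty,
      max_tokens = cfg$params$max_tokens)
    template <- (row$template %||% "plain")
    counter <- if (identical(template, "counterexample")) {
      if (is.null(cfg$counterexamples))
        stop_config("the counterexample template requires cfg$counterexamples")
      cfg$counterexamples
    } else NULL
    gen <- run_iterations(sel, be$completion, params, n_it, cfg$rng_seed,
                          counterexamples = counter, k = cfg$k_seeds)
    fl <- apply_scheme(gen$tallies, cfg$scheme, lex$index_terms, be$search,
                       cfg$google, cache, cfg$freq_threshold)
    list(params = c(as.list(row),
                    list(template = template)[!("template" %in% names(row))]),
         account = novelty_account(gen$tallies, fl$term[fl$positive], lex_full))
  })
  sweep_summary(results)
}
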