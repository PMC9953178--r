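# Filtering: web-search validation with query variants, depth, early
# termination and memoization; drug-name cross-reference; frequency threshold.

#' Construct a search backend
#'
#' A search backend is anything with a `search(query, max_results)` function
#' returning a data frame with character columns `title` and `snippet`, in
#' stable rank order for a given query. Live adapters signal rate/quota
#' exhaustion with [quota_error()].
#'
#' @param search Function `(query, max_results) -> data.frame(title, snippet)`.
#' @param name Backend label used in logs and manifests.
#' @return Object of class `slanglex_search_backend`.
#' @export
new_search_backend <- function(search, name = "custom") {
  stopifnot(is.function(search))
  structure(list(search = search, name = name),
            class = "slanglex_search_backend")
}

#' Configuration for the web-search filter
#'
#' A candidate term is searched alone and with the keywords "pill", "drug"
#' and "slang" appended — slang is polysemous, and the appended keyword pulls
#' drug-related result pages to the top. Each search's top `max_depth`
#' results are scanned in rank order for the index term in the title or
#' snippet.
#'
#' @param max_depth Results scanned per search (default 10; beyond the tenth
#'   result the synonym-to-noise ratio collapses).
#' @param variants Ordered keyword variants; `""` (the bare term) must come
#'   first.
#' @param match_mode `"substring"` (default; case-insensitive, tolerates
#'   "alprazolam-based") or `"whole-word"`.
#' @return List of class `slanglex_google_config`.
#' @export
google_filter_config <- function(max_depth = 10L,
                                 variants = c("", "pill", "drug", "slang"),
                                 match_mode = c("substring", "whole-word")) {
  match_mode <- match.arg(match_mode)
  if (max_depth < 1L) stop_precondition("max_depth must be >= 1")
  if (length(variants) < 1L || variants[1L] != "")
    stop_precondition("variants must start with \"\" (the bare term)")
  structure(list(max_depth = as.integer(max_depth), variants = variants,
                 match_mode = match_mode),
            class = "slanglex_google_config")
}

# --- memoization cache -------------------------------------------------------

#' Search-result cache
#'
#' Memoizes, per (term, variant), the depth of the first result whose title
#' or snippet contains the index term (`NA` for a scanned miss). A warm cache
#' answers repeated filter calls with zero backend traffic, which matters
#' when the live search API has daily limits; persisting it makes large runs
#' resumable.
#'
#' @return A new empty cache (an environment).
#' @export
new_search_cache <- function() new.env(parent = emptyenv())

cache_key <- function(term, variant) paste(term, variant, sep = "\t")

cache_get <- function(cache, term, variant) {
  if (is.null(cache)) return(NULL)
  key <- cache_key(term, variant)
  if (!exists(key, envir = cache, inherits = FALSE)) return(NULL)
  get(key, envir = cache, inherits = FALSE)
}

cache_set <- function(cache, term, variant, depth) {
  if (is.null(cache)) return(invisible(NULL))
  assign(cache_key(term, variant), depth, envir = cache)
  invisible(NULL)
}

#' Persist / restore a search cache
#'
#' TSV `term<TAB>variant<TAB>depth`, one line per scanned (term, variant),
#' with `-` recording a scanned miss. Writing then reading then writing again
#' reproduces the file byte-exactly.
#'
#' @param cache A cache from [new_search_cache()].
#' @param path File path.
#' @return `path` (write); a cache (read).
#' @export
write_search_cache <- function(cache, path) {
  keys <- sort(ls(envir = cache))
  lines <- vapply(keys, function(k) {
    d <- get(k, envir = cache, inherits = FALSE)
    paste0(k, "\t", if (is.na(d)) "-" else as.character(d))
  }, character(1L), USE.NAMES = FALSE)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_search_cache
#' @export
read_search_cache <- function(path) {
  cache <- new_search_cache()
  if (!file.exists(path)) return(cache)
  for (line in readLines(path, encoding = "UTF-8", warn = FALSE)) {
    if (!nzchar(line)) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    # variant may be the empty string, which strsplit drops at the tail
    if (length(parts) == 2L) parts <- c(parts[1L], "", parts[2L])
    if (length(parts) != 3L) stop_format("malformed cache line: %s", line)
    depth <- if (parts[3L] == "-") NA_integer_ else as.integer(parts[3L])
    cache_set(cache, parts[1L], parts[2L], depth)
  }
  cache
}

# --- the three filters -------------------------------------------------------

match_hit <- function(texts, index_term, match_mode) {
  if (match_mode == "substring") {
    grepl(index_term, tolower(texts), fixed = TRUE)
  } else {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", index_term), "\\b")
    grepl(pat, texts, ignore.case = TRUE, perl = TRUE)
  }
}

#' Web-search validation filter for one candidate term
#'
#' Searches the query variants in order; for each, scans the top
#' `cfg$max_depth` results in rank order (depth 1 = first result) for the
#' index term in title or snippet. On the first hit, records the 1-based
#' depth within that variant's results and the matching variant, and stops
#' all further searching for this term (early termination keeps API usage
#' within rate limits). Results are memoized per (term, variant) so repeated
#' calls issue no backend traffic.
#'
#' @param term Normalized candidate term.
#' @param index_term Normalized index term to look for.
#' @param backend A search backend.
#' @param cfg A [google_filter_config()].
#' @param cache Optional cache from [new_search_cache()].
#' @return List with `term`, `passed`, `first_hit_depth` (integer or `NA`),
#'   `matching_variant` (character or `NA`).
#' @export
google_filter <- function(term, index_term, backend,
                          cfg = google_filter_config(), cache = NULL) {
  stopifnot(inherits(backend, "slanglex_search_backend"))
  for (variant in cfg$variants) {
    depth <- cache_get(cache, term, variant)
    if (is.null(depth)) {
      query <- if (nzchar(variant)) paste(term, variant) else term
      res <- backend$search(query, cfg$max_depth)
      depth <- NA_integer_
      if (!is.null(res) && nrow(res) > 0L) {
        n <- min(nrow(res), cfg$max_depth)
        hits <- match_hit(res$title[seq_len(n)], index_term, cfg$match_mode) |
          match_hit(res$snippet[seq_len(n)], index_term, cfg$match_mode)
        if (any(hits)) depth <- which(hits)[1L]
      }
      cache_set(cache, term, variant, depth)
    }
    if (!is.na(depth)) {
      return(list(term = term, passed = TRUE,
                  first_hit_depth = as.integer(depth),
                  matching_variant = variant))
    }
  }
  list(term = term, passed = FALSE, first_hit_depth = NA_integer_,
       matching_variant = NA_character_)
}

#' Drug-name cross-reference filter
#'
#' Removes a candidate that is the generic name of a *different* drug: models
#' prompted for one drug readily volunteer others with the same indication.
#' A candidate equal to the queried index term itself passes.
#'
#' @param term Normalized candidate term(s); vectorized.
#' @param index_term The queried index term.
#' @param all_index_terms Character vector of every known index term.
#' @return Logical vector: `TRUE` = passes (kept), `FALSE` = filtered out.
#' @export
drug_name_filter <- function(term, index_term, all_index_terms) {
  !(term %in% all_index_terms & term != index_term)
}

#' Generation-frequency filter
#'
#' Keeps terms generated strictly more than `threshold` times; the default
#' threshold of 1 removes terms generated only once, which are overwhelmingly
#' non-synonyms before search filtering.
#'
#' @param frequency Integer vector of generation counts.
#' @param threshold Strictly-greater-than threshold (default 1).
#' @return Logical vector.
#' @export
frequency_filter <- function(frequency, threshold = 1L) {
  if (threshold < 1L) stop_precondition("threshold must be >= 1")
  frequency > threshold
}

#' Apply a filtering scheme to term tallies
#'
#' Computes per-term flags for each filter and the positive set as the
#' intersection of the predicates named in `scheme`. An empty scheme means
#' every term is positive (the "all generated terms" baseline). The final
#' lexicon scheme is `c("drug_name", "google")`.
#'
#' @param tallies Data frame from [tally_records()] (one index term).
#' @param scheme Subset of `c("drug_name", "google", "frequency")`; may be
#'   empty.
#' @param all_index_terms Every known index term (for the drug-name filter).
#' @param backend Search backend; required when `"google"` is in the scheme
#'   or google flags are wanted.
#' @param cfg A [google_filter_config()].
#' @param cache Optional search cache.
#' @param freq_threshold Frequency threshold (default 1).
#' @return Data frame with columns `index_term`, `term`, `frequency`,
#'   `passes_drug_name`, `passes_google`, `first_hit_depth`,
#'   `matching_variant`, `passes_frequency`, `positive`. Google columns are
#'   `NA` when no backend is supplied.
#' @export
apply_scheme <- function(tallies, scheme = c("drug_name", "google"),
                         all_index_terms = character(), backend = NULL,
                         cfg = google_filter_config(), cache = NULL,
                         freq_threshold = 1L) {
  known <- c("drug_name", "google", "frequency")
  if (!all(scheme %in% known))
    stop_config("unknown filter(s) in scheme: %s",
                paste(setdiff(scheme, known), collapse = ", "))
  if ("google" %in% scheme && is.null(backend))
    stop_config("scheme includes the google filter but no search backend was supplied")

  flags <- tallies[, c("index_term", "term", "frequency"), drop = FALSE]
  flags$passes_drug_name <- drug_name_filter(flags$term, flags$index_term,
                                             all_index_terms)
  if (!is.null(backend)) {
    outs <- lapply(seq_len(nrow(flags)), function(i) {
      google_filter(flags$term[i], flags$index_term[i], backend, cfg, cache)
    })
    flags$passes_google <- vapply(outs, `[[`, logical(1L), "passed")
    flags$first_hit_depth <- vapply(outs, `[[`, integer(1L), "first_hit_depth")
    flags$matching_variant <- vapply(outs, `[[`, character(1L), "matching_variant")
  } else {
    flags$passes_google <- NA
    flags$first_hit_depth <- NA_integer_
    flags$matching_variant <- NA_character_
  }
  flags$passes_frequency <- frequency_filter(flags$frequency, freq_threshold)

  pos <- rep(TRUE, nrow(flags))
  if ("drug_name" %in% scheme) pos <- pos & flags$passes_drug_name
  if ("google" %in% scheme) pos <- pos & flags$passes_google
  if ("frequency" %in% scheme) pos <- pos & flags$passes_frequency
  flags$positive <- pos
  rownames(flags) <- NULL
  flags
}

#' Write / read a filter report
#'
#' TSV mirroring the flag columns of [apply_scheme()].
#'
#' @param flags Data frame from [apply_scheme()].
#' @param path File path.
#' @return `path` (write); the flags data frame (read).
#' @export
write_filter_report <- function(flags, path) write_tsv(flags, path)

#' @rdname write_filter_report
#' @export
read_filter_report <- function(path) {
  rep <- read_tsv(path)
  rep$matching_variant <- as.character(rep$matching_variant)
  # the bare-term variant serializes as an empty field
  rep$matching_variant[!is.na(rep$passes_google) & rep$passes_google &
                         is.na(rep$matching_variant)] <- ""
  rep
}
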