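# Generation: completion-backend contract, enumerated-list parsing,
# normalization, and the iteration loop that builds term tallies.

#' Construct a completion backend
#'
#' A completion backend is anything with a `complete(prompt, params)` function
#' returning the completion text (possibly empty, never an error for an empty
#' completion). Live adapters must retry transient failures per their own
#' policy and signal quota exhaustion with [quota_error()] so callers can
#' checkpoint.
#'
#' @param complete Function `(prompt, params) -> character(1)`.
#' @param name Backend label used in logs and manifests.
#' @return Object of class `slanglex_completion_backend`.
#' @export
new_completion_backend <- function(complete, name = "custom") {
  stopifnot(is.function(complete))
  structure(list(complete = complete, name = name),
            class = "slanglex_completion_backend")
}

#' Normalize a generated term
#'
#' Lowercases, trims surrounding whitespace, and strips any trailing run of
#' sentence punctuation (`.`, `,`, `;`), then trims again. Normalization is
#' idempotent, giving each candidate a canonical form so that uniqueness and
#' frequency counts are well defined.
#'
#' @param x Character vector of raw parsed items.
#' @return Character vector of normalized terms (may contain empty strings,
#'   which callers drop).
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  # strip to a fixpoint: removing punctuation can expose trailing whitespace
  # (and vice versa), and idempotence is required of the canonical form
  repeat {
    y <- trimws(sub("[.,;]+$", "", x))
    if (identical(y, x)) return(x)
    x <- y
  }
}

#' Count whitespace-separated tokens in a term
#'
#' Multi-word generated items are retained (slang can be multi-word) but
#' flagged with their token count so downstream users can filter them.
#'
#' @param x Character vector of normalized terms.
#' @return Integer vector of token counts.
#' @export
token_count <- function(x) {
  vapply(strsplit(trimws(x), "\\s+"), function(t) sum(nzchar(t)), integer(1L))
}

#' Parse an enumerated-list completion into raw items
#'
#' The completion continues a prompt that ends with a hanging enumerator
#' ("4." or "3."), so its first line is the text of that item. Subsequent
#' lines are taken as items when they match `<int>.` or `<int>)` followed by
#' text; blank lines between items are skipped; parsing stops at the first
#' line that is neither blank nor a numbered item (models sometimes append
#' prose like "I hope this helps!"). An unparseable completion yields an
#' empty list — a failed iteration, not an error.
#'
#' @param completion Completion text.
#' @param next_index The hanging enumerator of the prompt (4 for the plain
#'   template, 3 for the counterexample template). Recorded for provenance;
#'   the grammar itself accepts any integer labels.
#' @return Character vector of raw items in order (untrimmed interior, outer
#'   whitespace removed).
#' @export
parse_completion <- function(completion, next_index = 4L) {
  if (is.null(completion) || length(completion) != 1L || is.na(completion))
    return(character())
  lines <- strsplit(completion, "\n", fixed = TRUE)[[1L]]
  items <- character()
  if (length(lines) == 0L) return(items)
  # first line continues the hanging enumerator
  first <- trimws(lines[1L])
  if (nzchar(first)) items <- c(items, first)
  if (length(lines) >= 2L) {
    for (line in lines[-1L]) {
      if (!nzchar(trimws(line))) next  # blank line between items
      m <- regmatches(line, regexec("^\\s*[0-9]+[.)]\\s*(.*)$", line))[[1L]]
      if (length(m) == 0L) break       # stop rule: not blank, not numbered
      item <- trimws(m[2L])
      if (nzchar(item)) items <- c(items, item)
    }
  }
  items
}

# deterministic per-(seed, index term, iteration) RNG seed; keeps results
# independent of iteration interleaving and lets interrupted runs resume
# mid-stream. Modulus is a prime below 2^31 so the seed stays a valid R int.
iteration_seed <- function(rng_seed, index_term, iteration) {
  base <- (as.double(rng_seed) %% 2147483629) +
    131 * (sum(utf8ToInt(index_term)) %% 16381) +
    7919 * (as.double(iteration) %% 262139)
  as.integer(base %% 2147483629)
}

#' Tally generation records into per-term frequencies
#'
#' @param records Data frame with columns `index_term`, `iteration`,
#'   `raw_text`, `term`.
#' @return Data frame with columns `index_term`, `term`, `frequency`,
#'   `token_count`, sorted by decreasing frequency then term.
#' @export
tally_records <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(index_term = character(), term = character(),
                      frequency = integer(), token_count = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(frequency = records$iteration),
                          by = list(index_term = records$index_term,
                                    term = records$term),
                          FUN = length)
  agg$token_count <- token_count(agg$term)
  agg <- agg[order(agg$index_term, -agg$frequency, agg$term), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Run repeated prompt-generate-parse iterations for one index term
#'
#' Each iteration seeds the RNG deterministically from (`rng_seed`, index
#' term, iteration number), samples seed synonyms, renders the prompt, asks
#' the backend for a completion, parses the enumerated list, and normalizes
#' the items. Iterations whose completion parses to nothing still count
#' toward `n_iterations` (no re-draw), keeping cost bounded and runs
#' comparable.
#'
#' Quota exhaustion ([quota_error()] from the backend) stops the loop
#' cleanly: the returned object has `status = "interrupted"` and
#' `next_iteration` set, and can be passed back via `prior_records` /
#' `start_iteration` to resume with identical results. Transient backend
#' errors are retried up to `max_retries` times (re-seeding the iteration),
#' then the iteration is skipped with a warning.
#'
#' @param sel Selection record from [term_selection()]; must be eligible.
#' @param backend A completion backend.
#' @param params Query parameters from [query_params()].
#' @param n_iterations Number of iterations (final pipeline runs used 1000).
#' @param rng_seed Integer seed governing all sampling.
#' @param counterexamples Optional 4 counterexamples; selects the
#'   counterexample template with 2 sampled seeds.
#' @param k Seeds per prompt (default 3; forced to 2 with counterexamples).
#' @param template Optional custom template list.
#' @param start_iteration First iteration to run (resume support).
#' @param prior_records Records from an interrupted run to prepend.
#' @param max_retries Retries per iteration on transient errors.
#' @return Object of class `slanglex_generation`: list with `records` (data
#'   frame `index_term`, `iteration`, `raw_text`, `term`), `tallies` (from
#'   [tally_records()]), `status` (`"complete"` or `"interrupted"`),
#'   `next_iteration`, `n_iterations`.
#' @export
run_iterations <- function(sel, backend, params = query_params(),
                           n_iterations = 1000L, rng_seed = 1L,
                           counterexamples = NULL, k = 3L, template = NULL,
                           start_iteration = 1L, prior_records = NULL,
                           max_retries = 2L) {
  stopifnot(inherits(backend, "slanglex_completion_backend"))
  if (!isTRUE(sel$eligible))
    stop_precondition("index term '%s' is not eligible (needs >= 3 usable synonyms)",
                      sel$index_term)
  if (n_iterations < 1L) stop_precondition("n_iterations must be >= 1")
  if (!is.null(counterexamples)) k <- 2L

  empty_rec <- data.frame(index_term = character(), iteration = integer(),
                          raw_text = character(), term = character(),
                          stringsAsFactors = FALSE)
  chunks <- list(if (is.null(prior_records)) empty_rec else prior_records)
  status <- "complete"
  next_iteration <- NA_integer_
  it <- as.integer(start_iteration)

  while (it <= n_iterations) {
    attempt <- 0L
    repeat {
      set.seed(iteration_seed(rng_seed, sel$index_term, it + 1000003L * attempt))
      seeds <- sample_seed_synonyms(sel, k = k)
      prompt <- render_prompt(sel$index_term, seeds, counterexamples, template)
      res <- tryCatch(
        list(ok = TRUE,
             text = backend$complete(prompt$rendered, params)),
        slanglex_quota_error = function(e) list(ok = FALSE, quota = TRUE, err = e),
        slanglex_transient_error = function(e) list(ok = FALSE, quota = FALSE, err = e))
      if (res$ok) break
      if (isTRUE(res$quota)) {
        status <- "interrupted"
        next_iteration <- it
        break
      }
      attempt <- attempt + 1L
      if (attempt > max_retries) {
        warning(sprintf("iteration %d for '%s' skipped after %d transient failures",
                        it, sel$index_term, max_retries),
                call. = FALSE)
        res <- list(ok = TRUE, text = "")
        break
      }
    }
    if (status == "interrupted") break
    raw <- parse_completion(res$text, prompt$next_index)
    term <- normalize_term(raw)
    keep <- nzchar(term)
    if (any(keep)) {
      chunks[[length(chunks) + 1L]] <-
        data.frame(index_term = sel$index_term, iteration = it,
                   raw_text = raw[keep], term = term[keep],
                   stringsAsFactors = FALSE)
    }
    it <- it + 1L
  }

  records <- do.call(rbind, chunks)
  rownames(records) <- NULL
  structure(list(records = records,
                 tallies = tally_records(records),
                 status = status,
                 next_iteration = next_iteration,
                 n_iterations = as.integer(n_iterations)),
            class = "slanglex_generation")
}

#' Write / read a raw generation log
#'
#' TSV with columns `index_term`, `iteration`, `raw_text`, `term`; the audit
#' trail of every parsed item, and the checkpoint format for resumable runs.
#'
#' @param gen A `slanglex_generation` object (or a bare records data frame).
#' @param path Output path.
#' @return `path` (write) or the records data frame (read), invisibly for
#'   write.
#' @export
write_generation_log <- function(gen, path) {
  records <- if (inherits(gen, "slanglex_generation")) gen$records else gen
  write_tsv(records, path)
}

#' @rdname write_generation_log
#' @export
read_generation_log <- function(path) {
  rec <- read_tsv(path, colClasses = c(index_term = "character",
                                       iteration = "integer",
                                       raw_text = "character",
                                       term = "character"))
  rec
}

#' @export
print.slanglex_generation <- function(x, ...) {
  it <- if (nrow(x$records) > 0L) x$records$index_term[1L] else "<empty>"
  cat(sprintf("Generation run: %s, %d records, %d unique terms (%s)\n",
              it, nrow(x$records), nrow(x$tallies), x$status))
  invisible(x)
}
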