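# Seed lexicon: reading the RedMed-style synonym table, selecting the
# controlled index terms to query, and membership tests used for novelty.

#' Synonym validation categories of the seed lexicon
#'
#' The seed table has one column per validation route: known brand names
#' (`known`), close edit distance (`edOne`, `edTwo`), close phonetic edit
#' distance (`misspellingPhon`), pill impressions (`pillMark`), web-search
#' validation (`google_ms`, `google_title`, `google_snippet`), and slang
#' dictionaries (`ud_slang`).
#'
#' @return Character vector of the nine category names.
#' @export
seed_categories <- function() {
  c("known", "edOne", "edTwo", "misspellingPhon", "pillMark",
    "google_ms", "google_title", "google_snippet", "ud_slang")
}

#' Categories sampled for prompting by default
#'
#' Only single-word brand names, edit-distance neighbours, phonetic
#' misspellings, and pill impressions are clean enough to seed prompts; the
#' web-search and slang-dictionary columns carry more false positives, and
#' presenting a model with irrelevant examples begets more irrelevant output.
#'
#' @return Character vector of the five default usable category names.
#' @export
usable_seed_categories <- function() {
  c("known", "edOne", "edTwo", "misspellingPhon", "pillMark")
}

#' Load a seed lexicon table
#'
#' Reads a CSV or TSV with one row per index term (drug generic name), a
#' required `index_term` column, and one column per synonym category, each
#' cell holding a delimiter-separated list of terms. All terms are lowercased
#' and trimmed; duplicates within an (index term, category) pair are
#' collapsed. Multi-word entries in the `known` column are dropped by default:
#' multi-word known drug terms are mostly short phrases that already contain a
#' synonym ("xanax works great") and add nothing as prompt seeds.
#'
#' @param path Path to the table. Extension `.csv` selects comma separation,
#'   anything else tab separation.
#' @param usable_categories Categories to retain. Defaults to
#'   [usable_seed_categories()]; pass [seed_categories()] for the full view
#'   used as the novelty reference.
#' @param delim Delimiter separating terms inside a cell (default `"|"`).
#' @param drop_multiword_known Drop `known` entries containing internal
#'   whitespace (default `TRUE`).
#' @return An object of class `slanglex_seed`: a list with `entries` (a
#'   data frame with columns `index_term`, `synonym`, `category`),
#'   `index_terms` (sorted unique index terms), and the load options.
#' @export
load_seed_lexicon <- function(path, usable_categories = usable_seed_categories(),
                              delim = "|", drop_multiword_known = TRUE) {
  if (!file.exists(path)) stop_format("seed lexicon file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(tab) == 0L) stop_format("seed lexicon file is empty: %s", path)
  bad <- setdiff(usable_categories, seed_categories())
  if (length(bad) > 0L)
    stop_format("unknown seed categories: %s", paste(bad, collapse = ", "))
  required <- c("index_term", usable_categories)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop_format("seed lexicon is missing required column(s): %s",
                paste(missing, collapse = ", "))

  tab$index_term <- trim_lower(tab$index_term)
  tab <- tab[order(tab$index_term), , drop = FALSE]

  rows <- vector("list", nrow(tab) * length(usable_categories))
  k <- 0L
  for (i in seq_len(nrow(tab))) {
    for (cat in usable_categories) {
      cell <- tab[[cat]][i]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      syns <- trim_lower(strsplit(cell, delim, fixed = TRUE)[[1L]])
      syns <- syns[nzchar(syns)]
      if (cat == "known" && drop_multiword_known)
        syns <- syns[!grepl("\\s", syns)]
      syns <- syns[!duplicated(syns)]
      if (length(syns) == 0L) next
      k <- k + 1L
      rows[[k]] <- data.frame(index_term = tab$index_term[i], synonym = syns,
                              category = cat, stringsAsFactors = FALSE)
    }
  }
  entries <- if (k > 0L) do.call(rbind, rows[seq_len(k)]) else
    data.frame(index_term = character(), synonym = character(),
               category = character(), stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 index_terms = sort(unique(tab$index_term)),
                 usable_categories = usable_categories,
                 delim = delim,
                 drop_multiword_known = drop_multiword_known),
            class = "slanglex_seed")
}

#' Write a seed lexicon back to disk
#'
#' Serializes in the same one-row-per-index-term layout [load_seed_lexicon()]
#' reads, with cells joined by the lexicon's delimiter. Loading the written
#' file with the same options reproduces the lexicon exactly.
#'
#' @param lex A `slanglex_seed` object.
#' @param path Output path; `.csv` for comma separation, else tab.
#' @return `path`, invisibly.
#' @export
write_seed_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "slanglex_seed"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cats <- lex$usable_categories
  out <- data.frame(index_term = lex$index_terms, stringsAsFactors = FALSE)
  for (cat in cats) {
    out[[cat]] <- vapply(lex$index_terms, function(it) {
      e <- lex$entries
      paste(e$synonym[e$index_term == it & e$category == cat],
            collapse = lex$delim)
    }, character(1L), USE.NAMES = FALSE)
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a controlled-substance name list
#'
#' One name per line, UTF-8; `#` starts a comment; blank lines ignored. Names
#' are lowercased and trimmed so that matching against index terms is exact
#' case-insensitive string equality.
#'
#' @param path Path to the text file.
#' @return Character vector of unique lowercased names.
#' @export
read_controlled_names <- function(path) {
  if (!file.exists(path)) stop_format("controlled-substance list not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trim_lower(lines)
  unique(lines[nzchar(lines)])
}

#' Read a per-index-term hit-count table
#'
#' Two-column TSV `index_term<TAB>hits` giving the number of exact-match
#' web-search hits on Reddit pages per index term. Counts are supplied as
#' data, never fetched live, so selection stays deterministic.
#'
#' @param path Path to the TSV (with header).
#' @return Named integer vector of hits keyed by lowercased index term.
#' @export
read_hit_counts <- function(path) {
  if (!file.exists(path)) stop_format("hit-count table not found: %s", path)
  tab <- read_tsv(path)
  if (!all(c("index_term", "hits") %in% names(tab)))
    stop_format("hit-count table must have columns index_term, hits")
  hits <- as.integer(tab$hits)
  names(hits) <- trim_lower(tab$index_term)
  hits
}

#' Select controlled index terms for querying
#'
#' Intersects the lexicon's index terms with the controlled-substance list
#' (exact, case-insensitive). A term is *eligible* for prompting when it has
#' at least three usable seed synonyms — fewer cannot fill the prompt
#' template. A term is *widely discussed* when its supplied hit count meets
#' the cutoff (default 10,000 Reddit hits, roughly the top quarter of terms).
#'
#' @param lex A `slanglex_seed` object (usable-category view).
#' @param controlled_names Character vector from [read_controlled_names()].
#' @param hit_counts Optional named vector from [read_hit_counts()].
#' @param cutoff Widely-discussed hit cutoff (default 10000).
#' @return Data frame, one row per index term in the intersection, ordered
#'   lexicographically, with columns `index_term`, `n_usable`, `eligible`,
#'   `widely_discussed`, `reddit_hits`.
#' @export
select_index_terms <- function(lex, controlled_names, hit_counts = NULL,
                               cutoff = 10000L) {
  stopifnot(inherits(lex, "slanglex_seed"))
  controlled <- unique(trim_lower(controlled_names))
  inter <- sort(intersect(lex$index_terms, controlled))
  n_usable <- vapply(inter, function(it) {
    length(unique(lex$entries$synonym[lex$entries$index_term == it]))
  }, integer(1L), USE.NAMES = FALSE)
  hits <- rep(NA_integer_, length(inter))
  if (!is.null(hit_counts)) {
    m <- match(inter, names(hit_counts))
    hits[!is.na(m)] <- as.integer(hit_counts[m[!is.na(m)]])
  }
  data.frame(index_term = inter,
             n_usable = n_usable,
             eligible = n_usable >= 3L,
             widely_discussed = !is.na(hits) & hits >= cutoff,
             reddit_hits = hits,
             stringsAsFactors = FALSE)
}

#' Usable seed synonyms for one index term
#'
#' @param lex A `slanglex_seed` object.
#' @param index_term Index term (matched case-insensitively).
#' @return Character vector of distinct usable synonyms (across categories).
#' @export
seed_synonyms <- function(lex, index_term) {
  stopifnot(inherits(lex, "slanglex_seed"))
  it <- trim_lower(index_term)
  unique(lex$entries$synonym[lex$entries$index_term == it])
}

#' Case-insensitive membership in the seed lexicon
#'
#' A term is "present" if it appears as a synonym in any loaded category of
#' any index term, or is itself an index term. Used as the novelty reference:
#' a filtered candidate absent from the seed lexicon is a novel discovery.
#'
#' @param lex A `slanglex_seed` object (load with all categories for the
#'   widest, most conservative novelty check).
#' @param terms Character vector of terms.
#' @return Logical vector.
#' @export
seed_membership <- function(lex, terms) {
  stopifnot(inherits(lex, "slanglex_seed"))
  t <- trim_lower(terms)
  t %in% lex$entries$synonym | t %in% lex$index_terms
}

#' Build a per-term selection record for generation
#'
#' Packages the index term, its usable synonyms, and its eligibility/widely-
#' discussed status into the unit consumed by [run_iterations()].
#'
#' @param lex A `slanglex_seed` object (usable view).
#' @param index_term One index term.
#' @param selection Optional data frame from [select_index_terms()]; if given,
#'   eligibility and hit information are taken from its matching row.
#' @return List with fields `index_term`, `usable_synonyms`, `eligible`,
#'   `widely_discussed`, `reddit_hits`.
#' @export
term_selection <- function(lex, index_term, selection = NULL) {
  it <- trim_lower(index_term)
  syns <- seed_synonyms(lex, it)
  rec <- list(index_term = it, usable_synonyms = syns,
              eligible = length(syns) >= 3L,
              widely_discussed = FALSE, reddit_hits = NA_integer_)
  if (!is.null(selection)) {
    row <- selection[selection$index_term == it, , drop = FALSE]
    if (nrow(row) == 1L) {
      rec$eligible <- row$eligible
      rec$widely_discussed <- row$widely_discussed
      rec$reddit_hits <- row$reddit_hits
    }
  }
  rec
}

#' @export
print.slanglex_seed <- function(x, ...) {
  cat(sprintf("Seed lexicon: %d index terms, %d entries (%s)\n",
              length(x$index_terms), nrow(x$entries),
              paste(x$usable_categories, collapse = ", ")))
  invisible(x)
}
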