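# Evaluation: confusion matrices against manual labels, the F-beta family,
# novelty accounting, and the summary tables/histograms.

#' Read a manual-label file
#'
#' CSV `index_term,term,label` with `label` in {`synonym`, `non-synonym`}.
#' Terms are normalized with [normalize_term()] so they align with generated
#' terms; duplicate (index term, term) pairs are an error.
#'
#' @param path Path to the CSV.
#' @return Data frame with columns `index_term`, `term`, `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_format("label file not found: %s", path)
  lab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("index_term", "term", "label")
  missing <- setdiff(need, names(lab))
  if (length(missing) > 0L)
    stop_format("label file is missing column(s): %s", paste(missing, collapse = ", "))
  lab$index_term <- trim_lower(lab$index_term)
  lab$term <- normalize_term(lab$term)
  lab$label <- trim_lower(lab$label)
  bad <- setdiff(unique(lab$label), c("synonym", "non-synonym"))
  if (length(bad) > 0L)
    stop_format("labels must be 'synonym' or 'non-synonym'; found: %s",
                paste(bad, collapse = ", "))
  if (anyDuplicated(paste(lab$index_term, lab$term, sep = "\r")))
    stop_format("duplicate (index_term, term) pairs in label file")
  lab[, need]
}

#' Confusion matrix of a predicted-positive term set against labels
#'
#' The evaluated universe is the labeled term set (for one index term);
#' every predicted term must be labeled — unlabeled predictions are a data
#' error listing the offenders. True negatives are computed too, although no
#' reported metric uses them, so full confusion matrices can be displayed.
#'
#' @param predicted_positive Character vector of terms predicted to be
#'   synonyms.
#' @param labels Data frame with columns `term`, `label` (and optionally
#'   `index_term`) covering every evaluated term.
#' @return Object of class `slanglex_confusion`: list with integer fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(predicted_positive, labels) {
  pred <- unique(predicted_positive)
  unlabeled <- setdiff(pred, labels$term)
  if (length(unlabeled) > 0L)
    stop_data("evaluated term(s) without a manual label: %s",
              paste(utils::head(unlabeled, 20L), collapse = ", "))
  syn <- unique(labels$term[labels$label == "synonym"])
  non <- unique(labels$term[labels$label == "non-synonym"])
  structure(list(tp = length(intersect(pred, syn)),
                 fp = length(intersect(pred, non)),
                 fn = length(setdiff(syn, pred)),
                 tn = length(setdiff(non, pred))),
            class = "slanglex_confusion")
}

#' @export
print.slanglex_confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2L, 2L,
              dimnames = list(predicted = c("0", "1"), truth = c("0", "1")))
  print(m)
  invisible(x)
}

fbeta <- function(precision, recall, beta) {
  b2 <- beta^2
  denom <- b2 * precision + recall
  ifelse(is.na(precision) | is.na(recall) | denom == 0, NA_real_,
         (1 + b2) * precision * recall / denom)
}

#' Precision, recall, F1 and F2 from a confusion matrix
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN); F1 = 2pr/(p+r);
#' F2 = 5pr/(4p+r), the beta = 2 F-measure that favors recall — appropriate
#' here because a missed synonym is unrecoverable downstream while a false
#' positive can be filtered later. A metric whose denominator is zero is
#' reported as `NA`; values are never rounded internally (round only at
#' presentation, e.g. 3 decimals in reports).
#'
#' @param cm A `slanglex_confusion` object.
#' @param scheme Optional scheme name carried into the row.
#' @return One-row data frame: `scheme`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`, `f2`.
#' @export
metrics <- function(cm, scheme = NA_character_) {
  stopifnot(inherits(cm, "slanglex_confusion"))
  precision <- if (cm$tp + cm$fp == 0L) NA_real_ else cm$tp / (cm$tp + cm$fp)
  recall <- if (cm$tp + cm$fn == 0L) NA_real_ else cm$tp / (cm$tp + cm$fn)
  data.frame(scheme = scheme, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
             precision = precision, recall = recall,
             f1 = fbeta(precision, recall, 1), f2 = fbeta(precision, recall, 2),
             stringsAsFactors = FALSE)
}

#' Compare the six classification schemes against manual labels
#'
#' One row per scheme: the all-generated baseline, the seed-membership
#' baseline (predict a term positive iff it is already in the seed lexicon),
#' drug-name only, drug-name + frequency, drug-name + search, and all three
#' filters. Labels must cover every unique generated term for the index term.
#'
#' @param tallies Tallies for one index term.
#' @param flags Flags from [apply_scheme()] for the same tallies (with google
#'   columns computed).
#' @param labels Label data frame covering the evaluated terms.
#' @param seed_lex Full-view seed lexicon (all categories) for the membership
#'   baseline.
#' @return Data frame of [metrics()] rows, one per scheme.
#' @export
scheme_comparison <- function(tallies, flags, labels, seed_lex) {
  if (nrow(labels) == 0L) stop_data("label set is empty")
  evaluated <- unique(tallies$term)
  unl <- setdiff(evaluated, labels$term)
  if (length(unl) > 0L)
    stop_data("generated term(s) without a manual label: %s",
              paste(utils::head(unl, 20L), collapse = ", "))
  f <- flags[match(evaluated, flags$term), , drop = FALSE]
  preds <- list(
    "all_generated" = evaluated,
    "seed_membership" = evaluated[seed_membership(seed_lex, evaluated)],
    "drug_name" = evaluated[f$passes_drug_name],
    "drug_name+frequency" = evaluated[f$passes_drug_name & f$passes_frequency],
    "drug_name+google" = evaluated[f$passes_drug_name & f$passes_google],
    "drug_name+frequency+google" =
      evaluated[f$passes_drug_name & f$passes_frequency & f$passes_google])
  lab <- labels[labels$term %in% evaluated, , drop = FALSE]
  out <- do.call(rbind, lapply(names(preds), function(nm) {
    metrics(confusion(preds[[nm]], lab), scheme = nm)
  }))
  rownames(out) <- NULL
  out
}

#' Histogram of first-hit search depths
#'
#' Counts unique terms by the depth at which the index term first appeared in
#' their search results; split by manual label when labels are given.
#'
#' @param flags Flags from [apply_scheme()] (google columns computed); only
#'   rows with a hit contribute.
#' @param labels Optional label data frame.
#' @return Data frame `depth`, `count` (unlabeled mode) or `depth`,
#'   `count_synonym`, `count_nonsynonym`.
#' @export
depth_histogram <- function(flags, labels = NULL) {
  hit <- flags[!is.na(flags$first_hit_depth), , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(if (is.null(labels))
      data.frame(depth = integer(), count = integer())
      else data.frame(depth = integer(), count_synonym = integer(),
                      count_nonsynonym = integer()))
  }
  depths <- sort(unique(hit$first_hit_depth))
  if (is.null(labels)) {
    data.frame(depth = depths,
               count = vapply(depths, function(d)
                 sum(hit$first_hit_depth == d), integer(1L)))
  } else {
    lab <- labels$label[match(hit$term, labels$term)]
    data.frame(depth = depths,
               count_synonym = vapply(depths, function(d)
                 sum(hit$first_hit_depth == d & lab == "synonym", na.rm = TRUE),
                 integer(1L)),
               count_nonsynonym = vapply(depths, function(d)
                 sum(hit$first_hit_depth == d & lab == "non-synonym", na.rm = TRUE),
                 integer(1L)))
  }
}

#' Histogram of generation frequencies
#'
#' Counts unique terms by generation frequency, split by manual label when
#' labels are given. With `with_google = TRUE` only terms passing the search
#' filter are counted (flags required), reproducing the before/after-filter
#' comparison. Terms failing the drug-name filter are omitted when flags are
#' supplied, matching how these distributions are displayed.
#'
#' @param tallies Tallies for one index term.
#' @param labels Optional label data frame.
#' @param flags Optional flags from [apply_scheme()].
#' @param with_google Restrict to terms passing the search filter.
#' @return Data frame `frequency`, `count` or `frequency`, `count_synonym`,
#'   `count_nonsynonym`.
#' @export
frequency_histogram <- function(tallies, labels = NULL, flags = NULL,
                                with_google = FALSE) {
  t <- tallies
  if (!is.null(flags)) {
    f <- flags[match(t$term, flags$term), , drop = FALSE]
    keep <- f$passes_drug_name
    if (with_google) keep <- keep & !is.na(f$passes_google) & f$passes_google
    t <- t[keep, , drop = FALSE]
  } else if (with_google) {
    stop_config("with_google = TRUE requires flags with google columns")
  }
  if (nrow(t) == 0L) {
    return(if (is.null(labels))
      data.frame(frequency = integer(), count = integer())
      else data.frame(frequency = integer(), count_synonym = integer(),
                      count_nonsynonym = integer()))
  }
  freqs <- sort(unique(t$frequency))
  if (is.null(labels)) {
    data.frame(frequency = freqs,
               count = vapply(freqs, function(fr)
                 sum(t$frequency == fr), integer(1L)))
  } else {
    lab <- labels$label[match(t$term, labels$term)]
    data.frame(frequency = freqs,
               count_synonym = vapply(freqs, function(fr)
                 sum(t$frequency == fr & lab == "synonym", na.rm = TRUE),
                 integer(1L)),
               count_nonsynonym = vapply(freqs, function(fr)
                 sum(t$frequency == fr & lab == "non-synonym", na.rm = TRUE),
                 integer(1L)))
  }
}

#' Novelty account for one index term
#'
#' Chains the per-term yield counts: total generation events >= unique
#' generated terms >= filtered synonyms >= unique novel synonyms (filtered
#' terms absent from the seed lexicon — the pipeline's yield metric). A term
#' equal to the queried index term can pass the filters but can never be
#' novel, since it is by definition in the seed lexicon.
#'
#' @param tallies Tallies for one index term.
#' @param positives Character vector of terms passing the active scheme.
#' @param seed_lex Full-view seed lexicon (novelty reference).
#' @return One-row data frame: `index_term`, `total_generated`,
#'   `unique_generated`, `gpt3_synonyms`, `ungs`.
#' @export
novelty_account <- function(tallies, positives, seed_lex) {
  it <- if (nrow(tallies) > 0L) tallies$index_term[1L] else NA_character_
  pos <- unique(positives)
  data.frame(index_term = it,
             total_generated = sum(tallies$frequency),
             unique_generated = nrow(tallies),
             gpt3_synonyms = length(pos),
             ungs = sum(!seed_membership(seed_lex, pos)),
             stringsAsFactors = FALSE)
}

#' Assemble a parameter-sweep summary table
#'
#' Binds one novelty account per parameter set into a table keyed by
#' temperature, template, frequency penalty and presence penalty.
#'
#' @param results List of lists, each with `params` (named list or one-row
#'   data frame holding any of `temperature`, `template`,
#'   `frequency_penalty`, `presence_penalty`) and `account` (a
#'   [novelty_account()] row).
#' @return Data frame with the parameter columns followed by the account
#'   columns.
#' @export
sweep_summary <- function(results) {
  rows <- lapply(results, function(r) {
    p <- as.data.frame(r$params, stringsAsFactors = FALSE)
    cbind(p, r$account)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marginal yield distribution over one sweep parameter
#'
#' Sums the unique-novel-synonym counts over all other parameters, per level
#' of `param`, so the marginal totals conserve the grand total.
#'
#' @param summary Data frame from [sweep_summary()] (or [run_sweep()]).
#' @param param One of the parameter column names.
#' @return Data frame `level`, `ungs` (summed), `mean_ungs`.
#' @export
sweep_marginal <- function(summary, param) {
  if (!param %in% names(summary))
    stop_precondition("no such sweep parameter column: %s", param)
  lv <- unique(summary[[param]])
  data.frame(level = lv,
             ungs = vapply(lv, function(v)
               sum(summary$ungs[summary[[param]] == v]), numeric(1L)),
             mean_ungs = vapply(lv, function(v)
               mean(summary$ungs[summary[[param]] == v]), numeric(1L)))
}

#' Round a metrics table for presentation
#'
#' @param report Data frame with `precision`, `recall`, `f1`, `f2` columns.
#' @param digits Decimal places (default 3, as printed in reports).
#' @return The data frame with the four metric columns rounded.
#' @export
round_metrics <- function(report, digits = 3L) {
  for (col in c("precision", "recall", "f1", "f2"))
    if (col %in% names(report)) report[[col]] <- round(report[[col]], digits)
  report
}
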