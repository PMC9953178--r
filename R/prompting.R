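# Prompt construction: seed sampling and the two numbered-list templates.

#' Completion query parameters
#'
#' Temperature trades likely answers for diverse ones; the frequency penalty
#' discourages verbatim token repetition; the presence penalty discourages
#' topic repetition. Defaults are the settings that maximized the yield of
#' unique novel synonyms in the parameter search: temperature 1.0 and both
#' penalties 0.0.
#'
#' @param temperature Real in \[0, 1\] (default 1.0).
#' @param frequency_penalty Real in \[-2, 2\] (default 0.0).
#' @param presence_penalty Real in \[-2, 2\] (default 0.0).
#' @param max_tokens Positive integer cap on the completion length (default
#'   256; enough for a ten-item list with room to spare).
#' @return List of class `slanglex_params`.
#' @export
query_params <- function(temperature = 1.0, frequency_penalty = 0.0,
                         presence_penalty = 0.0, max_tokens = 256L) {
  if (!is.numeric(temperature) || temperature < 0 || temperature > 1)
    stop_precondition("temperature must be in [0, 1], got %s", temperature)
  if (!is.numeric(frequency_penalty) || abs(frequency_penalty) > 2)
    stop_precondition("frequency_penalty must be in [-2, 2], got %s",
                      frequency_penalty)
  if (!is.numeric(presence_penalty) || abs(presence_penalty) > 2)
    stop_precondition("presence_penalty must be in [-2, 2], got %s",
                      presence_penalty)
  if (!is.numeric(max_tokens) || max_tokens < 1)
    stop_precondition("max_tokens must be a positive integer")
  structure(list(temperature = as.numeric(temperature),
                 frequency_penalty = as.numeric(frequency_penalty),
                 presence_penalty = as.numeric(presence_penalty),
                 max_tokens = as.integer(max_tokens)),
            class = "slanglex_params")
}

#' Uniformly sample seed synonyms for one prompt
#'
#' Draws `k` distinct synonyms uniformly without replacement from the index
#' term's usable pool. Each pipeline iteration samples independently, so the
#' same composition can recur across iterations.
#'
#' @param sel Selection record from [term_selection()].
#' @param k Number of seeds (default 3; use 2 with the counterexample
#'   template).
#' @param rng_seed Optional integer; when given, the draw is seeded and hence
#'   reproducible on its own. When `NULL`, the current RNG stream is used
#'   (the mode [run_iterations()] relies on).
#' @return Character vector of `k` distinct synonyms in sampled order.
#' @export
sample_seed_synonyms <- function(sel, k = 3L, rng_seed = NULL) {
  pool <- sel$usable_synonyms
  if (k > length(pool))
    stop_precondition("index term '%s' has only %d usable synonyms; %d requested",
                      sel$index_term, length(pool), k)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  pool[sample.int(length(pool), k)]
}

#' Default prompt templates
#'
#' The plain template asks for "ways to say" the index term and lists three
#' seed synonyms; the hanging "4." cues the model to continue the list. The
#' counterexample template first lists four hand-picked non-synonyms (drugs
#' with the same indication but different identity), then two seeds, ending
#' with a hanging "3.". Placeholders: `{index_term}`, `{seed_1}`..`{seed_3}`,
#' `{counter_1}`..`{counter_4}`.
#'
#' @param template `"plain"` or `"counterexample"`.
#' @return List with `text` (the template string) and `next_index` (the
#'   hanging enumerator value).
#' @export
default_prompt_template <- function(template = c("plain", "counterexample")) {
  template <- match.arg(template)
  if (template == "plain") {
    list(text = "ways to say {index_term}:\n1. {seed_1}\n2. {seed_2}\n3. {seed_3}\n4.",
         next_index = 4L)
  } else {
    list(text = paste0("these are not synonyms for {index_term}:\n",
                       "1. {counter_1}\n2. {counter_2}\n3. {counter_3}\n4. {counter_4}\n",
                       "but these are synonyms for {index_term}:\n",
                       "1. {seed_1}\n2. {seed_2}\n3."),
         next_index = 3L)
  }
}

#' Load a prompt template from a YAML file
#'
#' The file must define `text` (with the placeholders described in
#' [default_prompt_template()]) and `next_index` (the hanging enumerator the
#' parser resumes from). This lets users experiment with prompt wording
#' without touching code.
#'
#' @param path Path to the YAML file.
#' @return Template list as in [default_prompt_template()].
#' @export
load_prompt_template <- function(path) {
  tpl <- yaml::read_yaml(path)
  if (is.null(tpl$text) || is.null(tpl$next_index))
    stop_format("prompt template file must define 'text' and 'next_index'")
  list(text = tpl$text, next_index = as.integer(tpl$next_index))
}

#' Render a prompt from seeds (and optional counterexamples)
#'
#' Substitutes the index term, seed synonyms, and counterexamples into the
#' template, producing the exact byte sequence sent to the completion
#' backend. Rendering is pure: the same inputs always give the same bytes.
#'
#' @param index_term Index term (non-empty).
#' @param seeds Character vector: 3 seeds for the plain template, 2 for the
#'   counterexample template.
#' @param counterexamples Optional character vector of exactly 4 non-synonyms;
#'   presence selects the counterexample template.
#' @param template Optional template list (from [default_prompt_template()] or
#'   [load_prompt_template()]); defaults to the built-in template matching the
#'   argument shape.
#' @return List of class `slanglex_prompt` with fields `index_term`,
#'   `seed_synonyms`, `counterexamples`, `next_index`, `rendered`.
#' @export
render_prompt <- function(index_term, seeds, counterexamples = NULL,
                          template = NULL) {
  if (!is.character(index_term) || length(index_term) != 1L ||
      !nzchar(trimws(index_term)))
    stop_precondition("index_term must be a non-empty string")
  if (anyDuplicated(seeds))
    stop_precondition("seed synonyms must be distinct")
  if (is.null(counterexamples)) {
    if (length(seeds) != 3L)
      stop_precondition("plain template needs exactly 3 seeds, got %d",
                        length(seeds))
    if (is.null(template)) template <- default_prompt_template("plain")
  } else {
    if (length(seeds) != 2L || length(counterexamples) != 4L)
      stop_precondition(
        "counterexample template needs 2 seeds and 4 counterexamples, got %d and %d",
        length(seeds), length(counterexamples))
    if (is.null(template)) template <- default_prompt_template("counterexample")
  }
  subs <- c(index_term = index_term)
  for (i in seq_along(seeds)) subs[[paste0("seed_", i)]] <- seeds[i]
  for (i in seq_along(counterexamples))
    subs[[paste0("counter_", i)]] <- counterexamples[i]
  rendered <- template$text
  for (nm in names(subs))
    rendered <- gsub(paste0("{", nm, "}"), subs[[nm]], rendered, fixed = TRUE)
  structure(list(index_term = index_term, seed_synonyms = seeds,
                 counterexamples = counterexamples,
                 next_index = as.integer(template$next_index),
                 rendered = rendered),
            class = "slanglex_prompt")
}

#' @export
print.slanglex_prompt <- function(x, ...) {
  cat(x$rendered, "\n", sep = "")
  invisible(x)
}
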