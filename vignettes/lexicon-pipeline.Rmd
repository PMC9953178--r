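---
title: "Generating and validating drug-slang lexicons with language-model prompting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and validating drug-slang lexicons with language-model prompting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slanglex)
```

## The method

Social-media text about drug use is written in slang, brand names, and
misspellings that controlled vocabularies miss. `slanglex` extends an
existing validated synonym lexicon (a RedMed-style table: index terms =
DrugBank generic names, with synonyms in nine validation categories) by
few-shot prompting a text-completion language model and filtering what it
produces. One iteration, for one drug:

1. sample three of the drug's usable seed synonyms uniformly without
   replacement;
2. render the numbered-list prompt

   ```
   ways to say {index_term}:
   1. {seed_1}
   2. {seed_2}
   3. {seed_3}
   4.
   ```

   The hanging `4.` cues the model to continue the list. Enumerated prompts
   are used because completion models reliably continue them in the same
   format, which makes parsing mechanical; with three examples the models we
   target tend to complete lists to ten items, so each iteration typically
   yields seven candidates;
3. parse the completion back into items, normalize them, and add them to the
   drug's tally.

Repeating this many times (1000 iterations per drug in full-scale runs)
builds a frequency-tallied candidate set, which is then filtered:

* **Search filter.** Each candidate is searched — alone, then with "pill",
  "drug", and "slang" appended (slang is polysemous; the keyword pulls
  drug-context pages up). The candidate passes if the index term appears in
  the title or snippet of a top-`max_depth` result; the 1-based rank of the
  first such result (within the matching variant) is recorded as the depth.
  Searching for a term stops at its first hit, and every (term, variant)
  result is memoized, because live search APIs are rate- and quota-limited.
* **Drug-name filter.** Candidates that are generic names of *other* drugs
  are dropped: prompted for one anxiolytic, a model happily lists the
  others. A candidate equal to the queried index term passes (it is simply
  never novel).
* **Frequency filter.** Candidates generated no more than `threshold` times
  (strictly greater-than semantics; default threshold 1, i.e. drop
  singletons) can be dropped. This filter is *not* part of the default
  scheme: before search filtering, singleton generations are overwhelmingly
  junk, but after it the surviving singletons are mostly genuine, and real
  synonyms occur at every frequency.

The default published-lexicon scheme is therefore `drug_name + google`. Each
lexicon row keeps the evidence (frequency, hit depth, matching variant, flag
values) so users can re-filter without rerunning.

## Evaluation

Against manually labeled terms (`synonym` / `non-synonym`), predictions are
scored with precision, recall, and the F-measure family,

$$F_\beta = \frac{(1+\beta^2)\,p\,r}{\beta^2 p + r},$$

reported for $\beta = 1$ and $\beta = 2$ (so $F_2 = 5pr/(4p+r)$). $F_2$ is
preferred: when a lexicon is used to flag posts from a huge corpus, false
positives can be removed later but false negatives are gone. A metric whose
denominator is zero is reported as absent, never as zero, and rounding to
three decimals happens only at report serialization.

The evaluated universe for all metrics is the set of *generated* (unique,
normalized) terms for a drug; labels must cover it. The yield metric is the
UNGS — unique novel generated synonym: a term passing the scheme that is
absent from the seed lexicon. "Absent" is checked against *all* nine
categories and all index terms, case-insensitively — the widest reference,
hence the most conservative novelty claim.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `temperature` | 1.0 | Diversity is the product; yield of novel synonyms rises monotonically with temperature in parameter sweeps. Range [0, 1]. |
| `frequency_penalty`, `presence_penalty` | 0.0 | Sweeps showed no yield benefit from positive penalties; range [-2, 2]. |
| seeds per prompt (`k_seeds`) | 3 | Matches the observed complete-to-ten-items behavior, maximizing items generated per query. |
| `max_tokens` | 256 | Comfortably fits a ten-item list; completion APIs cap prompt + response jointly. |
| `max_depth` | 10 | Beyond the tenth search result the synonym-to-noise ratio collapses. |
| search variants | `"", "pill", "drug", "slang"` | Bare term first (cheapest hit), then disambiguating keywords. |
| `freq_threshold` | 1 | Strictly-greater-than; threshold 1 removes exactly the singletons. |
| `n_iterations` | 1000 | Full-scale setting; yield keeps accruing across hundreds of iterations because sampling of seeds keeps varying the prompt. |
| widely-discussed `cutoff` | 10,000 | Reddit hit count marking roughly the top quarter of drugs, the ones pharmacovigilance consumers care most about. |

Counterexample prompts (four hand-picked non-synonyms listed first, then two
seeds) are supported but not default: they sharply reduce novel-synonym
yield. Counterexamples are configuration, never auto-selected.

## Numerical and design choices

* **Normalization** lowercases, trims, and strips trailing runs of `.,;` to
  a fixpoint, so `normalize(normalize(x)) == normalize(x)` holds and
  frequency counts are over canonical forms. Multi-word candidates are kept
  (slang can be multi-word) and flagged with a token count; the single-word
  rule applies only to *seed* brand-name entries, which are otherwise often
  phrases that already contain a synonym.
* **Parsing grammar.** The completion, understood as continuing the hanging
  enumerator, is split on newlines; the first line is an item if non-empty;
  subsequent lines match `<int>.` or `<int>)` plus text; blank lines are
  skipped; the first line that is neither blank nor numbered stops parsing
  (models append pleasantries). An unparseable completion is a failed
  iteration, not an error, and failed iterations still count toward
  `n_iterations` so runs remain cost-bounded and comparable.
* **Determinism and resumability.** Every iteration reseeds the RNG from
  (run seed, index term, iteration number), so results are independent of
  scheduling, and a quota-interrupted run resumes mid-stream bit-exactly.
  Backends signal quota exhaustion as a distinct condition; the pipeline
  checkpoints generation records and the search cache and exits cleanly.
* **Search matching** is case-insensitive substring by default (tolerates
  "alprazolam-based"; configurable to whole-word). Depth budgets are
  per-variant, not shared: each of the four searches scans up to
  `max_depth` results, and the recorded depth is within the matching
  variant.
* **The search cache** is keyed `(term, variant)` and persists as a TSV that
  round-trips bit-exactly. The recorded depth is with respect to the index
  term active when the search was first issued; in practice each candidate
  belongs to a single drug's run, and a shared cache across drugs trades
  that edge case for resumability under daily API quotas.
* **Name matching** between the controlled-substance list and index terms is
  exact case-insensitive equality after trimming. Salt/ester qualifiers
  ("… hydrochloride") therefore do not match the bare generic name; supply a
  pre-normalized list if that matters for your inputs.
* **Live backends** are a contract only (`complete(prompt, params)`,
  `search(query, max_results)`, retry on transient errors, distinct quota
  condition). Requesting `backend: live` without supplying backend objects
  is an error — the package never silently substitutes mocks for live
  services.

## What the synthetic worlds do and do not show

`build_world()` creates a closed universe: per drug, planted true synonyms
(a few of which are seed-lexicon entries), the other drugs' names, and a
shared distractor pool, generated by the mock model from a Zipf-skewed
distribution with synonyms ranked first. Planted synonyms get a search hit
on one variant at a geometrically decaying depth; distractors hit only at a
configurable false-positive rate. This emulates the statistical structure
the pipeline exploits — skewed generation frequencies, depth-decaying hit
quality, confusable same-indication drug names, occasional trailing prose —
and the mock honors temperature qualitatively (argmax at 0, softened
sampling above), giving the sweep harness a monotone diversity knob rather
than a faithful model mechanism; frequency and presence penalties are
accepted but inert in the mock.

Passing tests on these worlds therefore demonstrate that the *machinery* is
correct: the filters compute what they claim, recovery is exact when the
world satisfies the filters' assumptions (no spurious hits, depths within
budget), precision degrades exactly as the closed form predicts under
injected search noise, and runs are deterministic and resumable. They do
not demonstrate anything about real model output or real search ranking:
real slang is polysemous, labels are imperfect, hit depths are not
geometric, and the generation distribution is not Zipf. Full-scale figures
(tens of drugs, a thousand iterations, thousands of generated terms per
drug) require live completion and search services and are documented here
as live-run expectations only.

The test suite uses worlds of 3–5 drugs with 8–30 planted synonyms, 40–200
distractors, and 20–150 iterations per drug — sizes chosen so the whole
suite exercises every path, including two full pipeline runs, in well under
a minute on one core.

## Known limitations

* Novelty is relative to the supplied seed lexicon; a thin seed table
  inflates UNGS counts.
* The search filter anchors validation to current web presence: a plausible
  term not yet used online is dropped. Run without the search filter to
  explore such terms, at the cost of a different validation burden.
* The drug-name filter cannot catch *brand* names of other drugs (only
  generic names are cross-referenced); those survive filtering and must be
  caught by labeling, as the confusable-anxiolytic examples show.
* Completion text containing tabs or newlines inside a single list item
  would not round-trip through the TSV logs; normalized terms never contain
  either.

```{r}
# the pieces in one breath: a tiny world, one drug, one scheme
wdir <- file.path(tempdir(), "vignette_world")
world <- build_world(world_spec(n_index_terms = 2, n_planted = 6, n_seed = 4,
                                n_distractors = 20, rng_seed = 17), wdir)
lex <- load_seed_lexicon(world$paths$seed_lexicon)
sel <- term_selection(lex, lex$index_terms[1])
gen <- run_iterations(sel, mock_completion_backend(world),
                      n_iterations = 30, rng_seed = 1)
flags <- apply_scheme(gen$tallies, c("drug_name", "google"),
                      lex$index_terms, mock_search_backend(world))
head(flags[flags$positive, c("term", "frequency", "first_hit_depth",
                             "matching_variant")])
```
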