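# slanglex

Automated generation of drug-slang lexicons by prompting a large language
model and filtering its output with web-search validation.

## The problem

Pharmacovigilance on social media — detecting and tracking drug-abuse trends
from what people actually post — founders on vocabulary: posts use slang,
brand names, borrowings, and misspellings ("zannies", "xanor", "alprazolan")
that never appear in structured drug dictionaries. Curated lexicons such as
the RedMed word-embedding lexicon help, but extending them has meant training
new embedding models on large forum corpora.

`slanglex` implements an alternative: repeatedly prompt a pre-trained
text-completion language model with a few known synonyms of a drug and
harvest what it adds, then keep only candidates that survive automated
validation. The package provides the full pipeline:

1. **Seed selection** — read a RedMed-style synonym table (nine validation
   categories per drug), intersect its index terms (DrugBank generic names)
   with a controlled-substance list, keep terms with at least three usable
   seed synonyms, and flag a "widely-discussed" subset by Reddit hit counts.
2. **Prompting** — sample three seed synonyms uniformly and render a
   numbered-list prompt ending in a hanging enumerator ("4."), which cues the
   model to continue the list; a counterexample template (non-synonyms listed
   first) is also provided.
3. **Generation & parsing** — a backend-agnostic completion contract, a
   grammar that parses enumerated completions (and stops at trailing prose),
   normalization, and frequency tallies over many iterations.
4. **Filtering** — three composable predicates per candidate term:
   - *search filter*: the term (alone, and with "pill"/"drug"/"slang"
     appended) is web-searched; it passes if the index term appears in a
     title or snippet of the top-*k* results (depth recorded, searches
     memoized, early-terminated);
   - *drug-name filter*: drop candidates that are generic names of other
     drugs (models readily volunteer same-indication drugs);
   - *frequency filter*: drop candidates generated no more than a threshold
     number of times.
5. **Evaluation** — confusion matrices against manual labels and the
   F-measure family, per filtering scheme:

   precision = TP/(TP+FP),  recall = TP/(TP+FN),
   F1 = 2·p·r/(p+r),  F2 = 5·p·r/(4·p+r).

   F2 (the β = 2 F-measure) is emphasized because a missed synonym is
   unrecoverable downstream, while false positives can be filtered later.
   The pipeline's yield metric is the **UNGS** — unique novel generated
   synonym: a filtered candidate absent from the seed lexicon.
6. **Synthetic worlds** — a generator for self-contained test universes
   (seed lexicon, planted ground truth, deterministic mock completion and
   search backends) so everything above runs and is verified offline.

Live API adapters are deliberately out of scope: the package defines the
backend contracts (including quota signalling, retry, checkpoint/resume) and
ships deterministic mocks; any object with a `complete(prompt, params)` or
`search(query, max_results)` function plugs in.

## Worked example

Build a small synthetic world (3 drugs, 8 planted synonyms each, 40
distractors), run the pipeline at 100 iterations per drug, and evaluate:

```r
library(slanglex)

wdir <- file.path(tempdir(), "demo_world")
world <- build_world(world_spec(n_index_terms = 3, n_planted = 8, n_seed = 4,
                                n_distractors = 40, rng_seed = 17), wdir)

cfg <- pipeline_config(seed_lexicon = world$paths$seed_lexicon,
                       controlled = world$paths$controlled,
                       hit_counts = world$paths$hit_counts,
                       world = wdir,
                       out_dir = file.path(tempdir(), "demo_run"),
                       n_iterations = 100, rng_seed = 42)
run <- run_pipeline(cfg)
run$accounts
#>   index_term total_generated unique_generated gpt3_synonyms ungs
#> 1     donube             700               50             8    3
#> 2     kozasu             700               48             8    3
#> 3     labeto             700               50             8    3
```

Each drug yielded 700 generation events (100 iterations × 7 list items), ~50
distinct candidates, of which exactly the 8 planted synonyms pass the final
drug-name + search scheme; 3 of those 8 are novel (not already seed-lexicon
entries). The lexicon rows carry the filter evidence:

```r
head(run$lexicon[, c("index_term", "term", "frequency", "first_hit_depth",
                     "matching_variant", "is_ungs")])
#>   index_term term frequency first_hit_depth matching_variant is_ungs
#> 1     donube fazo        21               1             pill    TRUE
#> 2     donube gava        20               2             drug    TRUE
#> 3     donube rune        86               2             pill   FALSE
#> 4     donube sago        21               2             drug    TRUE
#> 5     donube sepo        51               3            slang   FALSE
#> 6     donube sogi        72               1             drug   FALSE
```

Comparing classification schemes against the world's truth labels for one
drug reproduces the characteristic pattern — all-generated has perfect
recall but poor precision, seed membership has high precision but misses the
novel terms (its two false positives are *other* drugs' seed synonyms, the
confusable-drug phenomenon), and the drug-name + search scheme recovers the
planted truth exactly:

```r
lex  <- load_seed_lexicon(world$paths$seed_lexicon)
lexf <- load_seed_lexicon(world$paths$seed_lexicon, seed_categories(),
                          drop_multiword_known = FALSE)   # novelty reference
it <- lex$index_terms[1]
f <- run$flags[run$flags$index_term == it, ]
labels <- read_labels(world$paths$labels)
tab <- scheme_comparison(f[, c("index_term", "term", "frequency")], f,
                         labels[labels$index_term == it, ], lexf)
round_metrics(tab)[, c("scheme", "tp", "fp", "fn", "precision", "recall", "f1", "f2")]
#>                       scheme tp fp fn precision recall    f1    f2
#> 1              all_generated  8 42  0     0.160  1.000 0.276 0.488
#> 2            seed_membership  5  2  3     0.714  0.625 0.667 0.641
#> 3                  drug_name  8 40  0     0.167  1.000 0.286 0.500
#> 4        drug_name+frequency  8 39  0     0.170  1.000 0.291 0.506
#> 5           drug_name+google  8  0  0     1.000  1.000 1.000 1.000
#> 6 drug_name+frequency+google  8  0  0     1.000  1.000 1.000 1.000
```

A thin command-line interface wraps the same functions
(`exec/slanglex simulate | select | generate | filter | evaluate | lexicon |
sweep`), configured by a YAML file mirroring `pipeline_config()`.

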