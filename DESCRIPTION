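Package: slanglex
Title: Automated Drug-Slang Lexicon Generation via Language-Model
    Prompting and Search-Based Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds lexicons of colloquial drug synonyms (slang,
    misspellings, brand names) for social-media pharmacovigilance.
    Repeatedly prompts a text-completion language model with few-shot
    numbered-list prompts seeded from a known-synonym lexicon, parses the
    enumerated completions into candidate terms, and filters candidates
    with an automated web-search validation filter, a cross-reference
    against known drug generic names, and a generation-frequency
    threshold. Includes precision/recall/F1/F2 evaluation against manual
    labels, a parameter-sweep harness, deterministic mock completion and
    search backends, and a synthetic-world generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
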