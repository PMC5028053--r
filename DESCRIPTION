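Package: phenonorm
Title: Normalisation of Phenotype Mentions to Terminological Concepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps phenotype entity mentions found in clinical narratives and
    biomedical literature to concepts in a terminological resource such as the
    UMLS Metathesaurus. Implements the PhenoNorm hybrid matching algorithm:
    semantic-group filtering of the lexicon, inverted-index candidate retrieval
    with stepwise relaxation of the shared-token constraint, WordNet-style
    generation of semantic variants, combined Levenshtein/length-difference
    scoring, and a character n-gram fallback for run-together spellings.
    Includes exact-match and SoftTFIDF baselines, evaluation with
    coordination-split counting rules (accuracy, precision, recall, F-score,
    concept overlap), deterministic synthetic lexicon and benchmark generators,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
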