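# phenonorm

Normalisation of phenotype entity mentions — the causes, risk factors, and
signs or symptoms of a disease, as they appear in clinical narratives and
biomedical literature — to concepts in a terminological resource such as the
UMLS Metathesaurus.

The same concept surfaces in text in many guises: `light-headedness` vs
`lightheadedness`, `jugular venous pressure is elevated` vs
`elevated jugular venous pressure`, `3VD`, `diabetesmellitus`,
`increased chest pain and fatigue` (which mentions *two* concepts). A
terminology lists synonym strings for each concept but never every surface
form, so anyone linking mentions across text types needs a matcher that
bridges orthographic, morphological, structural and semantic variation. This
package is for text-mining practitioners and corpus builders who have entity
mentions in hand (from annotation or an NER system) and need concept
identifiers out, with no training data required.

## The method

`phenonorm` implements the PhenoNorm algorithm, a hybrid matcher that is
deliberately context-free (it sees only the mention string). For a mention
*m*, after coordination splitting, normalisation, stop-word removal and
abbreviation expansion:

1. semantic variants of *m* are generated by substituting, for each noun or
   adjective token, the words in its synset plus those one *similar-to* hop
   away (`elevated` → `raised`, `increased`);
2. an inverted index retrieves candidate synonyms sharing tokens with any
   variant, relaxing the required overlap from all *n* tokens down one at a
   time and keeping the first non-empty level; when no token overlaps at
   all, the rarest character *n*-gram of each token (n = 5, or 3 for short
   tokens) retrieves candidates instead — this is what recovers run-together
   spellings such as `diabetesmellitus`;
3. an exact match with any variant short-circuits with score 0; otherwise
   every candidate synonym *s* is scored against every variant *v* with

   ```
   score(v, s) = lev(v, s) + lambda * | |v| - |s| |
   ```

   (Levenshtein distance plus weighted absolute character-length
   difference, `lambda = 1` by default) and the candidate with the lowest
   score over any variant wins. The length term keeps qualified mentions on
   qualified concepts: `elevated jugular venous pressure` maps to
   `raised jugular venous pressure`, not to the shorter, more general
   `jugular venous pressure`.

Exact-match and SoftTFIDF baselines, evaluation (accuracy and
precision/recall/F with split-mention counting rules, per category), a
concept-overlap summary, and deterministic synthetic lexicon/benchmark
generators are included, as is a small CLI
(`system.file("cli", "phenonorm.R", package = "phenonorm")`) with
`build-index`, `normalize`, `evaluate` and `simulate` sub-commands.

## A worked example

```r
library(phenonorm)

lex <- example_lexicon()           # bundled toy lexicon (59 concepts)
idx <- build_indexes(lex)
res <- example_synonym_resource()  # qualifier-word synonym table
abb <- example_abbreviations()

normalize_mention("jugular venous pressure is elevated", lex, idx, res, abb)
#> <pheno_normalization> 'jugular venous pressure is elevated'
#>   'jugular venous pressure is elevated' -> C0004 ('raised jugular venous pressure', score 14.0, token-index)

normalize_mention("breast, brain, prostate and kidney cancer", lex, idx, res)
#> <pheno_normalization> 'breast, brain, prostate and kidney cancer'
#>   'breast cancer' -> C0020 ('breast cancer', score 0.0, exact)
#>   'brain cancer' -> C0021 ('brain cancer', score 0.0, exact)
#>   'prostate cancer' -> C0022 ('prostate cancer', score 0.0, exact)
#>   'kidney cancer' -> C0023 ('kidney cancer', score 0.0, exact)

normalize_mention("diabetesmellitus", lex, idx)
#> <pheno_normalization> 'diabetesmellitus'
#>   'diabetesmellitus' -> C0008 ('diabetes mellitus', score 2.0, ngram-fallback)

normalize_mention("3vd", lex, idx, res, abb)
#> <pheno_normalization> '3vd'
#>   '3vd' -> C0019 ('three vessel disease', score 0.0, exact)
```

The first mention is a full clause: stop-word removal and token-level
retrieval reach the qualified concept through the variant `elevated` →
`raised`, and the score (14) is the reordering cost between the normalised
clause and the winning synonym. The coordinated phrase is split four ways,
each conjunct inheriting the shared head `cancer` and matching its own
neoplasm concept exactly. The run-together mention reaches its concept
through the rarest-gram fallback (edit distance 1 plus length difference 1
= score 2), and the acronym is expanded from the abbreviation dictionary
before matching.

On real resources, load a lexicon with `load_rrf_lexicon("MRCONSO.RRF",
"MRSTY.RRF")` or `load_tsv_lexicon()`, filter it with
`filter_by_semantic_group(lex, disorder_group())`, and feed standoff mention
files through `normalize_mentions()` / `cmd_normalize()`.

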