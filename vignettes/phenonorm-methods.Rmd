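---
title: "Normalising phenotype mentions: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalising phenotype mentions: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(phenonorm)
```

## The problem

Phenotype concepts — the causes, risk factors, and signs or symptoms of a
disease — are mentioned in clinical narratives and in the literature in
highly variable ways: `jugular venous pressure is elevated`,
`light-headedness`, `3VD`, `increased chest pain and fatigue`. Downstream
integration of such text needs each mention linked to the unique concept it
denotes in a terminological resource (for the UMLS Metathesaurus, a CUI).
Resources list several synonym strings per concept, but never every surface
form, so normalisation must bridge orthographic, morphological, structural
and semantic gaps between mention and synonym.

This package implements the PhenoNorm algorithm, a hybrid of token-level
retrieval, character-level edit distance, and word-level semantic variant
generation, designed for exactly this variability. It is deliberately
context-free: only the mention string itself is consulted, never the
surrounding sentence.

## The procedure

A lexicon is loaded from UMLS RRF files or a plain TSV, filtered to a
semantic group (by default the conventional Disorders-group inventory of
twelve semantic types, shipped in `disorder_group()` and fully
overrideable — tools disagree on this boundary, and the choice matters, e.g.
whether the Finding type is included), and indexed two ways: an inverted
index from token to synonyms, and a character n-gram index.

For each mention:

1. **Coordination splitting.** Conjuncts joined by *and*/*or*/commas with a
   shared trailing head or shared leading qualifier are expanded into
   separate sub-mentions (`stable or unstable angina` becomes
   `stable angina` + `unstable angina`). Splitting is unconditional — even
   when the target resource happens to list the coordination as a single
   concept, a documented failure mode — and can be disabled with
   `split = FALSE`.
2. **Normalisation.** Lower-casing; intra-word hyphens/slashes collapsed
   (`light-headedness` → `lightheadedness`); punctuation as separators;
   stop-word removal (a small clinical-safe list that deliberately keeps
   negation words); dictionary-based abbreviation expansion, always taking
   the first-listed expansion — context-free by design.
3. **Semantic variants.** Each token is mapped to its alternatives: the same
   synset plus exactly one *similar-to* hop (capturing chains such as
   *elevated* / *raised* / *increased*), nouns and adjectives only,
   single-word substitutes only. The Cartesian product of per-token
   alternative sets gives the variant set, original first, capped.
4. **Exact match.** If any variant string equals a synonym string, that
   synonym's concept is returned with score 0.
5. **Retrieval with relaxation.** The inverted index yields, for every
   variant, the synonyms sharing its tokens; the shared-token requirement is
   relaxed from *all n* tokens downwards, pooling candidates across variants
   at each level, and the first non-empty level is kept. Candidates may
   carry extra tokens — this is what lets a qualified synonym
   (`high blood pressure`) survive for a mention using a different qualifier
   (`heightened blood pressure`).
6. **n-gram fallback.** If no token of any variant occurs in any synonym
   (run-together spellings such as `diabetesmellitus`), each token's rarest
   indexed n-gram retrieves candidates instead.
7. **Scoring.** Every candidate is scored against every variant with
   `edit_distance + length_weight * length_difference`; the candidate with
   the lowest score over any variant wins. Length matters for specificity: a
   mention carrying a qualifier should map to a qualified concept of similar
   overall length, not to the shortest synonym sharing the most words. The
   same property produces the two documented failure modes the
   implementation intentionally reproduces (`chronic leg edema` →
   `chronic leg ulcer`; `increased oxygen requirement` →
   `increased insulin requirement`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ngram_default` | 5 | fallback gram size (characters) |
| `ngram_short` | 3 | gram size for tokens shorter than the threshold |
| `short_token_threshold` | 5 | characters below which the short gram size applies |
| `length_weight` | 1 | weight of the length-difference term in the score |
| `variant_cap` | 256 | maximum variants per sub-mention |
| `relaxation_floor` | 1 | smallest shared-token level before the fallback |

The combined score is stated in the source method only as depending on
"both" the edit distance and the length difference; an additive form with a
tunable weight is the simplest faithful reading, and `length_weight = 1`
already reproduces every documented mapping and failure mode. Note the edit
distance is itself bounded below by the length difference, so the weight
amplifies an existing penalty.

Ties on the combined score are broken deterministically: more shared
tokens, then the shorter synonym, then the smallest concept id, then the
smallest synonym id. The original formulation does not state a tie policy;
determinism is the requirement here.

Degenerate inputs: a mention that is all stop words is unnormalisable and
reported unmapped; tokens shorter than a gram size are indexed and queried
as whole-token grams (otherwise such synonyms would be unreachable); grams
never seen in the index are ignored when choosing the rarest gram — a
zero-frequency gram retrieves nothing, so the minimum is taken over seen
grams only, leftmost on ties.

## Baselines

`baseline_exact()` maps only on normalised string equality.
`baseline_soft_tfidf()` implements SoftTFIDF: tokens pair when their
Jaro-Winkler similarity reaches 0.9 (the reference implementation's
default), each pair contributing the product of the two tokens' L2-normalised
TF-IDF weights and the character similarity, with IDF estimated over the
lexicon's synonym strings. Its characteristic error — preferring the
shortest synonym with the most exactly-shared tokens, thereby dropping
qualifier information — emerges from the weighting itself and is exercised
in the tests.

## What the synthetic generator emulates

`generate_lexicon()` builds concepts whose synonyms are pronounceable
pseudo-word phrases of 1–6 tokens: each concept owns a unique anchor word
(so the task is well-posed) plus context words from a shared pool (so
concepts overlap in vocabulary and retrieval is non-trivial). A quarter of
concepts, by default, come as qualified sibling pairs — the same base phrase
under `increased` versus `decreased` — because qualified concepts are the
centrepiece of the method's design. Synthetic vocabulary words are kept at
least three edits apart: distinct content words in real terminologies are
rarely a typo apart, and the perturbation budget (two character edits) must
not be able to cross word identity.

`perturb_synonym()` emulates the documented variation classes — word
reordering, character edits with a hard Levenshtein budget, run-together
spellings, qualifier substitution within semantic clusters, suffix
alternation. Each operation listed in the perturbation spec is applied with
probability one half per mention, so a benchmark mixes exact, mildly and doubly
perturbed mentions the way a corpus mixes exact and variant phrasings.

What the generator does **not** model: discourse, negation, context
sensitivity, abbreviation ambiguity resolved by context, multi-word-to-
one-word semantic mappings (`increased oxygen requirement` → `hypoxia` is
out of reach by design), or the extreme synonym-count skew of the full
Metathesaurus. Passing the synthetic recovery tests therefore demonstrates
the mechanics of retrieval, scoring and variant generation, not corpus-level
accuracy on real clinical text.

## Problem sizes used by the test-suite

The shipped tests run entirely offline: the bundled example lexicon (59
concepts, 68 synonyms, every target accompanied by distractors sharing
surface tokens); oracle-equivalence checks against a brute-force scan on 20
random lexicons of about 140 synonyms with 5 mentions each; recovery and baseline
ordering on 500-mention benchmarks over a 100-concept lexicon; and metric
properties on 1,000 random string pairs. These sizes keep the full suite
under a minute while giving every code path multiple independent checks.

## Evaluation conventions

Accuracy is correct/total. For a mention the system split into several
concepts, the default accuracy unit is the whole annotation — every
sub-mapping must be right — with `unit = "sub_mention"` as the alternative
reading, since the original accuracy unit for split mentions is not fully
specified. Precision/recall/F use the split-mention counting rules: a
correct mapping is a TP; a single-concept mention mapped to one wrong
concept is an FN; a single-concept mention wrongly split into two concepts
is one FP plus one FN, generalised to k-way splits as one FN plus (k − 1)
FP; mentions left unmapped count as FN. Undefined ratios are reported as
missing, never as zero.

## Known limitations

* Word-class lookup replaces part-of-speech tagging: a token is treated as a
  noun/adjective exactly when the synonym resource has such an entry for it.
  Mentions are short fragments where taggers are unreliable, but this means
  resource coverage directly bounds variant quality.
* Spelling errors are never corrected; they are absorbed (or not) by the
  edit-distance scoring.
* The method always maps when any candidate exists; unmapped is reserved for
  empty candidate sets, so there is no confidence thresholding.
* Coordination splitting is rule-based over shallow patterns; elliptical
  constructions outside the shared-head/shared-modifier patterns pass
  through unsplit.

## A worked example

```{r example}
lex <- example_lexicon()
idx <- build_indexes(lex)
res <- example_synonym_resource()
abb <- example_abbreviations()

normalize_mention("jugular venous pressure is elevated", lex, idx, res, abb)
normalize_mention("breast, brain, prostate and kidney cancer", lex, idx, res)
normalize_mention("diabetesmellitus", lex, idx)
```
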