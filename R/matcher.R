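#' Matcher configuration
#'
#' Tunable parameters of the matching algorithm.
#'
#' @param ngram_default gram size used by the n-gram fallback (default 5).
#' @param ngram_short gram size for short tokens (default 3).
#' @param short_token_threshold tokens with fewer characters than this use
#'   `ngram_short` (default 5).
#' @param length_weight non-negative coefficient (lambda) on the absolute
#'   character-length difference in the combined score (default 1). The edit
#'   distance is already bounded below by the length difference, so lambda
#'   amplifies length mismatch on top of that bound.
#' @param variant_cap maximum number of semantic variants per mention
#'   (default 256).
#' @param relaxation_floor smallest shared-token count considered during
#'   constraint relaxation before the n-gram fallback takes over (default 1).
#' @param tie_break tie-breaking policy for equal combined scores; the single
#'   shipped policy `"shared_tokens"` prefers the candidate sharing more
#'   tokens, then the shorter synonym, then the lexicographically smallest
#'   concept id.
#' @return A list of class `pheno_matcher_config`.
#' @export
matcher_config <- function(ngram_default = 5L, ngram_short = 3L,
                           short_token_threshold = 5L, length_weight = 1,
                           variant_cap = 256L, relaxation_floor = 1L,
                           tie_break = "shared_tokens") {
  stopifnot(ngram_default >= 1L, ngram_short >= 1L, length_weight >= 0,
            relaxation_floor >= 1L, variant_cap >= 1L)
  structure(
    list(ngram_default = as.integer(ngram_default),
         ngram_short = as.integer(ngram_short),
         short_token_threshold = as.integer(short_token_threshold),
         length_weight = as.numeric(length_weight),
         variant_cap = as.integer(variant_cap),
         relaxation_floor = as.integer(relaxation_floor),
         tie_break = match.arg(tie_break, "shared_tokens")),
    class = "pheno_matcher_config"
  )
}

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and substitutions
#' transforming one string into the other.
#'
#' @param a,b character vectors, recycled to a common length.
#' @return An integer vector of elementwise distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- integer(n)
  for (i in seq_len(n)) d[i] <- utils::adist(a[i], b[i])[1L, 1L]
  d
}

#' Combined similarity score between a mention and a synonym
#'
#' The score joins two signals: the Levenshtein distance between the two
#' normalised strings, and the absolute difference of their character
#' lengths, weighted by `length_weight`. Length matters for qualified
#' concepts: a mention carrying a qualifier should prefer a qualified synonym
#' of similar overall length over a shorter, more general one. Lower combined
#' scores mean higher similarity; the combined score is zero exactly when the
#' strings are identical.
#'
#' @param mention_string,synonym_string normalised strings (tokens joined by
#'   single spaces); `synonym_string` may be a vector.
#' @param config a [matcher_config()].
#' @return A data frame with columns `edit_distance`, `length_difference`,
#'   `combined`, one row per synonym string.
#' @export
score <- function(mention_string, synonym_string, config = matcher_config()) {
  ed <- drop(utils::adist(mention_string, synonym_string))
  ld <- abs(nchar(mention_string) - nchar(synonym_string))
  data.frame(edit_distance = as.integer(ed),
             length_difference = as.integer(ld),
             combined = as.numeric(ed + config$length_weight * ld))
}

# shared-token count of every usable synonym against one token set
shared_counts <- function(tokens, inverted_index, n_synonyms) {
  hits <- unlist(unclass(inverted_index)[unique(tokens)], use.names = FALSE)
  if (is.null(hits) || length(hits) == 0L) return(integer(0))
  counts <- tabulate(hits, nbins = n_synonyms)
  which_pos <- which(counts > 0L)
  setNames(counts[which_pos], which_pos)
}

#' Retrieve candidate synonyms by token intersection with relaxation
#'
#' For every variant of the mention, the inverted index supplies the synonyms
#' containing each token; synonyms are ranked by how many distinct variant
#' tokens they share. Starting from the full token count, the shared-count
#' constraint is relaxed one token at a time — candidates from all variants
#' are pooled at each level before relaxing further — and the first non-empty
#' level wins. Candidates may contain additional non-matching tokens, which
#' is what lets a qualified synonym (e.g. `high blood pressure`) survive for
#' a mention using a different qualifier. An empty result (no token of any
#' variant occurs in any synonym at or above `relaxation_floor`) signals the
#' caller to fall back to n-gram retrieval.
#'
#' @param variant_set a [generate_variants()] result.
#' @param inverted_index a [build_inverted_index()] result.
#' @param lexicon the `pheno_lexicon` the index was built from.
#' @param config a [matcher_config()].
#' @return A data frame with columns `synonym_id`, `shared_token_count`,
#'   `source` (`"token-index"`), `variant_index`; zero rows when nothing was
#'   retrieved.
#' @export
retrieve_candidates <- function(variant_set, inverted_index, lexicon,
                                config = matcher_config()) {
  stopifnot(inherits(variant_set, "pheno_variant_set"))
  n_syn <- nrow(lexicon$synonyms)
  per_variant <- lapply(variant_set$variants, shared_counts,
                        inverted_index = inverted_index, n_synonyms = n_syn)
  k_star <- suppressWarnings(max(0L, unlist(lapply(per_variant, max))))
  if (!is.finite(k_star) || k_star < config$relaxation_floor) {
    return(data.frame(synonym_id = integer(0), shared_token_count = integer(0),
                      source = character(0), variant_index = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(per_variant), function(v) {
    counts <- per_variant[[v]]
    sel <- counts == k_star
    if (!any(sel)) return(NULL)
    data.frame(synonym_id = as.integer(names(counts)[sel]),
               shared_token_count = unname(counts[sel]),
               variant_index = v, stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, rows)
  pooled <- pooled[!duplicated(pooled$synonym_id), , drop = FALSE]
  pooled <- pooled[order(pooled$synonym_id), , drop = FALSE]
  data.frame(synonym_id = pooled$synonym_id,
             shared_token_count = pooled$shared_token_count,
             source = "token-index", variant_index = pooled$variant_index,
             stringsAsFactors = FALSE)
}

#' Retrieve candidates through the character n-gram fallback
#'
#' Used when no token of the mention (or of any variant) occurs in any
#' synonym, typically for run-together or badly misspelled mentions such as
#' `diabetesmellitus`. For each token, the synonyms containing the token's
#' rarest indexed n-gram (see [rarest_ngram()]) are retrieved; scoring then
#' proceeds exactly as for token-index candidates.
#'
#' @param tokens the mention's normalised tokens.
#' @param ngram_index a [build_ngram_index()] result.
#' @param lexicon the `pheno_lexicon` the index was built from.
#' @param config a [matcher_config()].
#' @return A data frame in the same shape as [retrieve_candidates()], with
#'   `source = "ngram-fallback"` and `shared_token_count = 0`.
#' @export
ngram_fallback_candidates <- function(tokens, ngram_index, lexicon,
                                      config = matcher_config()) {
  ids <- integer(0)
  for (tok in tokens) {
    g <- rarest_ngram(tok, ngram_index, config)
    if (!is.na(g)) ids <- c(ids, ngram_index$postings[[g]])
  }
  ids <- sort(unique(ids))
  data.frame(synonym_id = ids,
             shared_token_count = rep(0L, length(ids)),
             source = rep("ngram-fallback", length(ids)),
             variant_index = rep(1L, length(ids)),
             stringsAsFactors = FALSE)
}

#' Build all retrieval structures for a lexicon
#'
#' Convenience bundle: the token inverted index, the character n-gram index,
#' and an exact-match table from normalised synonym string to synonym ids.
#'
#' @param lexicon a `pheno_lexicon`.
#' @param config a [matcher_config()].
#' @return A list of class `pheno_indexes` with elements `inverted`, `ngram`,
#'   `exact`, and `format_version`.
#' @export
build_indexes <- function(lexicon, config = matcher_config()) {
  use <- lexicon$synonyms$usable
  exact <- split(lexicon$synonyms$synonym_id[use],
                 lexicon$synonyms$norm_text[use])
  structure(
    list(inverted = build_inverted_index(lexicon),
         ngram = build_ngram_index(lexicon,
                                   c(config$ngram_short, config$ngram_default)),
         exact = exact,
         format_version = 1L),
    class = "pheno_indexes"
  )
}

# deterministic selection among scored candidates:
# lowest combined, then most shared tokens, then shortest synonym,
# then smallest concept_id, then smallest synonym_id
select_best <- function(cand, lexicon) {
  ord <- order(cand$combined, -cand$shared_token_count, cand$char_length,
               cand$concept_id, cand$synonym_id, method = "radix")
  cand[ord[1L], , drop = FALSE]
}

score_candidates <- function(cand, variant_strings, lexicon, config) {
  syn <- lexicon$synonyms[match(cand$synonym_id, lexicon$synonyms$synonym_id), ]
  d <- utils::adist(variant_strings, syn$norm_text)
  l <- abs(outer(nchar(variant_strings), nchar(syn$norm_text), `-`))
  comb <- d + config$length_weight * l
  # best achievable score per candidate over the original and all variants
  cand$combined <- apply(comb, 2L, min)
  cand$concept_id <- syn$concept_id
  cand$char_length <- syn$char_length
  cand$synonym <- syn$raw_text
  cand
}

#' Normalise a phenotype mention to a concept
#'
#' The full matching pipeline for one mention string:
#'
#' 1. the mention is split into coordinated sub-phrases (optional);
#' 2. each sub-phrase is normalised, stop words removed and abbreviations
#'    expanded;
#' 3. semantic variants are generated by word-level synonym substitution
#'    (optional);
#' 4. if the normalised sub-phrase or any variant equals a synonym string,
#'    that synonym's concept is returned immediately with score 0;
#' 5. otherwise candidates are retrieved by token intersection with stepwise
#'    relaxation, falling back to rarest-n-gram retrieval when no token
#'    overlaps the lexicon at all;
#' 6. the candidate synonym minimising the combined Levenshtein +
#'    length-difference score against the sub-phrase or any of its variants
#'    wins; ties break deterministically (more shared tokens, shorter
#'    synonym, smallest concept id).
#'
#' A sub-phrase is unmapped only when it is unnormalisable (all stop words)
#' or every retrieval path, including the fallback, returned nothing.
#'
#' @param raw_text the mention string.
#' @param lexicon a `pheno_lexicon` (typically semantic-group filtered).
#' @param indexes a [build_indexes()] result for `lexicon`; built on the fly
#'   when `NULL`.
#' @param resource a [read_synonym_resource()] object or `NULL` to disable
#'   semantic variants.
#' @param abbreviations a [read_abbreviations()] dictionary or `NULL`.
#' @param config a [matcher_config()].
#' @param split split coordinated phrases? (default `TRUE`)
#' @param use_variants generate semantic variants? (default `TRUE`; ignored
#'   when `resource` is `NULL`)
#' @param stop_words stop words for mention preprocessing; defaults to the
#'   list stored in the lexicon so both sides normalise identically.
#' @return An object of class `pheno_normalization`: list with `raw_text`,
#'   `mappings` (data frame: `sub_phrase`, `concept_id`, `synonym_id`,
#'   `synonym`, `score`, `source`, one row per sub-phrase; `NA` concept where
#'   unmapped), and `unmapped` (`TRUE` when every sub-phrase failed).
#' @export
normalize_mention <- function(raw_text, lexicon, indexes = NULL,
                              resource = NULL, abbreviations = NULL,
                              config = matcher_config(), split = TRUE,
                              use_variants = TRUE,
                              stop_words = lexicon$stop_words) {
  stopifnot(inherits(lexicon, "pheno_lexicon"))
  if (is.null(indexes)) indexes <- build_indexes(lexicon, config)
  phrases <- if (split) split_coordination(raw_text) else trimws(raw_text)

  mappings <- lapply(phrases, function(phrase) {
    unmapped_row <- data.frame(
      sub_phrase = phrase, concept_id = NA_character_,
      synonym_id = NA_integer_, synonym = NA_character_, score = NA_real_,
      source = "unmapped", stringsAsFactors = FALSE)
    tokens <- expand_abbreviations(normalize_tokens(phrase, stop_words),
                                   abbreviations, stop_words)
    if (length(tokens) == 0L) return(unmapped_row)

    vs <- if (use_variants && !is.null(resource))
      generate_variants(tokens, resource, cap = config$variant_cap)
    else generate_variants(tokens, NULL, cap = config$variant_cap)
    variant_strings <- vapply(vs$variants, paste, character(1), collapse = " ")

    # exact-match short-circuit: original first, then variants in order
    for (v in variant_strings) {
      hit <- indexes$exact[[v]]
      if (!is.null(hit)) {
        syn <- lexicon$synonyms[match(hit, lexicon$synonyms$synonym_id), ]
        pick <- order(syn$concept_id, syn$synonym_id, method = "radix")[1L]
        return(data.frame(
          sub_phrase = phrase, concept_id = syn$concept_id[pick],
          synonym_id = syn$synonym_id[pick], synonym = syn$raw_text[pick],
          score = 0, source = "exact", stringsAsFactors = FALSE))
      }
    }

    cand <- retrieve_candidates(vs, indexes$inverted, lexicon, config)
    if (nrow(cand) == 0L)
      cand <- ngram_fallback_candidates(tokens, indexes$ngram, lexicon, config)
    if (nrow(cand) == 0L) return(unmapped_row)

    cand <- score_candidates(cand, variant_strings, lexicon, config)
    best <- select_best(cand, lexicon)
    data.frame(sub_phrase = phrase, concept_id = best$concept_id,
               synonym_id = best$synonym_id, synonym = best$synonym,
               score = best$combined, source = best$source,
               stringsAsFactors = FALSE)
  })
  mappings <- do.call(rbind, mappings)
  rownames(mappings) <- NULL
  structure(list(raw_text = raw_text, mappings = mappings,
                 unmapped = all(is.na(mappings$concept_id))),
            class = "pheno_normalization")
}

#' @export
print.pheno_normalization <- function(x, ...) {
  cat(sprintf("<pheno_normalization> '%s'%s\n", x$raw_text,
              if (x$unmapped) " [unmapped]" else ""))
  for (i in seq_len(nrow(x$mappings))) {
    m <- x$mappings[i, ]
    if (is.na(m$concept_id)) {
      cat(sprintf("  '%s' -> <unmapped>\n", m$sub_phrase))
    } else {
      cat(sprintf("  '%s' -> %s ('%s', score %.1f, %s)\n", m$sub_phrase,
                  m$concept_id, m$synonym, m$score, m$source))
    }
  }
  invisible(x)
}

#' Normalise a vector of mentions
#'
#' Applies [normalize_mention()] to each string and binds the per-sub-phrase
#' mappings into one data frame.
#'
#' @param texts character vector of mention strings.
#' @param mention_ids optional identifiers, recycled against `texts`.
#' @inheritParams normalize_mention
#' @return A data frame with columns `mention_id`, `raw_text`, `sub_phrase`,
#'   `concept_id`, `synonym_id`, `synonym`, `score`, `source`.
#' @export
normalize_mentions <- function(texts, lexicon, indexes = NULL,
                               resource = NULL, abbreviations = NULL,
                               config = matcher_config(), split = TRUE,
                               use_variants = TRUE,
                               mention_ids = NULL) {
  if (is.null(indexes)) indexes <- build_indexes(lexicon, config)
  if (is.null(mention_ids)) mention_ids <- sprintf("m%04d", seq_along(texts))
  out <- lapply(seq_along(texts), function(i) {
    res <- normalize_mention(texts[i], lexicon, indexes, resource,
                             abbreviations, config, split, use_variants)
    cbind(data.frame(mention_id = mention_ids[i], raw_text = texts[i],
                     stringsAsFactors = FALSE),
          res$mappings)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exact-match baseline
#'
#' Maps a mention only when its normalised string equals a synonym's
#' normalised string (so pure case or punctuation differences still match);
#' otherwise the mention is left unmapped. No splitting, no variants, no
#' approximate matching — the floor any flexible matcher must beat.
#'
#' @inheritParams normalize_mention
#' @return A `pheno_normalization` object.
#' @export
baseline_exact <- function(raw_text, lexicon, indexes = NULL,
                           stop_words = lexicon$stop_words) {
  if (is.null(indexes)) indexes <- build_indexes(lexicon)
  tokens <- normalize_tokens(raw_text, stop_words)
  key <- paste(tokens, collapse = " ")
  hit <- if (length(tokens) > 0L) indexes$exact[[key]] else NULL
  if (is.null(hit)) {
    mappings <- data.frame(sub_phrase = trimws(raw_text),
                           concept_id = NA_character_,
                           synonym_id = NA_integer_, synonym = NA_character_,
                           score = NA_real_, source = "unmapped",
                           stringsAsFactors = FALSE)
  } else {
    syn <- lexicon$synonyms[match(hit, lexicon$synonyms$synonym_id), ]
    pick <- order(syn$concept_id, syn$synonym_id, method = "radix")[1L]
    mappings <- data.frame(sub_phrase = trimws(raw_text),
                           concept_id = syn$concept_id[pick],
                           synonym_id = syn$synonym_id[pick],
                           synonym = syn$raw_text[pick], score = 0,
                           source = "exact", stringsAsFactors = FALSE)
  }
  structure(list(raw_text = raw_text, mappings = mappings,
                 unmapped = is.na(mappings$concept_id[1L])),
            class = "pheno_normalization")
}
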