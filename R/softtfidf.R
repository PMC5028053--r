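#' SoftTFIDF baseline
#'
#' A hybrid token/character string-similarity baseline. Tokens of the mention
#' are paired with tokens of a synonym when their Jaro-Winkler similarity
#' reaches a threshold (default 0.9, the reference implementation's default),
#' and each pairing contributes the product of the two tokens' normalised
#' TF-IDF weights and the character similarity. IDF is estimated over the
#' lexicon's normalised synonym strings, which act as the document
#' collection; token weights are `log(tf) + 1` times `log(N / df)`,
#' L2-normalised within each string. The mention maps to the concept of the
#' synonym with the highest similarity; ties prefer the shorter synonym, then
#' the smallest concept id. Identical strings score exactly 1.
#'
#' `soft_tfidf_model()` precomputes the token statistics once;
#' `baseline_soft_tfidf()` scores one mention against the whole lexicon.
#'
#' @param lexicon a `pheno_lexicon`.
#' @param threshold Jaro-Winkler token-pairing threshold in (0, 1].
#' @return `soft_tfidf_model()` returns an object of class
#'   `pheno_softtfidf`; `baseline_soft_tfidf()` returns a
#'   `pheno_normalization` object whose `score` column holds the similarity
#'   (higher is better, unlike the main matcher's cost score).
#' @export
soft_tfidf_model <- function(lexicon, threshold = 0.9) {
  stopifnot(inherits(lexicon, "pheno_lexicon"), threshold > 0, threshold <= 1)
  use <- which(lexicon$synonyms$usable)
  toks <- lexicon$tokens[use]
  n_doc <- length(toks)
  df <- table(unlist(lapply(toks, unique)))
  idf <- log(n_doc / as.numeric(df))
  names(idf) <- names(df)
  weights <- lapply(toks, function(tk) {
    tf <- table(tk)
    w <- (log(as.numeric(tf)) + 1) * idf[names(tf)]
    w / sqrt(sum(w^2))
  })
  structure(
    list(synonym_id = lexicon$synonyms$synonym_id[use],
         concept_id = lexicon$synonyms$concept_id[use],
         raw_text = lexicon$synonyms$raw_text[use],
         norm_text = lexicon$synonyms$norm_text[use],
         char_length = lexicon$synonyms$char_length[use],
         weights = weights,
         idf = idf, n_doc = n_doc, threshold = threshold,
         stop_words = lexicon$stop_words),
    class = "pheno_softtfidf"
  )
}

# TF-IDF weights for an out-of-collection string; unseen tokens get the
# maximum attainable IDF, log(N / 1)
mention_weights <- function(tokens, model) {
  tf <- table(tokens)
  idf <- model$idf[names(tf)]
  idf[is.na(idf)] <- log(model$n_doc)
  w <- (log(as.numeric(tf)) + 1) * idf
  setNames(w / sqrt(sum(w^2)), names(tf))
}

soft_tfidf_similarity <- function(mention_tokens, model,
                                  simmat = NULL, vocab = NULL) {
  wm <- mention_weights(mention_tokens, model)
  m_tok <- names(wm)
  if (is.null(simmat)) {
    vocab <- sort(unique(names(model$idf)))
    simmat <- jaro_winkler_matrix(m_tok, vocab)
    rownames(simmat) <- m_tok
    colnames(simmat) <- vocab
  }
  vapply(seq_along(model$weights), function(i) {
    ws <- model$weights[[i]]
    s_tok <- names(ws)
    sims <- simmat[m_tok, s_tok, drop = FALSE]
    best_j <- max.col(sims, ties.method = "first")
    best <- sims[cbind(seq_along(m_tok), best_j)]
    ok <- best >= model$threshold
    if (!any(ok)) return(0)
    sum(wm[ok] * ws[best_j[ok]] * best[ok])
  }, numeric(1))
}

#' @param raw_text the mention string.
#' @param model a `pheno_softtfidf` model; built on the fly from `lexicon`
#'   when `NULL`.
#' @rdname soft_tfidf_model
#' @export
baseline_soft_tfidf <- function(raw_text, lexicon, model = NULL,
                                threshold = 0.9) {
  if (is.null(model)) model <- soft_tfidf_model(lexicon, threshold)
  tokens <- normalize_tokens(raw_text, model$stop_words)
  mappings <- data.frame(sub_phrase = trimws(raw_text),
                         concept_id = NA_character_, synonym_id = NA_integer_,
                         synonym = NA_character_, score = NA_real_,
                         source = "unmapped", stringsAsFactors = FALSE)
  if (length(tokens) > 0L) {
    sims <- soft_tfidf_similarity(tokens, model)
    if (any(sims > 0)) {
      ord <- order(-sims, model$char_length, model$concept_id,
                   model$synonym_id, method = "radix")
      pick <- ord[1L]
      mappings <- data.frame(sub_phrase = trimws(raw_text),
                             concept_id = model$concept_id[pick],
                             synonym_id = model$synonym_id[pick],
                             synonym = model$raw_text[pick],
                             score = sims[pick], source = "softtfidf",
                             stringsAsFactors = FALSE)
    }
  }
  structure(list(raw_text = raw_text, mappings = mappings,
                 unmapped = is.na(mappings$concept_id[1L])),
            class = "pheno_normalization")
}

# batch scoring with one shared mention-token x lexicon-vocabulary
# similarity matrix; used by benchmarks and the CLI
baseline_soft_tfidf_batch <- function(texts, model) {
  token_sets <- lapply(texts, normalize_tokens, stop_words = model$stop_words)
  m_vocab <- sort(unique(unlist(token_sets)))
  vocab <- sort(unique(names(model$idf)))
  simmat <- jaro_winkler_matrix(m_vocab, vocab)
  rownames(simmat) <- m_vocab
  colnames(simmat) <- vocab
  out <- lapply(seq_along(texts), function(i) {
    tokens <- token_sets[[i]]
    if (length(tokens) == 0L) {
      return(data.frame(raw_text = texts[i], concept_id = NA_character_,
                        synonym_id = NA_integer_, score = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sims <- soft_tfidf_similarity(tokens, model, simmat = simmat)
    if (!any(sims > 0)) {
      return(data.frame(raw_text = texts[i], concept_id = NA_character_,
                        synonym_id = NA_integer_, score = NA_real_,
                        stringsAsFactors = FALSE))
    }
    pick <- order(-sims, model$char_length, model$concept_id,
                  model$synonym_id, method = "radix")[1L]
    data.frame(raw_text = texts[i], concept_id = model$concept_id[pick],
               synonym_id = model$synonym_id[pick], score = sims[pick],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
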