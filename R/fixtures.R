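# pronounceable pseudo-word vocabulary: three CV syllables, deterministic
# order, greedily filtered so that any two words are >= 3 edits apart —
# distinct content words in real terminologies are rarely a typo apart, and
# the perturbation generators rely on small edits not crossing word identity
synthetic_vocabulary <- function(n) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
                  "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(consonants, vowels, paste0))
  m <- length(syl)
  idx <- (seq_len(1000L) * 617L) %% (m^3)
  pool <- unique(paste0(syl[idx %% m + 1L],
                        syl[(idx %/% m) %% m + 1L],
                        syl[(idx %/% (m^2)) %% m + 1L]))
  d <- utils::adist(pool, pool)
  kept <- integer(0)
  for (i in seq_along(pool)) {
    if (length(kept) == n) break
    if (length(kept) == 0L || min(d[i, kept]) >= 3L) kept <- c(kept, i)
  }
  if (length(kept) < n) stop("synthetic vocabulary exhausted")
  pool[kept]
}

# qualifier clusters drawn from the bundled synonym resource: words within a
# cluster are mutual semantic variants, across clusters they are opposites
default_qualifier_clusters <- function() {
  list(c("increased", "elevated", "raised"),
       c("decreased", "reduced", "worsening"))
}

#' Generate a deterministic synthetic lexicon
#'
#' Builds a lexicon of pronounceable multi-token synonym strings with
#' controlled token overlap between concepts. Every concept carries a unique
#' anchor token (so the mapping task is well-posed) plus zero or more context
#' tokens drawn from a shared pool (so distinct concepts share vocabulary and
#' candidate retrieval is non-trivial). A configurable fraction of concepts
#' come in qualified sibling pairs — the same base phrase prefixed with
#' opposing qualifiers (`increased` vs `decreased`), mirroring the qualified
#' concepts that make phenotype normalisation hard. Additional synonyms per
#' concept are token reorderings or morphological-suffix variants of the base
#' string. All semantic types are drawn from the Disorders group inventory.
#'
#' @param n_concepts number of concepts (>= 1).
#' @param synonyms_per_concept synonyms listed per plain concept (>= 1);
#'   qualified siblings always have one synonym each.
#' @param seed integer seed; identical inputs yield identical lexicons.
#' @param qualified_fraction fraction of concepts allocated to qualified
#'   sibling pairs (default 0.25).
#' @return A `pheno_lexicon` with provenance `"synthetic"`.
#' @export
generate_lexicon <- function(n_concepts, synonyms_per_concept = 2L, seed = 1L,
                             qualified_fraction = 0.25) {
  stopifnot(n_concepts >= 1L, synonyms_per_concept >= 1L,
            qualified_fraction >= 0, qualified_fraction <= 1)
  with_seed(seed, {
    n_pairs <- floor(n_concepts * qualified_fraction / 2)
    n_plain <- n_concepts - 2L * n_pairs
    context_pool <- synthetic_vocabulary(70L + n_concepts)[1:60]
    anchors <- synthetic_vocabulary(70L + n_concepts)[-(1:60)]
    anchors <- sample(anchors)
    disorder_types <- disorder_group()$member_types

    rows_cid <- character(0); rows_type <- character(0); rows_syn <- character(0)
    add_row <- function(cid, type, syn) {
      rows_cid <<- c(rows_cid, cid)
      rows_type <<- c(rows_type, type)
      rows_syn <<- c(rows_syn, syn)
    }
    cid_counter <- 0L
    next_cid <- function() {
      cid_counter <<- cid_counter + 1L
      sprintf("C%04d", cid_counter)
    }
    base_phrase <- function(anchor) {
      n_ctx <- sample(1:3, 1L)
      toks <- c(anchor, sample(context_pool, n_ctx))
      sample(toks)
    }
    variant_of <- function(tokens, which) {
      switch(which,
             reorder = if (length(tokens) > 1L) {
               perm <- sample(length(tokens))
               if (all(perm == seq_along(tokens))) perm <- rev(perm)
               tokens[perm]
             } else c(tokens, sample(context_pool, 1L)),
             suffix = {
               i <- sample(seq_along(tokens), 1L)
               tokens[i] <- paste0(tokens[i], sample(c("ic", "al", "osis"), 1L))
               tokens
             })
    }

    a_idx <- 0L
    for (p in seq_len(n_pairs)) {
      a_idx <- a_idx + 1L
      base <- base_phrase(anchors[a_idx])
      clusters <- default_qualifier_clusters()
      q1 <- clusters[[1L]][1L]; q2 <- clusters[[2L]][1L]
      type <- sample(disorder_types, 1L)
      add_row(next_cid(), type, paste(c(q1, base), collapse = " "))
      add_row(next_cid(), type, paste(c(q2, base), collapse = " "))
    }
    for (i in seq_len(n_plain)) {
      a_idx <- a_idx + 1L
      cid <- next_cid()
      type <- sample(disorder_types, 1L)
      base <- base_phrase(anchors[a_idx])
      add_row(cid, type, paste(base, collapse = " "))
      if (synonyms_per_concept > 1L) {
        for (s in seq_len(synonyms_per_concept - 1L)) {
          kind <- if (s %% 2L == 1L) "reorder" else "suffix"
          add_row(cid, type, paste(variant_of(base, kind), collapse = " "))
        }
      }
    }
    new_lexicon(rows_cid, rows_type, rows_syn, provenance = "synthetic")
  })
}

#' Perturbation specifications
#'
#' Describes how to turn a clean synonym string into a realistic mention.
#' The available operations emulate the variation classes a phenotype
#' normaliser must absorb: `token_reorder` (different word ordering),
#' `character_edits` (typos and morphological slips, at most `k` character
#' edits so the Levenshtein distance to the original is bounded by `k`),
#' `orthographic_join` (run-together spellings such as `diabetesmellitus`),
#' `qualifier_substitute` (swapping a qualifier for a semantic variant from
#' the same cluster, e.g. `increased` -> `elevated`), and
#' `morphological_suffix` (suffix alternation, e.g. a trailing `y` -> `i`).
#'
#' @param operations character vector, a subset of the operations above.
#' @param k maximum character edits for `character_edits` (default 2).
#' @param seed integer seed; the same spec and seed give the same output.
#' @param qualifier_pool list of word clusters for `qualifier_substitute`;
#'   defaults to the clusters of the bundled synonym resource.
#' @return A list of class `pheno_perturbation_spec`.
#' @export
perturbation_spec <- function(operations, k = 2L, seed = 1L,
                              qualifier_pool = default_qualifier_clusters()) {
  known <- c("token_reorder", "character_edits", "orthographic_join",
             "qualifier_substitute", "morphological_suffix")
  operations <- match.arg(operations, known, several.ok = TRUE)
  stopifnot(k >= 0L)
  structure(list(operations = operations, k = as.integer(k),
                 seed = as.integer(seed), qualifier_pool = qualifier_pool),
            class = "pheno_perturbation_spec")
}

apply_character_edits <- function(s, k) {
  n_edits <- if (k == 0L) 0L else sample(seq_len(k), 1L)
  edits_done <- 0L
  for (e in seq_len(n_edits)) {
    chars <- strsplit(s, "")[[1]]
    pos <- which(chars != " ")
    if (length(pos) <= 1L) break
    i <- sample(pos, 1L)
    op <- sample(c("sub", "ins", "del"), 1L)
    letter <- sample(letters, 1L)
    chars <- switch(op,
                    sub = { chars[i] <- letter; chars },
                    ins = append(chars, letter, after = i),
                    del = chars[-i])
    s <- paste(chars, collapse = "")
    edits_done <- edits_done + 1L
  }
  attr(s, "n_edits") <- edits_done
  s
}

#' Perturb a synonym string into a mention
#'
#' Samples, under the spec's seed, which of the spec's operations to apply to
#' this string (each independently with probability 1/2, so a benchmark mixes
#' clean and perturbed mentions the way a real corpus mixes exact and variant
#' phrasings), then applies the sampled operations in a fixed order
#' (qualifier substitution, token reorder, morphological suffix, orthographic
#' join, character edits). The returned string carries attributes `applied`
#' (the operations that actually changed something) and `n_edits` (character
#' edits performed, always `<= k`).
#'
#' @param synonym_string the clean synonym string.
#' @param spec a [perturbation_spec()].
#' @return A perturbed mention string.
#' @export
perturb_synonym <- function(synonym_string, spec) {
  stopifnot(inherits(spec, "pheno_perturbation_spec"))
  with_seed(spec$seed, {
    s <- synonym_string
    applied <- character(0)
    ops <- spec$operations[stats::runif(length(spec$operations)) < 0.5]

    if ("qualifier_substitute" %in% ops) {
      toks <- strsplit(s, " +")[[1]]
      for (i in seq_along(toks)) {
        cluster <- Find(function(cl) tolower(toks[i]) %in% cl,
                        spec$qualifier_pool)
        if (!is.null(cluster)) {
          others <- setdiff(cluster, tolower(toks[i]))
          if (length(others) > 0L) {
            toks[i] <- sample(others, 1L)
            applied <- c(applied, "qualifier_substitute")
            break
          }
        }
      }
      s <- paste(toks, collapse = " ")
    }
    if ("token_reorder" %in% ops) {
      toks <- strsplit(s, " +")[[1]]
      if (length(toks) > 1L) {
        perm <- sample(length(toks))
        if (all(perm == seq_along(toks))) perm <- rev(perm)
        s <- paste(toks[perm], collapse = " ")
        applied <- c(applied, "token_reorder")
      }
    }
    if ("morphological_suffix" %in% ops) {
      toks <- strsplit(s, " +")[[1]]
      i <- sample(seq_along(toks), 1L)
      toks[i] <- if (grepl("y$", toks[i])) sub("y$", "i", toks[i])
                 else paste0(toks[i], "i")
      s <- paste(toks, collapse = " ")
      applied <- c(applied, "morphological_suffix")
    }
    if ("orthographic_join" %in% ops) {
      toks <- strsplit(s, " +")[[1]]
      if (length(toks) > 1L) {
        i <- sample(seq_len(length(toks) - 1L), 1L)
        toks <- append(toks[-c(i, i + 1L)], paste0(toks[i], toks[i + 1L]),
                       after = i - 1L)
        s <- paste(toks, collapse = " ")
        applied <- c(applied, "orthographic_join")
      }
    }
    n_edits <- 0L
    if ("character_edits" %in% ops) {
      s <- apply_character_edits(s, spec$k)
      n_edits <- attr(s, "n_edits")
      if (n_edits > 0L) applied <- c(applied, "character_edits")
      s <- as.character(s)
    }
    structure(s, applied = applied, n_edits = n_edits)
  })
}

#' Generate a synthetic normalisation benchmark
#'
#' Samples synonyms from a lexicon, perturbs each with the given spec (every
#' mention gets its own seed derived from `spec$seed`), and returns a
#' standoff mention table carrying the owning concept as gold. Categories are
#' assigned round-robin over the four phenotype categories so per-category
#' reports are exercised.
#'
#' @param lexicon a non-empty `pheno_lexicon`.
#' @param spec a [perturbation_spec()].
#' @param n_mentions number of mentions to emit (0 gives an empty table).
#' @return A data frame in [read_mentions()] layout with gold concept ids.
#' @export
generate_benchmark <- function(lexicon, spec, n_mentions) {
  stopifnot(inherits(lexicon, "pheno_lexicon"), n_mentions >= 0L)
  cats <- c("Cause", "Risk factor", "Sign or symptom",
            "Non-traditional risk factor")
  if (n_mentions == 0L) {
    return(data.frame(mention_id = character(0), doc_id = character(0),
                      start = integer(0), end = integer(0),
                      text = character(0), category = character(0),
                      gold_concept_id = character(0), stringsAsFactors = FALSE))
  }
  usable <- which(lexicon$synonyms$usable)
  picks <- with_seed(spec$seed,
                     sample(usable, n_mentions, replace = TRUE))
  texts <- vapply(seq_len(n_mentions), function(i) {
    sp <- spec
    sp$seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    as.character(perturb_synonym(lexicon$synonyms$norm_text[picks[i]], sp))
  }, character(1))
  data.frame(
    mention_id = sprintf("m%04d", seq_len(n_mentions)),
    doc_id = "synthetic",
    start = 0L,
    end = nchar(texts),
    text = texts,
    category = cats[(seq_len(n_mentions) - 1L) %% length(cats) + 1L],
    gold_concept_id = lexicon$synonyms$concept_id[picks],
    stringsAsFactors = FALSE
  )
}
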