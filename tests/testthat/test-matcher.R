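# small lexicons for retrieval behaviour, built in code
jvp_lexicon <- function() {
  new_lexicon(
    c("C1", "C2", "C3", "C4"), rep("T033", 4),
    c("raised jugular venous pressure", "jugular venous pressure",
      "venous thrombosis", "blood pressure"))
}

test_that("levenshtein matches a dynamic-programming oracle and metric axioms", {
  expect_equal(levenshtein("abc", "abc"), 0L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  expect_equal(levenshtein("", "chest"), 5L)
  expect_equal(levenshtein("chest", ""), 5L)

  withr::with_seed(42, {
    a <- random_strings(200)
    b <- random_strings(200)
    c_ <- random_strings(200)
    dab <- levenshtein(a, b)
    for (i in seq_along(a)) {
      expect_equal(dab[i], lev_dp(a[i], b[i]))
    }
    expect_equal(dab, levenshtein(b, a))                       # symmetry
    expect_true(all(levenshtein(a, c_) <= dab + levenshtein(b, c_)))
    expect_true(all(dab >= abs(nchar(a) - nchar(b))))          # lower bound
  })
})

test_that("combined score adds weighted length difference to edit distance", {
  cfg <- matcher_config()
  s0 <- score("chest pain", "chest pain", cfg)
  expect_equal(s0$combined, 0)
  s1 <- score("kitten", "sitting", cfg)
  expect_equal(s1$edit_distance, 3L)
  expect_equal(s1$length_difference, 1L)
  expect_equal(s1$combined, 4)
  # zero combined score only for identical strings
  expect_gt(score("kitten", "kittens", cfg)$combined, 0)
  # the length term is what makes 'chronic leg ulcer' beat 'leg edema'
  worse <- score("chronic leg edema", "leg edema", cfg)$combined
  better <- score("chronic leg edema", "chronic leg ulcer", cfg)$combined
  expect_lt(better, worse)
})

test_that("retrieval keeps only the highest shared-token level, pooled over variants", {
  lex <- jvp_lexicon()
  idx <- build_inverted_index(lex)
  res <- example_synonym_resource()
  cfg <- matcher_config()

  vs <- generate_variants(normalize_tokens("elevated jugular venous pressure"),
                          res)
  cand <- retrieve_candidates(vs, idx, lex, cfg)
  # the variant elevated->raised shares all four tokens with the qualified
  # synonym, so the more general three-token match is dropped
  expect_equal(lex$synonyms$raw_text[cand$synonym_id],
               "raised jugular venous pressure")
  expect_equal(cand$shared_token_count, 4L)

  # candidates may be supersets of the mention tokens: both the qualified and
  # the bare synonym survive at the two-shared-token level
  bp_lex <- new_lexicon(c("C1", "C2"), c("T047", "T033"),
                        c("high blood pressure", "blood pressure"))
  bp_idx <- build_inverted_index(bp_lex)
  vs2 <- generate_variants(normalize_tokens("heightened blood pressure"), NULL)
  cand2 <- retrieve_candidates(vs2, bp_idx, bp_lex, cfg)
  expect_setequal(lex_syn <- bp_lex$synonyms$raw_text[cand2$synonym_id],
                  c("high blood pressure", "blood pressure"))
  expect_equal(cand2$shared_token_count, c(2L, 2L))

  # no token overlap at all -> empty, triggering the fallback
  vs3 <- generate_variants(c("qqq", "zzz"), NULL)
  expect_equal(nrow(retrieve_candidates(vs3, idx, lex, cfg)), 0L)
})

test_that("n-gram fallback retrieves run-together mentions via rare grams", {
  lex <- example_lexicon()
  idx <- build_indexes(lex)
  cfg <- matcher_config()
  cand <- ngram_fallback_candidates("diabetesmellitus", idx$ngram, lex, cfg)
  expect_true("diabetes mellitus" %in% lex$synonyms$raw_text[cand$synonym_id])
  expect_true(all(cand$source == "ngram-fallback"))

  expect_equal(nrow(ngram_fallback_candidates("qwqwqwqw", idx$ngram, lex, cfg)),
               0L)

  # a 4-character token falls back to 3-grams
  mell <- ngram_fallback_candidates("mell", idx$ngram, lex, cfg)
  expect_true(any(grepl("mellitus",
                        lex$synonyms$raw_text[mell$synonym_id])))
})

test_that("exact matches dominate regardless of other lexicon content", {
  lex <- new_lexicon(
    c("C1", "C2", "C3"), rep("T047", 3),
    c("chest pain", "chest pain severe", "chest pains"))
  idx <- build_indexes(lex)
  res <- normalize_mention("Chest Pain", lex, idx)
  expect_equal(res$mappings$concept_id, "C1")
  expect_equal(res$mappings$score, 0)
  expect_equal(res$mappings$source, "exact")
})

test_that("a token permutation of a synonym reaches the all-shared level and maps to it", {
  withr::with_seed(9, {
    lex <- generate_lexicon(40L, 1L, seed = 9)
    idx <- build_indexes(lex)
    multi <- which(lengths(lex$tokens) > 1L & lex$synonyms$usable)
    for (i in sample(multi, 10L)) {
      toks <- lex$tokens[[i]]
      perm <- paste(sample(toks), collapse = " ")
      got <- normalize_mention(perm, lex, idx)
      expect_equal(got$mappings$concept_id, lex$synonyms$concept_id[i])
    }
  })
})

test_that("mentions with no candidates anywhere are flagged unmapped", {
  lex <- jvp_lexicon()
  idx <- build_indexes(lex)
  res <- normalize_mention("qqqq wwww", lex, idx)
  expect_true(res$unmapped)
  expect_true(is.na(res$mappings$concept_id))

  stopish <- normalize_mention("the is was", lex, idx)
  expect_true(stopish$unmapped)
})

test_that("the chosen synonym equals the brute-force argmin over shared-token candidates", {
  res <- example_synonym_resource()
  n_checked <- 0L
  for (sd in 1:5) {
    lex <- generate_lexicon(50L, 2L, seed = sd)
    idx <- build_indexes(lex)
    spec <- perturbation_spec(
      c("character_edits", "token_reorder", "qualifier_substitute"),
      k = 2L, seed = sd)
    bench <- generate_benchmark(lex, spec, 5L)
    for (i in seq_len(nrow(bench))) {
      oracle <- brute_force_normalize(bench$text[i], lex, res)
      if (is.null(oracle)) next
      got <- normalize_mention(bench$text[i], lex, idx, res)
      expect_equal(got$mappings$synonym_id, oracle$synonym_id,
                   info = bench$text[i])
      expect_equal(got$mappings$score, oracle$combined, info = bench$text[i])
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 20L)
})

test_that("exact-match baseline maps only string-identical mentions", {
  lex <- jvp_lexicon()
  idx <- build_indexes(lex)
  expect_equal(baseline_exact("jugular venous pressure", lex, idx)$
                 mappings$concept_id, "C2")
  # case and punctuation differences still match after normalisation
  expect_equal(baseline_exact("Jugular Venous Pressure.", lex, idx)$
                 mappings$concept_id, "C2")
  expect_true(baseline_exact("elevated jugular venous pressure", lex, idx)$
                unmapped)
})

test_that("SoftTFIDF similarity equals a hand-computed weighted sum", {
  lex <- new_lexicon(c("CA", "CB", "CC"), rep("T047", 3),
                     c("alpha beta", "alpha gamma", "delta"))
  model <- soft_tfidf_model(lex)

  # identical strings score exactly 1
  hit <- baseline_soft_tfidf("alpha beta", lex, model)
  expect_equal(hit$mappings$concept_id, "CA")
  expect_equal(hit$mappings$score, 1, tolerance = 1e-12)

  # hand computation for the partial match 'alpha beta' vs 'alpha gamma':
  # idf(alpha) = log(3/2), idf(beta) = idf(gamma) = log(3); tf terms are 1;
  # both strings have L2 norm sqrt(log(1.5)^2 + log(3)^2); only 'alpha'
  # pairs, so sim = (log(1.5) / norm)^2
  w <- log(1.5); nrm2 <- log(1.5)^2 + log(3)^2
  sims <- phenonorm:::soft_tfidf_similarity(c("alpha", "beta"), model)
  expect_equal(sims[model$norm_text == "alpha gamma"], w^2 / nrm2,
               tolerance = 1e-12)
  expect_equal(sims[model$norm_text == "delta"], 0)
})

test_that("SoftTFIDF misses the qualified concept that the main matcher finds", {
  lex <- example_lexicon()
  idx <- build_indexes(lex)
  mention <- "moderately reduced left ventricular systolic function"
  soft <- baseline_soft_tfidf(mention, lex)
  expect_equal(soft$mappings$synonym,
               "moderate left ventricular systolic dysfunction")
  main <- normalize_mention(mention, lex, idx, example_synonym_resource())
  expect_equal(
    main$mappings$synonym,
    "moderately or severely depressed left ventricular systolic function")
})
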