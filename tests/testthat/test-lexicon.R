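test_that("TSV lexicon loading counts, deduplicates, and errors on degenerate input", {
  path <- write_tmp_tsv(c(
    "concept_id\tsemantic_type\tsynonym",
    "C1\tT047\theart failure",
    "C1\tT047\tcardiac failure",
    "C2\tT184\tchest pain",
    "C2\tT184\tchest discomfort"
  ))
  lex <- load_tsv_lexicon(path)
  expect_s3_class(lex, "pheno_lexicon")
  expect_equal(nrow(lex$concepts), 2L)
  expect_equal(nrow(lex$synonyms), 4L)

  # duplicate (concept, string) pair is dropped, case-insensitively
  dup <- write_tmp_tsv(c("C1\tT047\theart failure",
                         "C1\tT047\tHeart Failure"))
  expect_equal(nrow(load_tsv_lexicon(dup)$synonyms), 1L)

  header_only <- write_tmp_tsv("concept_id\tsemantic_type\tsynonym")
  expect_error(load_tsv_lexicon(header_only), "no data rows")

  malformed <- write_tmp_tsv(c("C1\tT047\theart failure", "bad row"))
  expect_warning(lex2 <- load_tsv_lexicon(malformed), "malformed")
  expect_equal(nrow(lex2$synonyms), 1L)
})

test_that("TSV write -> load round-trips lexicon content deterministically", {
  lex <- generate_lexicon(10L, synonyms_per_concept = 2L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_lexicon(lex, path)
  back <- load_tsv_lexicon(path)
  expect_equal(back$concepts, lex$concepts)
  expect_equal(back$synonyms, lex$synonyms)
  expect_equal(back$tokens, lex$tokens)
  # loading the same file twice yields identical lexicons
  expect_identical(back, load_tsv_lexicon(path))
})

test_that("RRF loading parses MRCONSO/MRSTY, attaches types, skips bad rows", {
  mrconso <- write_tmp_tsv(c(
    "C0001|ENG|P|L1|PF|S1|Y|A1||||SRC|PT|1|heart failure|0|N|",
    "C0001|ENG|S|L2|VO|S2|N|A2||||SRC|SY|1|cardiac failure|0|N|",
    "C0002|ENG|P|L3|PF|S3|Y|A3||||SRC|PT|2|chest pain|0|N|",
    "C0003|FRE|P|L4|PF|S4|Y|A4||||SRC|PT|3|douleur thoracique|0|N|",
    "garbled row without pipes"
  ))
  mrsty <- write_tmp_tsv(c(
    "C0001|T047|B1.2|Disease or Syndrome|AT1||",
    "C0002|T184|B1.3|Sign or Symptom|AT2||"
  ))
  expect_warning(lex <- load_rrf_lexicon(mrconso, mrsty), "malformed")
  # two English concepts, three synonyms; the French row is filtered out
  expect_equal(nrow(lex$concepts), 2L)
  expect_equal(nrow(lex$synonyms), 3L)
  expect_equal(lex$concepts$semantic_types[lex$concepts$concept_id == "C0001"],
               "T047")
  expect_equal(lex$provenance, "RRF")

  empty <- write_tmp_tsv(character(0))
  expect_error(load_rrf_lexicon(empty, mrsty), "empty")
})

test_that("semantic-group filtering keeps exactly the member concepts", {
  lex <- new_lexicon(
    concept_id = c("C1", "C2", "C3", "C4", "C5"),
    semantic_type = c("T047", "T184", "T121", "T121", "T047|T121"),
    synonym = c("ulax vebo", "wyx pain", "drugone", "drugtwo", "mixed thing"))
  grp <- semantic_group("Disorders-ish", c("T047", "T184"))
  kept <- filter_by_semantic_group(lex, grp)
  expect_setequal(kept$concepts$concept_id, c("C1", "C2", "C5"))
  # complement partitions the concept set
  comp <- filter_by_semantic_group(lex, semantic_group("rest", "T121"))
  expect_setequal(union(kept$concepts$concept_id,
                        comp$concepts$concept_id),
                  lex$concepts$concept_id)
  # identity and empty filters
  all_types <- semantic_group("all", c("T047", "T184", "T121"))
  expect_equal(filter_by_semantic_group(lex, all_types)$concepts,
               lex$concepts)
  none <- filter_by_semantic_group(lex, semantic_group("none", "T999"))
  expect_equal(nrow(none$concepts), 0L)
  expect_equal(nrow(none$synonyms), 0L)
  # original untouched
  expect_equal(nrow(lex$concepts), 5L)
})

test_that("inverted index equals a brute-force scan over all synonyms", {
  lex <- new_lexicon(c("C1", "C2"), c("T047", "T047"),
                     c("chest pain", "chest wall"))
  idx <- build_inverted_index(lex)
  expect_setequal(idx[["chest"]], lex$synonyms$synonym_id)
  expect_equal(idx[["pain"]],
               lex$synonyms$synonym_id[lex$synonyms$raw_text == "chest pain"])

  # property: postings match a scan, on random lexicons
  for (sd in 1:3) {
    rl <- generate_lexicon(40L, 2L, seed = sd)
    ridx <- build_inverted_index(rl)
    vocab <- unique(unlist(rl$tokens))
    for (tok in vocab) {
      scan <- rl$synonyms$synonym_id[vapply(rl$tokens, function(t) tok %in% t,
                                            logical(1)) & rl$synonyms$usable]
      expect_equal(ridx[[tok]], sort(scan))
    }
    expect_setequal(names(ridx), vocab)
  }

  # a lexicon filtered down to nothing has empty postings
  empty <- filter_by_semantic_group(lex, semantic_group("none", "T999"))
  expect_length(unclass(build_inverted_index(empty)), 0L)
})

test_that("all-stop-word synonyms are flagged unusable and never indexed", {
  lex <- new_lexicon(c("C1", "C1"), c("T047", "T047"),
                     c("the was", "heart failure"))
  expect_false(lex$synonyms$usable[lex$synonyms$raw_text == "the was"])
  idx <- build_inverted_index(lex)
  unusable_id <- lex$synonyms$synonym_id[!lex$synonyms$usable]
  expect_false(any(unusable_id %in% unlist(unclass(idx))))
})

test_that("n-gram index covers token and run-together grams with exact counts", {
  lex <- new_lexicon(c("C1", "C2"), c("T047", "T047"),
                     c("diabetes mellitus", "diabetes insipidus"))
  ngx <- build_ngram_index(lex, gram_sizes = c(3L, 5L))
  expect_true("diabe" %in% names(ngx$postings))
  expect_equal(ngx$gram_freq[["diabe"]], 2L)
  # grams spanning the stripped multi-token string are indexed too
  expect_true("tesme" %in% names(ngx$postings))

  # gram_freq always equals posting size, on a random lexicon
  rl <- generate_lexicon(30L, 2L, seed = 5L)
  rgx <- build_ngram_index(rl)
  expect_equal(unname(rgx$gram_freq), lengths(unname(rgx$postings)))

  empty <- filter_by_semantic_group(lex, semantic_group("none", "T999"))
  expect_length(build_ngram_index(empty)$postings, 0L)
})

test_that("rarest_ngram picks the least frequent seen gram, leftmost on ties", {
  lex <- new_lexicon(
    c("C1", "C2", "C3"), rep("T047", 3),
    c("diabetes mellitus", "diabetes insipidus", "gestational diabetes mellitus"))
  ngx <- build_ngram_index(lex)
  cfg <- matcher_config()
  tok <- "diabetesmellitus"
  # independent expectation: enumerate the token's 5-grams and recount
  grams <- substring(tok, 1:(nchar(tok) - 4L), 5:nchar(tok))
  freq <- vapply(grams, function(g)
    sum(vapply(seq_len(nrow(lex$synonyms)), function(i) {
      joined <- gsub(" ", "", lex$synonyms$norm_text[i])
      grepl(g, joined, fixed = TRUE) ||
        any(grepl(g, lex$tokens[[i]], fixed = TRUE))
    }, logical(1))), integer(1))
  seen <- freq > 0
  expected <- grams[seen][which.min(freq[seen])]
  expect_equal(rarest_ngram(tok, ngx, cfg), expected)

  # tokens shorter than the threshold use the short gram size
  expect_equal(nchar(rarest_ngram("mell", ngx, cfg)), 3L)
  # tokens shorter than the gram size are used whole
  short_lex <- new_lexicon("C1", "T047", "ab cd")
  short_ngx <- build_ngram_index(short_lex)
  expect_equal(rarest_ngram("ab", short_ngx, cfg), "ab")
  # nothing indexed for the token -> NA
  expect_true(is.na(rarest_ngram("qqqqqq", short_ngx, cfg)))
})
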