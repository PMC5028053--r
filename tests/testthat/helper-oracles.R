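# Independent oracles used to compute expected values.

# plain dynamic-programming Levenshtein distance, written independently of
# the package's implementation
lev_dp <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    cur[1L] <- i
    for (j in seq_len(nb)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[nb + 1L]
}

# brute-force reference for normalize_mention on a single (unsplit) phrase:
# scans every synonym, no index. Mirrors the published selection rule:
# exact match on any variant wins with score 0; otherwise candidates are the
# synonyms sharing the maximum number of tokens with any variant, scored by
# DP edit distance plus weighted length difference, minimised over variants.
brute_force_normalize <- function(text, lexicon, resource = NULL,
                                  length_weight = 1, cap = 256L) {
  tokens <- normalize_tokens(text, lexicon$stop_words)
  if (length(tokens) == 0L) return(NULL)
  vs <- generate_variants(tokens, resource, cap = cap)
  vstr <- vapply(vs$variants, paste, character(1), collapse = " ")
  syn <- lexicon$synonyms
  usable <- which(syn$usable)

  for (v in vstr) {
    hits <- usable[syn$norm_text[usable] == v]
    if (length(hits) > 0L) {
      pick <- hits[order(syn$concept_id[hits], syn$synonym_id[hits])][1L]
      return(list(synonym_id = syn$synonym_id[pick],
                  concept_id = syn$concept_id[pick], combined = 0))
    }
  }

  shared <- vapply(usable, function(i) {
    stoks <- unique(lexicon$tokens[[i]])
    max(vapply(vs$variants, function(vt) length(intersect(unique(vt), stoks)),
               integer(1)))
  }, integer(1))
  k_star <- max(shared)
  if (k_star < 1L) return(NULL)
  cand <- usable[shared == k_star]
  combined <- vapply(cand, function(i) {
    min(vapply(vstr, function(v) {
      lev_dp(v, syn$norm_text[i]) +
        length_weight * abs(nchar(v) - nchar(syn$norm_text[i]))
    }, numeric(1)))
  }, numeric(1))
  ord <- order(combined, syn$char_length[cand], syn$concept_id[cand],
               syn$synonym_id[cand])
  pick <- cand[ord[1L]]
  list(synonym_id = syn$synonym_id[pick], concept_id = syn$concept_id[pick],
       combined = combined[ord[1L]])
}

# random letter strings for metric property tests
random_strings <- function(n, max_len = 12L) {
  vapply(seq_len(n), function(i) {
    len <- sample(0:max_len, 1L)
    paste(sample(letters[1:6], len, replace = TRUE), collapse = "")
  }, character(1))
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
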