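#' Lexicon objects
#'
#' A `pheno_lexicon` holds the target side of normalisation: concepts
#' (identified by an opaque id such as a CUI), their semantic types, and the
#' synonym strings listed for each concept. Synonym strings are stored both as
#' given in the source and in a normalised form (lower-cased, punctuation
#' stripped, stop words removed, whitespace-tokenised), since all matching
#' operates on the normalised side.
#'
#' @param concept_id character vector, one entry per synonym row.
#' @param semantic_type character vector parallel to `concept_id`; multiple
#'   types for one concept may be given on separate rows or joined with `|`.
#' @param synonym character vector of synonym strings parallel to `concept_id`.
#' @param stop_words character vector of stop words used when normalising
#'   synonym strings; defaults to the bundled clinical-safe list.
#' @param provenance one of `"RRF"`, `"TSV"`, `"synthetic"`.
#'
#' @return An object of class `pheno_lexicon`: a list with elements
#'   `concepts` (data frame: `concept_id`, `preferred_name`, `semantic_types`),
#'   `synonyms` (data frame: `synonym_id`, `concept_id`, `raw_text`,
#'   `norm_text`, `char_length`, `usable`), `tokens` (list of token vectors
#'   parallel to `synonyms`), `stop_words`, and `provenance`.
#'   Duplicate (concept, string) pairs are removed, comparing case-folded
#'   strings. A synonym whose tokens are all stop words is kept but flagged
#'   `usable = FALSE` and never indexed.
#' @export
new_lexicon <- function(concept_id, semantic_type, synonym,
                        stop_words = default_stop_words(),
                        provenance = "TSV") {
  stopifnot(length(concept_id) == length(synonym),
            length(semantic_type) == length(synonym))
  if (length(synonym) == 0L) stop("lexicon has no rows")
  concept_id <- as.character(concept_id)
  semantic_type <- as.character(semantic_type)
  synonym <- as.character(synonym)

  keep <- nzchar(trimws(synonym)) & nzchar(trimws(concept_id))
  concept_id <- concept_id[keep]
  semantic_type <- semantic_type[keep]
  synonym <- synonym[keep]
  if (length(synonym) == 0L) stop("lexicon has no usable rows")

  # semantic types per concept, aggregated before synonym dedup
  type_rows <- unlist(strsplit(semantic_type, "|", fixed = TRUE))
  type_cid <- rep(concept_id, lengths(strsplit(semantic_type, "|", fixed = TRUE)))
  types_by_concept <- vapply(
    split(type_rows, type_cid),
    function(x) paste(sort(unique(x[nzchar(x)])), collapse = "|"),
    character(1)
  )

  dup <- duplicated(paste0(concept_id, "\r", tolower(synonym)))
  concept_id <- concept_id[!dup]
  synonym <- synonym[!dup]

  # stable order: concept then synonym string
  ord <- order(concept_id, tolower(synonym), method = "radix")
  concept_id <- concept_id[ord]
  synonym <- synonym[ord]

  tokens <- lapply(synonym, normalize_tokens, stop_words = stop_words)
  norm_text <- vapply(tokens, paste, character(1), collapse = " ")
  usable <- lengths(tokens) > 0L

  cids <- unique(concept_id)
  concepts <- data.frame(
    concept_id = cids,
    preferred_name = synonym[match(cids, concept_id)],
    semantic_types = unname(types_by_concept[cids]),
    stringsAsFactors = FALSE
  )
  concepts$semantic_types[is.na(concepts$semantic_types)] <- ""

  synonyms <- data.frame(
    synonym_id = seq_along(synonym),
    concept_id = concept_id,
    raw_text = synonym,
    norm_text = norm_text,
    char_length = nchar(norm_text),
    usable = usable,
    stringsAsFactors = FALSE
  )

  structure(
    list(concepts = concepts, synonyms = synonyms, tokens = tokens,
         stop_words = stop_words, provenance = provenance),
    class = "pheno_lexicon"
  )
}

#' @export
print.pheno_lexicon <- function(x, ...) {
  cat(sprintf("<pheno_lexicon> %d concepts, %d synonyms (%d usable), source: %s\n",
              nrow(x$concepts), nrow(x$synonyms), sum(x$synonyms$usable),
              x$provenance))
  invisible(x)
}

#' Read a lexicon from UMLS Metathesaurus RRF files
#'
#' Parses `MRCONSO.RRF` (concept strings) and `MRSTY.RRF` (semantic types) in
#' the standard pipe-delimited column layout, tolerating a trailing pipe.
#' Rows are filtered to one language and, by default, to non-suppressed
#' entries. Malformed rows are skipped with a single warning giving the count.
#'
#' @param concept_file_path path to `MRCONSO.RRF`.
#' @param type_file_path path to `MRSTY.RRF`.
#' @param language keep rows with this `LAT` value (default `"ENG"`).
#' @param keep_suppressed keep rows whose `SUPPRESS` flag is not `"N"`?
#' @param stop_words stop words used to normalise synonym strings.
#' @return A [new_lexicon()] object with provenance `"RRF"`.
#' @export
load_rrf_lexicon <- function(concept_file_path, type_file_path,
                             language = "ENG", keep_suppressed = FALSE,
                             stop_words = default_stop_words()) {
  if (!file.exists(concept_file_path)) stop("no such file: ", concept_file_path)
  if (!file.exists(type_file_path)) stop("no such file: ", type_file_path)

  con_lines <- readLines(concept_file_path, warn = FALSE, encoding = "UTF-8")
  con_lines <- con_lines[nzchar(con_lines)]
  if (length(con_lines) == 0L) stop("empty MRCONSO file: ", concept_file_path)
  fields <- strsplit(con_lines, "|", fixed = TRUE)
  # MRCONSO: CUI|LAT|TS|LUI|STT|SUI|ISPREF|AUI|SAUI|SCUI|SDUI|SAB|TTY|CODE|STR|SRL|SUPPRESS|CVF
  ok <- lengths(fields) >= 15L
  if (any(!ok)) {
    warning(sum(!ok), " malformed MRCONSO row(s) skipped")
    fields <- fields[ok]
  }
  if (length(fields) == 0L) stop("no usable MRCONSO rows")
  cui <- vapply(fields, `[[`, character(1), 1L)
  lat <- vapply(fields, `[[`, character(1), 2L)
  str <- vapply(fields, `[[`, character(1), 15L)
  sup <- vapply(fields, function(f) if (length(f) >= 17L) f[[17L]] else "N",
                character(1))
  keep <- lat == language & nzchar(str)
  if (!keep_suppressed) keep <- keep & (sup %in% c("N", ""))
  if (!any(keep)) stop("no usable MRCONSO rows after filtering")
  cui <- cui[keep]; str <- str[keep]

  sty_lines <- readLines(type_file_path, warn = FALSE, encoding = "UTF-8")
  sty_lines <- sty_lines[nzchar(sty_lines)]
  sty_fields <- strsplit(sty_lines, "|", fixed = TRUE)
  sty_ok <- lengths(sty_fields) >= 2L
  if (any(!sty_ok)) {
    warning(sum(!sty_ok), " malformed MRSTY row(s) skipped")
    sty_fields <- sty_fields[sty_ok]
  }
  sty_cui <- vapply(sty_fields, `[[`, character(1), 1L)
  sty_tui <- vapply(sty_fields, `[[`, character(1), 2L)
  tui_by_cui <- vapply(split(sty_tui, sty_cui),
                       function(x) paste(sort(unique(x)), collapse = "|"),
                       character(1))
  semantic_type <- unname(tui_by_cui[cui])
  semantic_type[is.na(semantic_type)] <- ""

  new_lexicon(cui, semantic_type, str, stop_words = stop_words,
              provenance = "RRF")
}

#' Read and write the plain TSV lexicon interchange format
#'
#' The TSV format is `concept_id<TAB>semantic_type<TAB>synonym`, UTF-8, one
#' synonym per row; a header row with those column names is accepted and
#' skipped. Rows with the wrong column count are skipped with a warning.
#' The writer emits one row per (synonym, semantic type), sorted by
#' concept id then synonym, so that write -> load round-trips.
#'
#' @param path file path.
#' @param stop_words stop words used to normalise synonym strings.
#' @return `load_tsv_lexicon()` returns a [new_lexicon()] object;
#'   `write_tsv_lexicon()` returns `path` invisibly.
#' @export
load_tsv_lexicon <- function(path, stop_words = default_stop_words()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L &&
      identical(tolower(lines[1L]), "concept_id\tsemantic_type\tsynonym")) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) stop("lexicon file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 3L
  if (any(!ok)) warning(sum(!ok), " malformed lexicon row(s) skipped")
  fields <- fields[ok]
  if (length(fields) == 0L) stop("no usable lexicon rows in ", path)
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  new_lexicon(m[, 1L], m[, 2L], m[, 3L], stop_words = stop_words,
              provenance = "TSV")
}

#' @param lexicon a `pheno_lexicon`.
#' @rdname load_tsv_lexicon
#' @export
write_tsv_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "pheno_lexicon"))
  syn <- lexicon$synonyms
  types <- lexicon$concepts$semantic_types[
    match(syn$concept_id, lexicon$concepts$concept_id)]
  type_list <- strsplit(ifelse(nzchar(types), types, ""), "|", fixed = TRUE)
  type_list[lengths(type_list) == 0L] <- list("")
  n_rep <- lengths(type_list)
  rows <- data.frame(
    concept_id = rep(syn$concept_id, n_rep),
    semantic_type = unlist(type_list),
    synonym = rep(syn$raw_text, n_rep),
    stringsAsFactors = FALSE
  )
  rows <- rows[order(rows$concept_id, tolower(rows$synonym), rows$semantic_type,
                     method = "radix"), ]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("concept_id\tsemantic_type\tsynonym",
               paste(rows$concept_id, rows$semantic_type, rows$synonym,
                     sep = "\t")),
             con, useBytes = TRUE)
  invisible(path)
}

#' Semantic group specifications
#'
#' A semantic group names a set of semantic-type identifiers; filtering a
#' lexicon to a group keeps exactly the concepts carrying at least one member
#' type. `disorder_group()` ships the conventional Disorders-group inventory
#' (the UMLS semantic group subsuming diseases, dysfunctions, findings, signs
#' and symptoms); the member set is fully overrideable because different tools
#' draw this boundary differently, e.g. some exclude the Finding type.
#'
#' @param group_name a label for the group.
#' @param member_types non-empty character vector of semantic-type identifiers.
#' @return An object of class `pheno_semantic_group`.
#' @export
semantic_group <- function(group_name, member_types) {
  member_types <- unique(as.character(member_types))
  if (length(member_types) == 0L) stop("member_types must be non-empty")
  structure(list(group_name = group_name, member_types = member_types),
            class = "pheno_semantic_group")
}

#' @rdname semantic_group
#' @export
disorder_group <- function() {
  semantic_group("Disorders", c(
    "T019", # Congenital Abnormality
    "T020", # Acquired Abnormality
    "T033", # Finding
    "T037", # Injury or Poisoning
    "T046", # Pathologic Function
    "T047", # Disease or Syndrome
    "T048", # Mental or Behavioral Dysfunction
    "T049", # Cell or Molecular Dysfunction
    "T050", # Experimental Model of Disease
    "T184", # Sign or Symptom
    "T190", # Anatomical Abnormality
    "T191"  # Neoplastic Process
  ))
}

#' Filter a lexicon to a semantic group
#'
#' Returns a new lexicon containing exactly the concepts that carry at least
#' one semantic type in the group, together with all their synonyms. The input
#' lexicon is not modified; an empty result is legal.
#'
#' @param lexicon a `pheno_lexicon`.
#' @param group_spec a [semantic_group()].
#' @return A `pheno_lexicon`.
#' @export
filter_by_semantic_group <- function(lexicon, group_spec) {
  stopifnot(inherits(lexicon, "pheno_lexicon"),
            inherits(group_spec, "pheno_semantic_group"))
  types <- strsplit(lexicon$concepts$semantic_types, "|", fixed = TRUE)
  keep_concept <- vapply(types, function(t) any(t %in% group_spec$member_types),
                         logical(1))
  kept_ids <- lexicon$concepts$concept_id[keep_concept]
  keep_syn <- lexicon$synonyms$concept_id %in% kept_ids
  out <- lexicon
  out$concepts <- lexicon$concepts[keep_concept, , drop = FALSE]
  out$synonyms <- lexicon$synonyms[keep_syn, , drop = FALSE]
  out$tokens <- lexicon$tokens[keep_syn]
  rownames(out$concepts) <- NULL
  rownames(out$synonyms) <- NULL
  out
}

#' Build the token-level inverted index
#'
#' Maps every token occurring in a usable synonym's normalised form to the set
#' of synonym ids containing it. The index is built once over the whole
#' (filtered) lexicon vocabulary and reused across mentions. Synonyms whose
#' tokens were all stop words are absent from every posting list.
#'
#' @param lexicon a `pheno_lexicon`.
#' @return An object of class `pheno_inverted_index`: a named list of sorted
#'   integer synonym-id vectors, one per token.
#' @export
build_inverted_index <- function(lexicon) {
  stopifnot(inherits(lexicon, "pheno_lexicon"))
  use <- lexicon$synonyms$usable
  toks <- lapply(lexicon$tokens[use], unique)
  ids <- lexicon$synonyms$synonym_id[use]
  if (length(ids) == 0L) {
    postings <- list()
  } else {
    postings <- split(rep(ids, lengths(toks)), unlist(toks))
    postings <- lapply(postings, function(p) sort(unique(p)))
    postings <- postings[order(names(postings), method = "radix")]
  }
  structure(postings, class = "pheno_inverted_index")
}

# character n-grams of a string; the whole string when shorter than n
char_ngrams <- function(s, n) {
  nc <- nchar(s)
  if (nc <= n) return(s)
  substring(s, 1:(nc - n + 1L), n:nc)
}

#' Build the character n-gram index
#'
#' Indexes each usable synonym under the character n-grams of every token of
#' its normalised form, for each gram size, plus the grams of the
#' whitespace-stripped full string, so that run-together mentions (e.g.
#' `diabetesmellitus`) can reach multi-token synonyms. Tokens shorter than a
#' gram size are indexed under the whole token.
#'
#' @param lexicon a `pheno_lexicon`.
#' @param gram_sizes integer vector of gram sizes (default `c(3, 5)`).
#' @return An object of class `pheno_ngram_index`: list with `postings`
#'   (named list gram -> sorted synonym ids), `gram_freq` (named integer
#'   vector, posting-set sizes), and `gram_sizes`.
#' @export
build_ngram_index <- function(lexicon, gram_sizes = c(3L, 5L)) {
  stopifnot(inherits(lexicon, "pheno_lexicon"))
  gram_sizes <- sort(unique(as.integer(gram_sizes)))
  stopifnot(all(gram_sizes >= 1L))
  use <- which(lexicon$synonyms$usable)
  gram_lists <- lapply(use, function(i) {
    toks <- unique(lexicon$tokens[[i]])
    grams <- unlist(lapply(gram_sizes, function(n) {
      g <- unlist(lapply(toks, char_ngrams, n = n), use.names = FALSE)
      if (length(toks) > 1L) {
        g <- c(g, char_ngrams(gsub(" ", "", lexicon$synonyms$norm_text[i],
                                   fixed = TRUE), n))
      }
      g
    }), use.names = FALSE)
    unique(grams)
  })
  ids <- lexicon$synonyms$synonym_id[use]
  if (length(ids) == 0L) {
    postings <- list()
  } else {
    postings <- split(rep(ids, lengths(gram_lists)), unlist(gram_lists))
    postings <- lapply(postings, function(p) sort(unique(p)))
    postings <- postings[order(names(postings), method = "radix")]
  }
  structure(
    list(postings = postings,
         gram_freq = setNames(as.integer(lengths(postings)), names(postings)),
         gram_sizes = gram_sizes),
    class = "pheno_ngram_index"
  )
}

#' Rarest informative n-gram of a token
#'
#' Picks the gram size from the configuration (the default size, or the short
#' size when the token has fewer characters than the short-token threshold),
#' enumerates the token's grams left to right, and returns the gram with the
#' smallest positive posting frequency in the index — rare grams are the most
#' informative retrieval keys. Ties are broken by leftmost position. Grams
#' never seen in the index are ignored; if no gram of the token is indexed,
#' `NA` is returned. A token shorter than the gram size is used whole.
#'
#' @param token a non-empty token.
#' @param ngram_index a [build_ngram_index()] result.
#' @param config a [matcher_config()].
#' @return A single gram string, or `NA_character_`.
#' @export
rarest_ngram <- function(token, ngram_index, config = matcher_config()) {
  stopifnot(nzchar(token))
  size <- if (nchar(token) < config$short_token_threshold)
    config$ngram_short else config$ngram_default
  grams <- char_ngrams(token, size)
  freq <- ngram_index$gram_freq[grams]
  freq[is.na(freq)] <- 0L
  seen <- freq > 0L
  if (!any(seen)) return(NA_character_)
  grams <- grams[seen]
  grams[which.min(freq[seen])]
}
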