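#' Read a synonym resource for semantic-variant generation
#'
#' Loads a word-level synonym/similarity table in the TSV format
#' `word<TAB>class<TAB>relation<TAB>alternative`, where `class` is `noun` or
#' `adjective` and `relation` is `synonym` (same synset) or `similar` (one
#' similar-to link away). Rows with other classes or relations are skipped
#' with a warning. Multi-word alternatives are discarded: substitution is
#' word-for-word. The resulting object satisfies the lookup contract used by
#' [token_alternatives()]; any backing store honouring the same contract
#' (e.g. an adapter over a full lexical database such as WordNet) can be
#' substituted — it only needs `synonym` and `similar` named-list fields
#' mapping words to lower-cased single-word alternatives.
#'
#' @param path TSV file path; defaults to the bundled fixture resource
#'   covering common clinical qualifier words.
#' @return An object of class `pheno_synonym_resource` with named-list fields
#'   `synonym` and `similar`.
#' @export
read_synonym_resource <- function(path = pkg_extdata("synonym_resource.tsv")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 4L
  if (any(!ok)) warning(sum(!ok), " malformed synonym-resource row(s) skipped")
  fields <- fields[ok]
  word <- tolower(vapply(fields, `[[`, character(1), 1L))
  cls <- tolower(vapply(fields, `[[`, character(1), 2L))
  rel <- tolower(vapply(fields, `[[`, character(1), 3L))
  alt <- tolower(vapply(fields, `[[`, character(1), 4L))
  keep <- cls %in% c("noun", "adjective") & rel %in% c("synonym", "similar") &
    !grepl(" ", alt, fixed = TRUE)
  if (any(!keep)) {
    warning(sum(!keep),
            " synonym-resource row(s) with unsupported class/relation or ",
            "multi-word alternative skipped")
  }
  word <- word[keep]; rel <- rel[keep]; alt <- alt[keep]
  as_map <- function(which_rel) {
    sel <- rel == which_rel
    if (!any(sel)) return(list())
    lapply(split(alt[sel], factor(word[sel], levels = unique(word[sel]))),
           unique)
  }
  structure(list(synonym = as_map("synonym"), similar = as_map("similar")),
            class = "pheno_synonym_resource")
}

#' Alternatives for one token
#'
#' Returns the token itself, the words sharing a synset with it (`synonym`
#' relation, for noun and adjective senses), and the words exactly one
#' similar-to hop away from that synset — i.e. the similar-relation
#' alternatives of the token and of its same-synset words. A word unknown to
#' the resource maps to itself only. Deeper traversal is deliberately not
#' performed: one similar-to hop captures qualifier chains such as
#' elevated / raised / increased without uncontrolled expansion.
#'
#' @param token a non-empty lower-cased token.
#' @param resource a [read_synonym_resource()] object, or `NULL`.
#' @return A sorted character vector always containing `token`.
#' @export
token_alternatives <- function(token, resource = NULL) {
  stopifnot(nzchar(token))
  if (is.null(resource)) return(token)
  synset <- unique(c(token, resource$synonym[[token]]))
  one_hop <- unlist(lapply(synset, function(w) resource$similar[[w]]),
                    use.names = FALSE)
  sort(unique(c(synset, one_hop)))
}

#' Generate semantic variants of a token sequence
#'
#' Builds the Cartesian product of the per-token alternative sets, emulating
#' synonym substitution over the mention's nouns and adjectives. Enumeration
#' is deterministic: at each position the original token comes first followed
#' by its remaining alternatives in sorted order, and positions vary
#' rightmost-fastest, so the original sequence is always element 1. The
#' product is truncated at `cap` variants (the combination space is otherwise
#' unbounded) with the `truncated` flag set.
#'
#' @param tokens non-empty character vector of normalised tokens.
#' @param resource a [read_synonym_resource()] object, or `NULL` for no
#'   substitution.
#' @param cap maximum number of variants retained (default 256).
#' @return An object of class `pheno_variant_set`: list with `original`,
#'   `variants` (list of token vectors, original first, no duplicates),
#'   `cap`, and `truncated`.
#' @export
generate_variants <- function(tokens, resource = NULL, cap = 256L) {
  stopifnot(length(tokens) > 0L, cap >= 1L)
  alts <- lapply(tokens, function(tok) {
    a <- token_alternatives(tok, resource)
    c(tok, setdiff(a, tok))
  })
  sizes <- lengths(alts)
  total <- prod(sizes)
  n_keep <- as.integer(min(total, cap))
  n_tok <- length(tokens)
  # mixed-radix enumeration, rightmost position fastest
  variants <- vector("list", n_keep)
  for (v in seq_len(n_keep)) {
    idx <- v - 1L
    pick <- integer(n_tok)
    for (p in n_tok:1) {
      pick[p] <- idx %% sizes[p] + 1L
      idx <- idx %/% sizes[p]
    }
    variants[[v]] <- vapply(seq_len(n_tok), function(p) alts[[p]][pick[p]],
                            character(1))
  }
  keys <- vapply(variants, paste, character(1), collapse = " ")
  variants <- variants[!duplicated(keys)]
  structure(
    list(original = tokens, variants = variants, cap = as.integer(cap),
         truncated = total > cap),
    class = "pheno_variant_set"
  )
}

#' @export
print.pheno_variant_set <- function(x, ...) {
  cat(sprintf("<pheno_variant_set> '%s': %d variant(s)%s\n",
              paste(x$original, collapse = " "), length(x$variants),
              if (x$truncated) sprintf(" (truncated at %d)", x$cap) else ""))
  invisible(x)
}
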