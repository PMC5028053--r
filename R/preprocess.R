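#' Default stop-word list
#'
#' A small clinical-safe stop-word list (articles, copulas, prepositions,
#' pronouns, conjunctions). Negation words (`no`, `not`, `without`) are
#' deliberately excluded: dropping them would merge clinically opposite
#' mentions. The list is shipped as `extdata/stopwords.txt` and can be
#' replaced wholesale by passing any character vector where a `stop_words`
#' argument is accepted.
#'
#' @return A lower-cased character vector.
#' @export
default_stop_words <- function() {
  cached <- .pheno_cache$stop_words
  if (!is.null(cached)) return(cached)
  words <- readLines(pkg_extdata("stopwords.txt"), warn = FALSE)
  words <- tolower(trimws(words))
  words <- words[nzchar(words) & !startsWith(words, "#")]
  .pheno_cache$stop_words <- words
  words
}

.pheno_cache <- new.env(parent = emptyenv())

#' Normalise and tokenise a mention or synonym string
#'
#' Lower-cases, collapses intra-word hyphens and slashes (so
#' `light-headedness` and `lightheadedness` normalise identically), treats
#' remaining punctuation as token separators, splits on whitespace, and
#' removes stop words, preserving token order. Digits are kept (`type 2
#' diabetes`, `3vd`).
#'
#' @param raw_text a non-empty string.
#' @param stop_words character vector of stop words to remove.
#' @return A character vector of tokens. When the input contained tokens but
#'   all of them were stop words, the result has length zero and carries the
#'   attribute `all_stop_words = TRUE`; callers treat such mentions as
#'   unnormalisable.
#' @export
normalize_tokens <- function(raw_text, stop_words = default_stop_words()) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L, nzchar(raw_text))
  s <- tolower(raw_text)
  # join hyphen/slash-linked word fragments, then strip other punctuation
  s <- gsub("(?<=[a-z0-9])[-/](?=[a-z0-9])", "", s, perl = TRUE)
  s <- gsub("[^a-z0-9]+", " ", s)
  toks <- strsplit(trimws(s), " +")[[1]]
  toks <- toks[nzchar(toks)]
  had_tokens <- length(toks) > 0L
  toks <- toks[!toks %in% stop_words]
  if (length(toks) == 0L && had_tokens) attr(toks, "all_stop_words") <- TRUE
  toks
}

#' Read an abbreviation dictionary
#'
#' TSV format `short_form<TAB>expansion`, one row per expansion; repeated
#' short forms accumulate alternatives and the first row listed is the
#' default. Short forms are matched case-insensitively against normalised
#' tokens.
#'
#' @param path TSV file path.
#' @return A named list mapping lower-cased short form to a character vector
#'   of expansions (default first), of class `pheno_abbreviations`.
#' @export
read_abbreviations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 2L
  if (any(!ok)) warning(sum(!ok), " malformed abbreviation row(s) skipped")
  fields <- fields[ok]
  short <- tolower(vapply(fields, `[[`, character(1), 1L))
  long <- vapply(fields, `[[`, character(1), 2L)
  structure(split(long, factor(short, levels = unique(short))),
            class = "pheno_abbreviations")
}

#' Expand abbreviations in a token sequence
#'
#' Each token matching a dictionary short form is replaced in place by the
#' normalised tokens of its default (first-listed) expansion; other tokens are
#' untouched. Expansion is context-free: an ambiguous short form always takes
#' the default, and the ambiguity is reported via a message.
#'
#' @param tokens character vector of normalised tokens.
#' @param dictionary a [read_abbreviations()] dictionary, or `NULL`/empty for
#'   the identity.
#' @param stop_words stop words removed from expansions, so expanded mentions
#'   normalise the same way as lexicon synonyms.
#' @return A character vector of tokens.
#' @export
expand_abbreviations <- function(tokens, dictionary = NULL,
                                 stop_words = default_stop_words()) {
  if (is.null(dictionary) || length(dictionary) == 0L || length(tokens) == 0L)
    return(tokens)
  hit <- tokens %in% names(dictionary)
  if (!any(hit)) return(tokens)
  out <- lapply(seq_along(tokens), function(i) {
    if (!hit[i]) return(tokens[i])
    expansions <- dictionary[[tokens[i]]]
    if (length(expansions) > 1L) {
      message("ambiguous short form '", tokens[i], "': using default '",
              expansions[1L], "'")
    }
    normalize_tokens(expansions[1L], stop_words = stop_words)
  })
  unlist(out, use.names = FALSE)
}

# qualifier words eligible to be distributed as a shared leading modifier
default_qualifier_words <- function() {
  c("increased", "increasing", "decreased", "decreasing", "elevated",
    "raised", "reduced", "worsening", "severe", "mild", "moderate",
    "chronic", "acute", "progressive", "recurrent", "persistent",
    "intermittent", "bilateral", "high", "low")
}

#' Split a coordinated phrase into separate mentions
#'
#' Coordinated noun phrases frequently bundle several distinct concepts into
#' one annotation (`increased chest pain and fatigue` mentions both
#' `increased chest pain` and `increased fatigue`). This splitter detects
#' conjuncts joined by `and`, `or` or commas and distributes shared material
#' over them using two shallow patterns:
#'
#' * shared trailing head — when the final conjunct is longer than all the
#'   others, its surplus trailing tokens are appended to each earlier
#'   conjunct (`stable or unstable angina` -> `stable angina`,
#'   `unstable angina`; `breast, brain, prostate and kidney cancer` ->
#'   four `... cancer` phrases);
#' * shared leading modifier — when the first conjunct is longer than the
#'   rest and opens with qualifier words, that qualifier run is prefixed to
#'   each later conjunct (`increased chest pain and fatigue` ->
#'   `increased chest pain`, `increased fatigue`).
#'
#' When neither pattern applies the bare conjuncts are returned; without any
#' coordination the input comes back as a single phrase. Splitting is applied
#' unconditionally, even where the target resource lists the coordination as
#' one concept (a known failure mode, e.g. `breast and ovarian cancer
#' syndrome`); pass `split = FALSE` to [normalize_mention()] to disable it.
#'
#' @param raw_text a non-empty string.
#' @param qualifier_words words eligible for leading-modifier distribution.
#' @return A character vector of phrase strings in surface order.
#' @export
split_coordination <- function(raw_text,
                               qualifier_words = default_qualifier_words()) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L, nzchar(raw_text))
  chunks <- strsplit(raw_text, "\\s*,\\s*|\\s+(?i:and|or)\\s+",
                     perl = TRUE)[[1]]
  chunks <- trimws(chunks)
  chunks <- chunks[nzchar(chunks)]
  if (length(chunks) <= 1L) return(trimws(raw_text))
  toks <- strsplit(chunks, "\\s+")
  len <- lengths(toks)
  k <- length(chunks)

  if (len[k] >= 2L && all(len[-k] < len[k])) {
    # shared trailing head distributed from the last conjunct
    head_tokens <- tail(toks[[k]], len[k] - max(len[-k]))
    head_str <- paste(head_tokens, collapse = " ")
    return(c(paste(chunks[-k], head_str), chunks[k]))
  }

  if (len[1L] > max(len[-1L])) {
    run <- 0L
    while (run < len[1L] - 1L && tolower(toks[[1L]][run + 1L]) %in% qualifier_words)
      run <- run + 1L
    if (run >= 1L) {
      mod <- paste(toks[[1L]][seq_len(run)], collapse = " ")
      return(c(chunks[1L], paste(mod, chunks[-1L])))
    }
  }
  chunks
}

#' Read and write standoff mention files
#'
#' The standoff format is TSV with columns
#' `doc_id<TAB>start<TAB>end<TAB>text<TAB>category<TAB>gold_concept_id`,
#' where the last two columns are optional and spans are 0-based half-open
#' character offsets. A file whose lines contain no tab is accepted as a bare
#' list of mention strings, one per line. Multiple gold concepts for one
#' mention (legal coordination splits) are separated by `;`.
#'
#' @param path file path.
#' @return `read_mentions()` returns a data frame with columns `mention_id`,
#'   `doc_id`, `start`, `end`, `text`, `category`, `gold_concept_id` (the last
#'   may be `NA`); `write_mentions()` returns `path` invisibly.
#' @export
read_mentions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && startsWith(tolower(lines[1L]), "doc_id\t"))
    lines <- lines[-1L]
  if (length(lines) == 0L) {
    return(data.frame(mention_id = character(0), doc_id = character(0),
                      start = integer(0), end = integer(0),
                      text = character(0), category = character(0),
                      gold_concept_id = character(0), stringsAsFactors = FALSE))
  }
  if (!any(grepl("\t", lines, fixed = TRUE))) {
    return(data.frame(
      mention_id = sprintf("m%04d", seq_along(lines)),
      doc_id = NA_character_, start = NA_integer_, end = NA_integer_,
      text = lines, category = NA_character_,
      gold_concept_id = NA_character_, stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 4L
  if (any(!ok)) warning(sum(!ok), " malformed standoff row(s) skipped")
  fields <- fields[ok]
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i && nzchar(f[[i]])) f[[i]]
           else default, character(1))
  }
  data.frame(
    mention_id = sprintf("m%04d", seq_along(fields)),
    doc_id = get_col(1L),
    start = as.integer(get_col(2L)),
    end = as.integer(get_col(3L)),
    text = get_col(4L),
    category = get_col(5L),
    gold_concept_id = get_col(6L),
    stringsAsFactors = FALSE
  )
}

#' @param mentions a data frame as returned by [read_mentions()] or
#'   [generate_benchmark()].
#' @rdname read_mentions
#' @export
write_mentions <- function(mentions, path) {
  cols <- c("doc_id", "start", "end", "text", "category", "gold_concept_id")
  for (col in cols) if (is.null(mentions[[col]])) mentions[[col]] <- NA
  body <- do.call(paste, c(lapply(cols, function(col) {
    v <- as.character(mentions[[col]])
    ifelse(is.na(v), "", v)
  }), sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), body), con, useBytes = TRUE)
  invisible(path)
}
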