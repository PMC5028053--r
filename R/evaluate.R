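# split a ';'-joined gold/prediction cell into a concept-id set
split_ids <- function(x) {
  if (length(x) == 0L || all(is.na(x))) return(character(0))
  ids <- unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE), use.names = FALSE)
  unique(trimws(ids[nzchar(trimws(ids))]))
}

# collect per-mention predicted and gold concept sets from long-format frames
collect_sets <- function(predictions, gold) {
  stopifnot(all(c("mention_id", "concept_id") %in% names(predictions)),
            all(c("mention_id", "gold_concept_id") %in% names(gold)))
  if (nrow(gold) == 0L) stop("empty gold standard")
  gold_sets <- lapply(split(gold$gold_concept_id, gold$mention_id), split_ids)
  pred_sets <- lapply(split(predictions$concept_id, predictions$mention_id),
                      split_ids)
  ids <- names(gold_sets)
  orphans <- setdiff(names(pred_sets), ids)
  if (length(orphans) > 0L) {
    stop("predictions contain mention ids absent from gold: ",
         paste(head(orphans, 5L), collapse = ", "))
  }
  category <- gold$category[match(ids, gold$mention_id)]
  category[is.na(category)] <- "other"
  list(ids = ids,
       gold = gold_sets,
       pred = lapply(ids, function(i) pred_sets[[i]] %||% character(0)),
       category = category)
}

#' Normalisation accuracy
#'
#' Accuracy = correct / total, overall and per semantic category, where
#' `correct` counts mentions normalised to the right concept(s) and `total`
#' counts all gold mentions. With the default `unit = "mention"` a mention is
#' correct only when its full predicted concept set equals the gold set
#' (every coordination-split sub-mention must be right); with
#' `unit = "sub_mention"` each gold concept of a mention is scored
#' individually, so partially correct splits earn partial credit.
#'
#' @param predictions data frame with columns `mention_id` and `concept_id`
#'   (several rows, or `;`-joined ids, for split mentions; `NA` = unmapped).
#' @param gold data frame with columns `mention_id`, `gold_concept_id`, and
#'   optionally `category`.
#' @param unit accuracy unit, `"mention"` or `"sub_mention"`.
#' @return An object of class `pheno_eval_report` with components `overall`
#'   (one-row data frame: `total`, `correct`, `accuracy`) and `by_category`.
#' @export
accuracy <- function(predictions, gold, unit = c("mention", "sub_mention")) {
  unit <- match.arg(unit)
  sets <- collect_sets(predictions, gold)
  if (unit == "mention") {
    total <- rep(1L, length(sets$ids))
    correct <- mapply(function(p, g) as.integer(setequal(p, g)),
                      sets$pred, sets$gold)
  } else {
    total <- lengths(sets$gold)
    correct <- mapply(function(p, g) sum(g %in% p), sets$pred, sets$gold)
  }
  per_cat <- function(sel) {
    tot <- sum(total[sel]); cor <- sum(correct[sel])
    data.frame(total = tot, correct = cor,
               accuracy = if (tot > 0L) cor / tot else NA_real_)
  }
  cats <- sort(unique(sets$category))
  by_category <- do.call(rbind, lapply(cats, function(cat) {
    cbind(data.frame(category = cat, stringsAsFactors = FALSE),
          per_cat(sets$category == cat))
  }))
  structure(list(overall = per_cat(rep(TRUE, length(total))),
                 by_category = by_category, unit = unit),
            class = "pheno_eval_report")
}

#' Precision, recall and F-score with split-mention counting rules
#'
#' Counts true positives, false positives and false negatives per gold
#' mention under the counting rules appropriate for a normaliser that may
#' split a mention into several concepts:
#'
#' * every correctly predicted gold concept is 1 TP;
#' * a single-concept mention mapped to one wrong concept is 1 FN (not an
#'   FP) — the system attempted the right granularity and missed;
#' * a single-concept mention wrongly split into k incorrect concepts is
#'   1 FN plus (k - 1) FP — the canonical 2-way wrong split counts 1 FP and
#'   1 FN;
#' * for mentions whose gold itself lists several concepts (legal splits),
#'   every unmatched gold concept is 1 FN and every extra prediction 1 FP;
#' * an unmapped mention contributes its gold concepts as FN.
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F = 2PR/(P+R); undefined ratios are reported as `NA`, never as zero.
#'
#' @inheritParams accuracy
#' @return A `pheno_eval_report` with `overall` and `by_category` frames
#'   carrying `tp`, `fp`, `fn`, `precision`, `recall`, `f_score`.
#' @export
prf_with_split_rules <- function(predictions, gold) {
  sets <- collect_sets(predictions, gold)
  counts <- mapply(function(p, g) {
    tp <- length(intersect(g, p))
    if (length(g) == 1L && tp == 0L) {
      # single-concept gold, all predictions wrong
      c(tp = 0L, fp = max(0L, length(p) - 1L), fn = 1L)
    } else {
      c(tp = tp, fp = length(setdiff(p, g)), fn = length(setdiff(g, p)))
    }
  }, sets$pred, sets$gold)
  summarise <- function(sel) {
    tp <- sum(counts["tp", sel]); fp <- sum(counts["fp", sel])
    fn <- sum(counts["fn", sel])
    p <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
    f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r)
         else NA_real_
    data.frame(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
               f_score = f)
  }
  cats <- sort(unique(sets$category))
  by_category <- do.call(rbind, lapply(cats, function(cat) {
    cbind(data.frame(category = cat, stringsAsFactors = FALSE),
          summarise(sets$category == cat))
  }))
  structure(list(overall = summarise(rep(TRUE, ncol(counts))),
                 by_category = by_category),
            class = "pheno_eval_report")
}

#' @export
print.pheno_eval_report <- function(x, ...) {
  cat("<pheno_eval_report>\n")
  cat("overall:\n")
  print(x$overall, row.names = FALSE)
  if (!is.null(x$by_category) && nrow(x$by_category) > 0L) {
    cat("by category:\n")
    print(x$by_category, row.names = FALSE)
  }
  invisible(x)
}

#' Concept overlap between two text sources
#'
#' Partitions the union of two concept-id sets into the concepts unique to
#' the first set, the shared concepts, and those unique to the second set —
#' the summary used to compare which concepts appear in EHR narratives versus
#' literature articles.
#'
#' @param concept_set_a,concept_set_b character vectors of concept ids.
#' @return A named integer vector `c(only_a, shared, only_b)`.
#' @export
concept_overlap <- function(concept_set_a, concept_set_b) {
  a <- unique(concept_set_a)
  b <- unique(concept_set_b)
  c(only_a = length(setdiff(a, b)),
    shared = length(intersect(a, b)),
    only_b = length(setdiff(b, a)))
}
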