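# strict match keys: an entity matches iff (doc, start, end, label) all
# agree; a relation iff both endpoint entity keys and its type agree
entity_keys <- function(doc) {
  e <- doc$entities
  if (nrow(e) == 0L) return(data.frame(key = character(0),
                                       type = character(0)))
  data.frame(key = paste(doc$doc_id, e$start, e$end, e$label, sep = "\r"),
             type = e$label, stringsAsFactors = FALSE)
}

relation_keys <- function(doc) {
  r <- doc$relations
  if (nrow(r) == 0L) return(data.frame(key = character(0),
                                       type = character(0)))
  e <- doc$entities
  ek <- function(ids) {
    i <- match(ids, e$id)
    paste(e$start[i], e$end[i], e$label[i], sep = ",")
  }
  data.frame(key = paste(doc$doc_id, ek(r$subject_id), ek(r$object_id),
                         r$type, sep = "\r"),
             type = r$type, stringsAsFactors = FALSE)
}

pool_keys <- function(docs, level) {
  f <- if (level == "entities") entity_keys else relation_keys
  out <- do.call(rbind, lapply(docs, f))
  if (is.null(out)) data.frame(key = character(0), type = character(0))
  else unique(out)
}

prf <- function(n_gold, n_pred, n_match) {
  p <- if (n_pred > 0) n_match / n_pred else 0
  r <- if (n_gold > 0) n_match / n_gold else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

check_aligned <- function(gold, pred) {
  gid <- vapply(gold, `[[`, character(1), "doc_id")
  pid <- vapply(pred, `[[`, character(1), "doc_id")
  if (!setequal(gid, pid) || anyDuplicated(gid) || anyDuplicated(pid)) {
    stop("gold and pred corpora must contain the same document ids")
  }
  gtxt <- setNames(vapply(gold, `[[`, character(1), "text"), gid)
  ptxt <- setNames(vapply(pred, `[[`, character(1), "text"), pid)
  if (!identical(gtxt[sort(gid)], ptxt[sort(gid)])) {
    stop("gold and pred documents must share identical texts")
  }
}

score_sets <- function(gkeys, pkeys, level) {
  inter <- intersect(gkeys$key, pkeys$key)
  micro <- prf(nrow(gkeys), nrow(pkeys), length(inter))
  types <- sort(unique(c(gkeys$type, pkeys$type)))
  per_type <- do.call(rbind, lapply(types, function(tp) {
    g <- gkeys$key[gkeys$type == tp]
    p <- pkeys$key[pkeys$type == tp]
    s <- prf(length(g), length(p), length(intersect(g, p)))
    data.frame(type = tp, precision = s[["precision"]],
               recall = s[["recall"]], f1 = s[["f1"]],
               n_gold = length(g), n_pred = length(p),
               n_match = length(intersect(g, p)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_type)) {
    per_type <- data.frame(type = character(0), precision = numeric(0),
                           recall = numeric(0), f1 = numeric(0),
                           n_gold = integer(0), n_pred = integer(0),
                           n_match = integer(0))
  }
  structure(list(level = level,
                 precision = micro[["precision"]],
                 recall = micro[["recall"]],
                 f1 = micro[["f1"]],
                 n_gold = nrow(gkeys), n_pred = nrow(pkeys),
                 n_match = length(inter),
                 per_type = per_type),
            class = "tcm_eval")
}

#' @export
print.tcm_eval <- function(x, digits = 4, ...) {
  cat(sprintf("Strict %s scores (micro): P=%.*f R=%.*f F1=%.*f  (gold=%d pred=%d match=%d)\n",
              x$level, digits, x$precision, digits, x$recall, digits, x$f1,
              x$n_gold, x$n_pred, x$n_match))
  if (nrow(x$per_type)) {
    pt <- x$per_type
    pt$precision <- round(pt$precision, digits)
    pt$recall <- round(pt$recall, digits)
    pt$f1 <- round(pt$f1, digits)
    print(pt, row.names = FALSE)
  }
  invisible(x)
}

#' Strict entity scoring
#'
#' Precision, recall and F1 over entity keys: an entity in the
#' prediction counts as correct if and only if all of its constituent
#' elements - both boundaries and the type - agree with a gold entity
#' in the same document. `P = |y1 ∩ y2| / |y2|`, `R = |y1 ∩ y2| / |y1|`,
#' `F1 = 2PR/(P+R)`; by convention a score with zero denominator is 0.
#' Micro scores pool keys over all documents; per-type scores restrict
#' to one label.
#'
#' @param gold,pred Lists of `tcm_document` objects over the same
#'   document ids and texts.
#' @return A `tcm_eval` object.
#' @export
strict_entity_prf <- function(gold, pred) {
  check_aligned(gold, pred)
  score_sets(pool_keys(gold, "entities"), pool_keys(pred, "entities"),
             "entities")
}

#' Strict relation scoring
#'
#' Like [strict_entity_prf()] but over relation keys: a predicted
#' relation is correct iff its subject entity, object entity (both by
#' strict span+label identity) and its relation type all agree with a
#' gold relation. A reversed subject/object pair therefore counts as
#' wrong.
#'
#' @inheritParams strict_entity_prf
#' @return A `tcm_eval` object.
#' @export
strict_relation_prf <- function(gold, pred) {
  check_aligned(gold, pred)
  score_sets(pool_keys(gold, "relations"), pool_keys(pred, "relations"),
             "relations")
}

#' Inter-annotator agreement
#'
#' Pairwise agreement between two annotators of the same documents:
#' annotator `a` is taken as the reference and `b` as the prediction,
#' scored strictly. Because `|a ∩ b|` is symmetric, swapping the two
#' annotators leaves the F1 score unchanged (precision and recall
#' trade places).
#'
#' @param a,b Lists of `tcm_document` objects from the two annotators.
#' @param level `"entities"` or `"relations"`.
#' @return A `tcm_eval` object.
#' @export
iaa_report <- function(a, b, level = c("entities", "relations")) {
  level <- match.arg(level)
  if (level == "entities") strict_entity_prf(a, b)
  else strict_relation_prf(a, b)
}

#' Per-sentence annotation rate
#'
#' The symptom-information utilization of an annotation scheme: for
#' each sentence (a segment ending at, and including, its sentence
#' delimiter), the fraction of characters covered by entity spans;
#' delimiters count in the denominator. The corpus-level value is the
#' unweighted mean over all sentences.
#'
#' @param docs List of `tcm_document` objects (or one document).
#' @param cfg A [segmentation_config()].
#' @return List with `rate` (corpus mean) and `per_sentence` (data
#'   frame with `doc_id`, `sentence`, `start`, `end`, `covered`,
#'   `total`, `rate`).
#' @export
annotation_rate <- function(docs, cfg = segmentation_config()) {
  if (inherits(docs, "tcm_document")) docs <- list(docs)
  if (length(docs) == 0L) stop("annotation_rate: empty corpus")
  rows <- list()
  for (doc in docs) {
    n <- nchar(doc$text)
    if (n == 0L) next
    chars <- strsplit(doc$text, "")[[1]]
    delim_pos <- which(chars %in% cfg$sentence_delims)  # 1-based
    starts <- c(0L, delim_pos)                           # 0-based unit starts
    ends <- c(delim_pos, if (length(delim_pos) == 0L || max(delim_pos) < n) n)
    starts <- starts[seq_along(ends)]
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    covered <- logical(n)
    for (i in seq_len(nrow(doc$entities))) {
      s <- doc$entities$start[i]; e <- doc$entities$end[i]
      if (!is.na(s) && !is.na(e) && s >= 0L && e <= n && s < e) {
        covered[(s + 1L):e] <- TRUE
      }
    }
    for (k in seq_along(starts)) {
      tot <- ends[k] - starts[k]
      cov <- sum(covered[(starts[k] + 1L):ends[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = doc$doc_id, sentence = k, start = starts[k], end = ends[k],
        covered = cov, total = tot, rate = cov / tot,
        stringsAsFactors = FALSE)
    }
  }
  per_sentence <- do.call(rbind, rows)
  if (is.null(per_sentence)) stop("annotation_rate: corpus has no text")
  list(rate = mean(per_sentence$rate), per_sentence = per_sentence)
}
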