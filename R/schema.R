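#' Entity type labels of the fine-grained symptom schema
#'
#' The schema distinguishes twelve entity types. `State` is a symptom
#' element that cannot stand alone and must combine with a position;
#' `Symp_S` (single symptom) expresses a complete symptom on its own.
#' The position triad is `Pos_SCP` (scope qualifier, e.g. left/both),
#' `Pos_Pri` (primary subject such as an anatomical part) and `Pos_Sub`
#' (subordinate aspect between primary and state, e.g. quantity, colour,
#' quality). The remaining types are modifiers: `Time`, `Cond`
#' (triggering circumstance), `Neg` (negation), `Freq`, `Sev_Qual` and
#' `Sev_Quant` (qualitative/quantitative severity) and `Trend`
#' (direction of change).
#'
#' @return Character vector of the 12 entity type labels.
#' @export
#' @examples
#' entity_types()
entity_types <- function() {
  c("State", "Pos_Pri", "Pos_SCP", "Pos_Sub", "Symp_S", "Time",
    "Cond", "Neg", "Freq", "Sev_Qual", "Sev_Quant", "Trend")
}

#' Relation types and their endpoint-constraint matrix
#'
#' Each of the ten directed relation types is named subject_object and
#' constrains which entity types may appear at either end. Except for
#' the position relations, every relation takes a `State` or `Symp_S`
#' subject; the position relations follow the progressive order
#' subordinate -> primary -> scope.
#'
#' @return A data frame with one row per relation type and columns
#'   `type`, `subjects` (comma-separated allowed subject labels) and
#'   `object` (the single allowed object label).
#' @export
#' @examples
#' relation_types()
relation_types <- function() {
  data.frame(
    type = c("SPri", "SSub", "SSCP", "SN", "STi",
             "SC", "SF", "SQual", "SQuant", "STr"),
    subjects = c("State,Pos_Sub",
                 "State",
                 "State,Pos_Pri,Pos_Sub",
                 "State,Symp_S",
                 "State,Symp_S",
                 "State,Symp_S",
                 "State,Symp_S",
                 "State,Symp_S",
                 "State,Symp_S",
                 "State,Symp_S"),
    object = c("Pos_Pri", "Pos_Sub", "Pos_SCP", "Neg", "Time",
               "Cond", "Freq", "Sev_Qual", "Sev_Quant", "Trend"),
    stringsAsFactors = FALSE
  )
}

# allowed subject labels for one relation type, as a character vector
allowed_subjects <- function(type) {
  rt <- relation_types()
  strsplit(rt$subjects[rt$type == type], ",", fixed = TRUE)[[1]]
}

# allowed object label for one relation type
allowed_object <- function(type) {
  rt <- relation_types()
  rt$object[rt$type == type]
}

#' Segmentation configuration
#'
#' Clause and sentence boundaries drive the scope of every extraction
#' rule. Clauses are delimited by the full-width comma and period;
#' sentences by the full-width period only. The enumeration mark and
#' semicolons are deliberately not delimiters by default, matching the
#' letter of the extraction rules; pass different sets to change that.
#'
#' @param clause_delims Character vector of single-character clause
#'   delimiters.
#' @param sentence_delims Character vector of single-character sentence
#'   delimiters; must be a subset of `clause_delims`.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(clause_delims = c("，", "。"),
                                sentence_delims = "。") {
  stopifnot(all(nchar(clause_delims) == 1L), all(nchar(sentence_delims) == 1L))
  if (!all(sentence_delims %in% clause_delims)) {
    stop("sentence_delims must be a subset of clause_delims")
  }
  structure(list(clause_delims = clause_delims,
                 sentence_delims = sentence_delims),
            class = "segmentation_config")
}

# spans (0-based, half-open) of maximal runs of non-delimiter characters
delim_spans <- function(text, delims) {
  n <- nchar(text)
  if (n == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  is_delim <- chars %in% delims
  r <- rle(is_delim)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Clause spans of a text
#'
#' Splits a text into clause spans at the configured clause delimiters.
#' Spans are 0-based, half-open, counted in Unicode code points;
#' delimiter characters belong to no span, and a trailing segment
#' without a final delimiter is still emitted.
#'
#' @param text A single string.
#' @param cfg A [segmentation_config()].
#' @return Data frame with columns `start` and `end`.
#' @export
#' @examples
#' clause_spans("A，B。")  # two clauses
clause_spans <- function(text, cfg = segmentation_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  delim_spans(text, cfg$clause_delims)
}

#' Sentence spans of a text
#'
#' Like [clause_spans()] but splits only at sentence delimiters, so
#' commas do not break a sentence.
#'
#' @inheritParams clause_spans
#' @return Data frame with columns `start` and `end`.
#' @export
sentence_spans <- function(text, cfg = segmentation_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  delim_spans(text, cfg$sentence_delims)
}

# 0-based half-open substring on code points (vectorized over offsets)
substr0 <- function(text, start, end) {
  substring(text, start + 1L, end)
}

empty_entities <- function() {
  data.frame(id = integer(0), label = character(0), start = integer(0),
             end = integer(0), text = character(0), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = integer(0), subject_id = integer(0), object_id = integer(0),
             type = character(0), stringsAsFactors = FALSE)
}

#' Construct an annotated document
#'
#' The unit of all I/O and rule application: a text together with typed
#' entity spans and typed directed relations. Offsets are 0-based,
#' half-open and counted in Unicode code points so that each Chinese
#' character occupies one position. Entity `text` fields are filled in
#' from the document text when missing. Exact duplicate relations (same
#' subject, object and type) are collapsed with a warning.
#'
#' @param doc_id Document identifier (coerced to character).
#' @param text Document text, a single UTF-8 string.
#' @param entities Data frame with columns `id`, `label`, `start`,
#'   `end` and optionally `text`.
#' @param relations Data frame with columns `id`, `subject_id`,
#'   `object_id`, `type`.
#' @return An object of class `tcm_document`.
#' @seealso [validate_document()] for the validity checks.
#' @export
annotated_document <- function(doc_id, text,
                               entities = empty_entities(),
                               relations = empty_relations()) {
  stopifnot(is.character(text), length(text) == 1L)
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (nrow(entities) == 0L) entities <- empty_entities()
  if (nrow(relations) == 0L) relations <- empty_relations()
  entities$id <- as.integer(entities$id)
  entities$start <- as.integer(entities$start)
  entities$end <- as.integer(entities$end)
  if (is.null(entities$text)) {
    entities$text <- substr0(text, entities$start, entities$end)
  }
  relations$id <- as.integer(relations$id)
  relations$subject_id <- as.integer(relations$subject_id)
  relations$object_id <- as.integer(relations$object_id)
  dup <- duplicated(relations[, c("subject_id", "object_id", "type")])
  if (any(dup)) {
    warning(sprintf("document %s: %d duplicate relation(s) collapsed",
                    as.character(doc_id), sum(dup)))
    relations <- relations[!dup, , drop = FALSE]
  }
  rownames(entities) <- NULL
  rownames(relations) <- NULL
  structure(list(doc_id = as.character(doc_id), text = text,
                 entities = entities, relations = relations),
            class = "tcm_document")
}

#' @export
print.tcm_document <- function(x, ...) {
  cat(sprintf("<tcm_document %s: %d code points, %d entities, %d relations>\n",
              x$doc_id, nchar(x$text), nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

# entities sorted by (start, end); ties broken by id for stability
sorted_entities <- function(doc) {
  e <- doc$entities
  e[order(e$start, e$end, e$id), , drop = FALSE]
}

violation <- function(kind, severity, message, entity_id = NA_integer_,
                      relation_id = NA_integer_) {
  data.frame(kind = kind, severity = severity, message = message,
             entity_id = as.integer(entity_id),
             relation_id = as.integer(relation_id),
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  violation(character(0), character(0), character(0), integer(0), integer(0))
}

#' Validate an annotated document
#'
#' Checks the annotation principles and schema constraints: span bounds
#' and text/offset agreement, no overlapping and no nested entity
#' annotation, unique `(start, end, label)` triples, resolvable relation
#' endpoints, no self-relations, and conformance of every relation to
#' the endpoint-constraint matrix of [relation_types()]. An entity whose
#' surface contains a clause delimiter is flagged as a `suspicious_span`
#' warning rather than an error. Violations are returned as data, never
#' thrown; the result is empty if and only if the document is valid
#' (warnings excluded when `warnings = FALSE` is not requested).
#'
#' @param doc A `tcm_document`.
#' @param cfg A [segmentation_config()], used for the suspicious-span
#'   warning only.
#' @param warnings Include warning-severity records? Default `TRUE`.
#' @return Data frame with columns `kind`, `severity`, `message`,
#'   `entity_id`, `relation_id`; zero rows when the document is valid.
#' @export
validate_document <- function(doc, cfg = segmentation_config(),
                              warnings = TRUE) {
  stopifnot(inherits(doc, "tcm_document"))
  out <- list(no_violations())
  e <- sorted_entities(doc)
  n <- nchar(doc$text)
  known <- entity_types()

  for (i in seq_len(nrow(e))) {
    ei <- e[i, ]
    if (!(ei$label %in% known)) {
      out[[length(out) + 1L]] <- violation(
        "unknown_label", "error",
        sprintf("entity %d has unknown label '%s'", ei$id, ei$label), ei$id)
    }
    if (is.na(ei$start) || is.na(ei$end) ||
        ei$start < 0L || ei$start >= ei$end || ei$end > n) {
      out[[length(out) + 1L]] <- violation(
        "bad_span", "error",
        sprintf("entity %d span [%s,%s) outside text of length %d",
                ei$id, ei$start, ei$end, n), ei$id)
      next
    }
    actual <- substr0(doc$text, ei$start, ei$end)
    if (!identical(actual, ei$text)) {
      out[[length(out) + 1L]] <- violation(
        "text_mismatch", "error",
        sprintf("entity %d text '%s' != document substring '%s'",
                ei$id, ei$text, actual), ei$id)
    }
    if (any(strsplit(actual, "")[[1]] %in% cfg$clause_delims)) {
      out[[length(out) + 1L]] <- violation(
        "suspicious_span", "warning",
        sprintf("entity %d surface '%s' contains a delimiter", ei$id, actual),
        ei$id)
    }
  }

  if (nrow(e) > 1L) {
    for (i in seq_len(nrow(e) - 1L)) {
      a <- e[i, ]
      for (j in (i + 1L):nrow(e)) {
        b <- e[j, ]
        if (b$start >= a$end) break
        # sorted by (start, end), so a$start <= b$start: containment in
        # either direction is nesting, partial intersection is overlap
        kind <- if (b$end <= a$end || a$start == b$start) "nesting" else "overlap"
        out[[length(out) + 1L]] <- violation(
          kind, "error",
          sprintf("entities %d [%d,%d) and %d [%d,%d) %s",
                  a$id, a$start, a$end, b$id, b$start, b$end, kind),
          b$id)
      }
    }
    key <- paste(e$start, e$end, e$label)
    dup <- duplicated(key)
    for (i in which(dup)) {
      out[[length(out) + 1L]] <- violation(
        "duplicate_entity", "error",
        sprintf("entity %d duplicates span/label of another entity", e$id[i]),
        e$id[i])
    }
  }

  r <- doc$relations
  rt <- relation_types()
  for (i in seq_len(nrow(r))) {
    ri <- r[i, ]
    if (!(ri$type %in% rt$type)) {
      out[[length(out) + 1L]] <- violation(
        "unknown_relation_type", "error",
        sprintf("relation %d has unknown type '%s'", ri$id, ri$type),
        relation_id = ri$id)
      next
    }
    si <- match(ri$subject_id, doc$entities$id)
    oi <- match(ri$object_id, doc$entities$id)
    if (is.na(si) || is.na(oi)) {
      out[[length(out) + 1L]] <- violation(
        "dangling_relation", "error",
        sprintf("relation %d references missing entity id(s)", ri$id),
        relation_id = ri$id)
      next
    }
    if (ri$subject_id == ri$object_id) {
      out[[length(out) + 1L]] <- violation(
        "self_relation", "error",
        sprintf("relation %d relates entity %d to itself", ri$id,
                ri$subject_id),
        relation_id = ri$id)
      next
    }
    slab <- doc$entities$label[si]
    olab <- doc$entities$label[oi]
    if (!(slab %in% allowed_subjects(ri$type)) ||
        !identical(olab, allowed_object(ri$type))) {
      out[[length(out) + 1L]] <- violation(
        "constraint", "error",
        sprintf("relation %d (%s) has endpoints %s -> %s, not allowed",
                ri$id, ri$type, slab, olab),
        relation_id = ri$id)
    }
  }
  dup <- duplicated(r[, c("subject_id", "object_id", "type")])
  for (i in which(dup)) {
    out[[length(out) + 1L]] <- violation(
      "duplicate_relation", "error",
      sprintf("relation %d duplicates another relation", r$id[i]),
      relation_id = r$id[i])
  }

  res <- do.call(rbind, out)
  res <- res[order(match(res$severity, c("error", "warning"))), , drop = FALSE]
  if (!warnings) res <- res[res$severity != "warning", , drop = FALSE]
  rownames(res) <- NULL
  res
}
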