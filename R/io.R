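#' Read an annotation JSONL corpus
#'
#' Reads one JSON record per line in the relation-export dialect of the
#' doccano annotation tool: `{"id", "text", "entities": [{"id",
#' "label", "start_offset", "end_offset"}], "relations": [{"id",
#' "from_id", "to_id", "type"}]}`. `start_offset`/`end_offset` map to
#' the package's `start`/`end` (0-based code points) and
#' `from_id`/`to_id` to `subject_id`/`object_id` (a relation reads
#' subject -> object left to right). Each document is validated on
#' load; violations (e.g. a span outside the text, a dangling
#' relation) are attached as the `"violations"` attribute rather than
#' aborting the read. Unknown top-level keys are kept and written back
#' by [write_annotations()].
#'
#' @param path Path to a UTF-8 JSONL file.
#' @return List of `tcm_document` objects.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("%s line %d: malformed JSON (%s)", path, i,
                     conditionMessage(e)), call. = FALSE)
      })
    if (is.null(rec$text)) {
      stop(sprintf("%s line %d: record has no 'text' key", path, i),
           call. = FALSE)
    }
    ents <- if (length(rec$entities)) {
      do.call(rbind, lapply(rec$entities, function(x) {
        data.frame(id = as.integer(x$id), label = as.character(x$label),
                   start = as.integer(x$start_offset),
                   end = as.integer(x$end_offset),
                   stringsAsFactors = FALSE)
      }))
    } else empty_entities()
    rels <- if (length(rec$relations)) {
      do.call(rbind, lapply(rec$relations, function(x) {
        data.frame(id = as.integer(x$id),
                   subject_id = as.integer(x$from_id),
                   object_id = as.integer(x$to_id),
                   type = as.character(x$type), stringsAsFactors = FALSE)
      }))
    } else empty_relations()
    doc_id <- if (!is.null(rec$id)) rec$id else i - 1L
    # entity text is reconstructed from offsets; bad spans surface as
    # violations, with a placeholder text so the document still loads
    ok <- !is.na(ents$start) & !is.na(ents$end) & ents$start >= 0L &
      ents$start < ents$end & ents$end <= nchar(rec$text)
    ents$text <- NA_character_
    if (any(ok)) {
      ents$text[ok] <- substr0(rec$text, ents$start[ok], ents$end[ok])
    }
    doc <- annotated_document(doc_id, rec$text, ents, rels)
    attr(doc, "violations") <- validate_document(doc)
    extra <- rec[setdiff(names(rec), c("id", "text", "entities", "relations"))]
    if (length(extra)) attr(doc, "extra") <- extra
    docs[[i]] <- doc
  }
  docs
}

#' Write an annotation JSONL corpus
#'
#' Inverse of [read_annotations()]: one record per document, in input
#' order, using the same relation-export dialect. Reading the written
#' file back reproduces the documents (round-trip identity).
#'
#' @param docs List of `tcm_document` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(docs, path) {
  lines <- vapply(docs, function(doc) {
    e <- doc$entities
    r <- doc$relations
    rec <- list(
      id = maybe_int(doc$doc_id),
      text = doc$text,
      entities = lapply(seq_len(nrow(e)), function(i) {
        list(id = e$id[i], label = e$label[i],
             start_offset = e$start[i], end_offset = e$end[i])
      }),
      relations = lapply(seq_len(nrow(r)), function(i) {
        list(id = r$id[i], from_id = r$subject_id[i],
             to_id = r$object_id[i], type = r$type[i])
      }))
    extra <- attr(doc, "extra")
    if (length(extra)) rec <- c(rec, extra)
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# doc ids that look like integers go back out as integers
maybe_int <- function(x) {
  if (grepl("^-?[0-9]+$", x)) as.integer(x) else x
}

#' Fixed column order of the normalized-row table
#'
#' @return Character vector of the 12 column names.
#' @export
normalized_columns <- function() {
  c("doc_id", "time", "position_scope", "position_primary",
    "position_subordinate", "state_or_symptom", "negation", "condition",
    "frequency", "severity_qualitative", "severity_quantitative", "trend")
}

#' Write normalized symptom rows as TSV
#'
#' Writes the table produced by [normalize_document()] (or a row-bound
#' collection over a corpus) as a tab-separated file with a fixed
#' header. Absent cells hold `missing_token`. TSV is used because cell
#' values may contain the full-width comma.
#'
#' @param rows Data frame with the [normalized_columns()] columns.
#' @param path Output path.
#' @param missing_token Placeholder for absent values; default `"-"`.
#' @return Invisibly, `path`.
#' @export
write_normalized_rows <- function(rows, path, missing_token = "-") {
  cols <- normalized_columns()
  if (nrow(rows) == 0L) {
    rows <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                   cols), stringsAsFactors = FALSE)
  }
  stopifnot(all(cols %in% names(rows)))
  rows <- rows[, cols, drop = FALSE]
  for (cn in cols) {
    v <- as.character(rows[[cn]])
    v[is.na(v) | v == "" | v == "-"] <- missing_token
    rows[[cn]] <- v
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "")
  invisible(path)
}

#' @importFrom stats setNames
NULL
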