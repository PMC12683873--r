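position_labels <- c("Pos_Pri", "Pos_Sub", "Pos_SCP")

#' Position paths of a state or single symptom
#'
#' Starting from a `State` or `Symp_S` root, recursively follows
#' relations whose subject is the current node and whose object is a
#' position entity (`Pos_Pri`, `Pos_Sub`, `Pos_SCP`), recording the
#' label and surface of each node visited. A node with several
#' outgoing position relations is a branch point: each branch yields
#' its own (maximal) path, and each path later becomes its own output
#' row. A visited set breaks reference cycles. A root with no position
#' relations yields one empty path.
#'
#' @param doc A `tcm_document`.
#' @param root A `State` or `Symp_S` entity row (or id).
#' @return List of paths; each path is a data frame with columns
#'   `label` and `text` (zero rows for the empty path).
#' @export
position_paths <- function(doc, root) {
  if (!is.data.frame(root)) root <- entity_by_id(doc, root)
  if (!(root$label %in% c("State", "Symp_S"))) {
    stop("position_paths: root is not a State or Symp_S")
  }
  r <- doc$relations
  ents <- doc$entities
  children <- function(id) {
    obj <- r$object_id[r$subject_id == id]
    obj[ents$label[match(obj, ents$id)] %in% position_labels]
  }
  paths <- list()
  walk <- function(id, path, visited) {
    kids <- setdiff(children(id), visited)
    if (length(kids) == 0L) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (k in kids) {
      ki <- match(k, ents$id)
      step <- data.frame(label = ents$label[ki], text = ents$text[ki],
                         stringsAsFactors = FALSE)
      walk(k, rbind(path, step), c(visited, k))
    }
  }
  walk(root$id, data.frame(label = character(0), text = character(0),
                           stringsAsFactors = FALSE), root$id)
  paths
}

attribute_relation_types <- c("STi", "SN", "SC", "SF", "SQual", "SQuant",
                              "STr")

#' Attribute map of a state or single symptom
#'
#' Collects the object surfaces of all attribute relations (`STi`,
#' `SN`, `SC`, `SF`, `SQual`, `SQuant`, `STr`) whose subject is the
#' root; several values of the same type are joined with `";"` in
#' document order.
#'
#' @param doc A `tcm_document`.
#' @param root A `State` or `Symp_S` entity row (or id).
#' @return Named character vector (possibly empty), names drawn from
#'   the attribute relation types.
#' @export
attribute_map <- function(doc, root) {
  if (!is.data.frame(root)) root <- entity_by_id(doc, root)
  if (!(root$label %in% c("State", "Symp_S"))) {
    stop("attribute_map: root is not a State or Symp_S")
  }
  r <- doc$relations
  r <- r[r$subject_id == root$id & r$type %in% attribute_relation_types, ,
         drop = FALSE]
  if (nrow(r) == 0L) return(setNames(character(0), character(0)))
  oi <- match(r$object_id, doc$entities$id)
  r$obj_start <- doc$entities$start[oi]
  r$obj_text <- doc$entities$text[oi]
  r <- r[order(r$obj_start), , drop = FALSE]
  vapply(split(r$obj_text, factor(r$type, levels = unique(r$type))),
         paste, character(1), collapse = ";")[unique(r$type)]
}

attr_column_map <- c(STi = "time", SN = "negation", SC = "condition",
                     SF = "frequency", SQual = "severity_qualitative",
                     SQuant = "severity_quantitative", STr = "trend")

path_column_map <- c(Pos_SCP = "position_scope", Pos_Pri = "position_primary",
                     Pos_Sub = "position_subordinate")

#' Normalize a document into standardized symptom rows
#'
#' Combines position paths and attribute maps into the fixed-column
#' normalized table: one row per (root x position path), where roots
#' are the document's `State` and `Symp_S` entities in document order.
#' Path elements fill the scope/primary/subordinate columns (several
#' elements of the same column within one path are joined with `";"`);
#' the attribute map fills the remaining columns; absent values hold
#' `"-"`. A compound record such as a pulse described as stringy,
#' thready and weak therefore splits into one row per single state,
#' each repeating the shared position.
#'
#' @param doc A valid `tcm_document`, typically after
#'   [extract_relations()] or manual annotation.
#' @return Data frame with the [normalized_columns()] columns.
#' @export
normalize_document <- function(doc) {
  stopifnot(inherits(doc, "tcm_document"))
  e <- sorted_entities(doc)
  roots <- e[e$label %in% c("State", "Symp_S"), , drop = FALSE]
  cols <- normalized_columns()
  rows <- list()
  for (i in seq_len(nrow(roots))) {
    root <- roots[i, , drop = FALSE]
    amap <- attribute_map(doc, root)
    for (path in position_paths(doc, root)) {
      row <- setNames(as.list(rep("-", length(cols))), cols)
      row$doc_id <- doc$doc_id
      row$state_or_symptom <- root$text
      if (nrow(path)) {
        by_col <- split(path$text, factor(path_column_map[path$label],
                                          levels = unname(path_column_map)))
        for (cn in names(by_col)) {
          if (length(by_col[[cn]])) row[[cn]] <- paste(by_col[[cn]],
                                                       collapse = ";")
        }
      }
      for (tp in names(amap)) row[[attr_column_map[[tp]]]] <- amap[[tp]]
      rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                 stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize a corpus
#'
#' Row-binds [normalize_document()] over a list of documents.
#'
#' @param docs List of `tcm_document` objects.
#' @return Data frame with the [normalized_columns()] columns.
#' @export
normalize_corpus <- function(docs) {
  out <- do.call(rbind, lapply(docs, normalize_document))
  if (is.null(out)) out <- normalize_document(
    annotated_document("empty", " "))
  rownames(out) <- NULL
  out
}
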