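#' Rule-engine configuration
#'
#' Controls the scope bounds of the five extraction rules. The defaults
#' follow the rule statements: the Rule 1 leftward scan crosses clause
#' commas (a shared primary position may be written once for several
#' states) but stops at the sentence boundary; the Rule 2 rightward
#' scan stops at the clause boundary; subordinate-to-primary chaining
#' is off because the printed rules never emit `SPri` with a `Pos_Sub`
#' subject, even though manual annotation does.
#'
#' @param segmentation A [segmentation_config()].
#' @param bound_rule1_left_scan_at_sentence Stop Rule 1's leftward scan
#'   (and neighbour lookup) at the sentence boundary?
#' @param rule2_stop_at_clause Stop Rule 2's rightward scan at the
#'   clause boundary?
#' @param chain_subordinate_to_primary Additionally link each `Pos_Sub`
#'   that serves as an `SSub` object to its nearest `Pos_Pri` via
#'   `SPri`?
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(segmentation = segmentation_config(),
                        bound_rule1_left_scan_at_sentence = TRUE,
                        rule2_stop_at_clause = TRUE,
                        chain_subordinate_to_primary = FALSE) {
  stopifnot(inherits(segmentation, "segmentation_config"),
            is.logical(bound_rule1_left_scan_at_sentence),
            is.logical(rule2_stop_at_clause),
            is.logical(chain_subordinate_to_primary))
  structure(list(segmentation = segmentation,
                 bound_rule1_left_scan_at_sentence =
                   isTRUE(bound_rule1_left_scan_at_sentence),
                 rule2_stop_at_clause = isTRUE(rule2_stop_at_clause),
                 chain_subordinate_to_primary =
                   isTRUE(chain_subordinate_to_primary)),
            class = "rule_config")
}

# index (in a spans data frame) of the span containing offset pos, or NA
span_index_at <- function(spans, pos) {
  hit <- which(spans$start <= pos & pos < spans$end)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# relation rows without ids (assigned by extract_relations)
rel_row <- function(subject_id, object_id, type) {
  data.frame(subject_id = as.integer(subject_id),
             object_id = as.integer(object_id),
             type = type, stringsAsFactors = FALSE)
}

no_rel <- function() rel_row(integer(0), integer(0), character(0))

entity_by_id <- function(doc, id) {
  doc$entities[match(id, doc$entities$id), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared geometry for the rule scans: entities in (start, end) order,
# the sentence/clause index of each, and clause-delimiter positions;
# computed once per document in extract_relations
rule_context <- function(doc, cfg) {
  e <- sorted_entities(doc)
  sent <- sentence_spans(doc$text, cfg$segmentation)
  cla <- clause_spans(doc$text, cfg$segmentation)
  chars <- strsplit(doc$text, "")[[1]]
  list(entities = e,
       n = nchar(doc$text),
       sentence = vapply(e$start, function(p) span_index_at(sent, p),
                         integer(1)),
       clause = vapply(e$start, function(p) span_index_at(cla, p),
                       integer(1)),
       delim_pos = which(chars %in% cfg$segmentation$clause_delims) - 1L)
}

#' Neighbouring entities of an entity
#'
#' The left and right neighbours of `e` in `(start, end)` span order.
#' When the rule configuration bounds scans at sentence boundaries, a
#' neighbour lying in a different sentence is reported as absent.
#'
#' @param doc A `tcm_document`.
#' @param e One row of `doc$entities` (or an entity id).
#' @param cfg A [rule_config()].
#' @return List with elements `left` and `right`, each a one-row entity
#'   data frame or `NULL`.
#' @export
neighbor_entities <- function(doc, e, cfg = rule_config(), .ctx = NULL) {
  if (!is.data.frame(e)) e <- entity_by_id(doc, e)
  ctx <- .ctx %||% rule_context(doc, cfg)
  i <- match(e$id, ctx$entities$id)
  stopifnot(!is.na(i))
  pick <- function(j) {
    if (j < 1L || j > nrow(ctx$entities)) return(NULL)
    if (cfg$bound_rule1_left_scan_at_sentence &&
        !identical(ctx$sentence[j], ctx$sentence[i])) return(NULL)
    ctx$entities[j, , drop = FALSE]
  }
  list(left = pick(i - 1L), right = pick(i + 1L))
}

#' Rule 1: attach a state to its position
#'
#' For a `State` entity, inspect its left and right neighbours: if both
#' are `Pos_Pri`, relate to the left one (`SPri`); if only the right
#' neighbour is `Pos_Pri`, relate to it; otherwise scan leftward -
#' crossing clause commas but, by default, not the sentence start - for
#' the first position entity, emitting `SPri`, `SSub` or `SSCP`
#' according to its type. At most one relation results.
#'
#' @param doc A `tcm_document`.
#' @param state A `State` entity row (or id).
#' @param cfg A [rule_config()].
#' @return Zero- or one-row relation data frame (`subject_id`,
#'   `object_id`, `type`).
#' @export
rule1_position_for_state <- function(doc, state, cfg = rule_config(),
                                     .ctx = NULL) {
  if (!is.data.frame(state)) state <- entity_by_id(doc, state)
  if (!identical(state$label, "State")) {
    stop("rule1_position_for_state: entity is not a State")
  }
  ctx <- .ctx %||% rule_context(doc, cfg)
  nb <- neighbor_entities(doc, state, cfg, .ctx = ctx)
  left_pri <- !is.null(nb$left) && nb$left$label == "Pos_Pri"
  right_pri <- !is.null(nb$right) && nb$right$label == "Pos_Pri"
  if (left_pri && right_pri) {
    return(rel_row(state$id, nb$left$id, "SPri"))
  }
  if (right_pri && !left_pri) {
    return(rel_row(state$id, nb$right$id, "SPri"))
  }
  i <- match(state$id, ctx$entities$id)
  for (j in rev(seq_len(i - 1L))) {
    if (cfg$bound_rule1_left_scan_at_sentence &&
        !identical(ctx$sentence[j], ctx$sentence[i])) break
    lab <- ctx$entities$label[j]
    type <- switch(lab, Pos_Pri = "SPri", Pos_Sub = "SSub", Pos_SCP = "SSCP",
                   NULL)
    if (!is.null(type)) {
      return(rel_row(state$id, ctx$entities$id[j], type))
    }
  }
  no_rel()
}

#' Rule 2: attach a scope qualifier to its position head
#'
#' For a `Pos_SCP` entity, scan rightward - skipping entities that are
#' neither `Pos_Pri` nor `Pos_Sub` (stacked scopes therefore share one
#' head) and, by default, stopping at the clause boundary - for the
#' first `Pos_Pri` or `Pos_Sub`, which becomes the subject of an `SSCP`
#' relation with the scope as object.
#'
#' @param doc A `tcm_document`.
#' @param scope A `Pos_SCP` entity row (or id).
#' @param cfg A [rule_config()].
#' @return Zero- or one-row relation data frame.
#' @export
rule2_scope_attachment <- function(doc, scope, cfg = rule_config(),
                                   .ctx = NULL) {
  if (!is.data.frame(scope)) scope <- entity_by_id(doc, scope)
  if (!identical(scope$label, "Pos_SCP")) {
    stop("rule2_scope_attachment: entity is not a Pos_SCP")
  }
  ctx <- .ctx %||% rule_context(doc, cfg)
  i <- match(scope$id, ctx$entities$id)
  js <- seq_len(nrow(ctx$entities))
  js <- js[js > i]
  for (j in js) {
    if (cfg$rule2_stop_at_clause &&
        !identical(ctx$clause[j], ctx$clause[i])) break
    if (ctx$entities$label[j] %in% c("Pos_Pri", "Pos_Sub")) {
      return(rel_row(ctx$entities$id[j], scope$id, "SSCP"))
    }
  }
  no_rel()
}

#' Rule 3: negation scope
#'
#' Every `State` or `Symp_S` strictly to the right of a `Neg` entity
#' and before the next clause delimiter is negated by it (`SN`,
#' negation as object). The enumeration mark does not stop the scan.
#'
#' @param doc A `tcm_document`.
#' @param neg A `Neg` entity row (or id).
#' @param cfg A [rule_config()].
#' @return Relation data frame, one row per negated state.
#' @export
rule3_negation_scope <- function(doc, neg, cfg = rule_config(),
                                .ctx = NULL) {
  if (!is.data.frame(neg)) neg <- entity_by_id(doc, neg)
  if (!identical(neg$label, "Neg")) {
    stop("rule3_negation_scope: entity is not a Neg")
  }
  ctx <- .ctx %||% rule_context(doc, cfg)
  after <- ctx$delim_pos[ctx$delim_pos >= neg$end]
  stop_at <- if (length(after)) min(after) else ctx$n
  e <- ctx$entities
  hit <- e$label %in% c("State", "Symp_S") & e$start >= neg$end &
    e$start < stop_at
  rel_row(e$id[hit], rep(neg$id, sum(hit)), rep("SN", sum(hit)))
}

#' Rule 4: time scope
#'
#' A `Time` entity governs every `State` or `Symp_S` from its end up to
#' the start of the next `Time` entity (or the document end), crossing
#' clause and sentence boundaries; each governed state yields an `STi`
#' relation with the time as object. States before the first time
#' expression receive no time.
#'
#' @param doc A `tcm_document`.
#' @param time A `Time` entity row (or id).
#' @param cfg A [rule_config()].
#' @return Relation data frame, one row per governed state.
#' @export
rule4_time_scope <- function(doc, time, cfg = rule_config(),
                             .ctx = NULL) {
  if (!is.data.frame(time)) time <- entity_by_id(doc, time)
  if (!identical(time$label, "Time")) {
    stop("rule4_time_scope: entity is not a Time")
  }
  ctx <- .ctx %||% rule_context(doc, cfg)
  e <- ctx$entities
  later_times <- e$start[e$label == "Time" & e$start >= time$end]
  stop_at <- if (length(later_times)) min(later_times) else ctx$n
  hit <- e$label %in% c("State", "Symp_S") & e$start >= time$end &
    e$start < stop_at
  rel_row(e$id[hit], rep(time$id, sum(hit)), rep("STi", sum(hit)))
}

rule5_type_map <- c(Cond = "SC", Trend = "STr", Freq = "SF",
                    Sev_Qual = "SQual", Sev_Quant = "SQuant")

#' Rule 5: clause-local attributes
#'
#' A `Cond`, `Trend`, `Freq`, `Sev_Qual` or `Sev_Quant` entity relates
#' to every `State` or `Symp_S` inside the same clause, producing `SC`,
#' `STr`, `SF`, `SQual` or `SQuant` relations with the attribute as
#' object.
#'
#' @param doc A `tcm_document`.
#' @param attr An attribute entity row (or id).
#' @param cfg A [rule_config()].
#' @return Relation data frame, one row per co-clausal state.
#' @export
rule5_clause_attributes <- function(doc, attr, cfg = rule_config(),
                                    .ctx = NULL) {
  if (!is.data.frame(attr)) attr <- entity_by_id(doc, attr)
  if (!(attr$label %in% names(rule5_type_map))) {
    stop("rule5_clause_attributes: entity is not an attribute type")
  }
  ctx <- .ctx %||% rule_context(doc, cfg)
  e <- ctx$entities
  ci <- ctx$clause[match(attr$id, e$id)]
  hit <- e$label %in% c("State", "Symp_S") & !is.na(ctx$clause) &
    ctx$clause == ci
  type <- rule5_type_map[[attr$label]]
  rel_row(e$id[hit], rep(attr$id, sum(hit)), rep(type, sum(hit)))
}

#' Extract relations from an annotated document's entities
#'
#' Applies the five extraction rules to every eligible entity and
#' returns a copy of the document whose relations are the de-duplicated
#' union of the rule outputs. Pre-existing relations are replaced, not
#' merged. With `chain_subordinate_to_primary`, each `Pos_Sub` serving
#' as an `SSub` object is additionally linked by `SPri` to the nearest
#' `Pos_Pri` to its left within the sentence (falling back to the
#' nearest to the right).
#'
#' @param doc A `tcm_document` (its entities are used; its relations
#'   are ignored).
#' @param cfg A [rule_config()].
#' @return A `tcm_document` with predicted relations.
#' @export
#' @examples
#' d <- annotated_document("d2", "脉弦细弱。", data.frame(
#'   id = 0:3, label = c("Pos_Pri", "State", "State", "State"),
#'   start = 0:3, end = 1:4))
#' extract_relations(d)$relations
extract_relations <- function(doc, cfg = rule_config()) {
  stopifnot(inherits(doc, "tcm_document"))
  ctx <- rule_context(doc, cfg)
  e <- ctx$entities
  out <- list(no_rel())
  for (i in seq_len(nrow(e))) {
    row <- e[i, , drop = FALSE]
    out[[length(out) + 1L]] <- switch(
      row$label,
      State = rule1_position_for_state(doc, row, cfg, .ctx = ctx),
      Pos_SCP = rule2_scope_attachment(doc, row, cfg, .ctx = ctx),
      Neg = rule3_negation_scope(doc, row, cfg, .ctx = ctx),
      Time = rule4_time_scope(doc, row, cfg, .ctx = ctx),
      Cond = , Trend = , Freq = , Sev_Qual = , Sev_Quant =
        rule5_clause_attributes(doc, row, cfg, .ctx = ctx),
      no_rel())
  }
  rel <- do.call(rbind, out)
  if (cfg$chain_subordinate_to_primary && nrow(rel)) {
    subs <- unique(rel$object_id[rel$type == "SSub"])
    for (sid in subs) {
      i <- match(sid, ctx$entities$id)
      same_sent <- which(ctx$sentence == ctx$sentence[i] &
                           ctx$entities$label == "Pos_Pri")
      left <- same_sent[same_sent < i]
      right <- same_sent[same_sent > i]
      j <- if (length(left)) max(left) else if (length(right)) min(right)
        else NA_integer_
      if (!is.na(j)) {
        rel <- rbind(rel, rel_row(sid, ctx$entities$id[j], "SPri"))
      }
    }
  }
  rel <- rel[!duplicated(rel[, c("subject_id", "object_id", "type")]), ,
             drop = FALSE]
  rel <- rel[order(rel$subject_id, rel$object_id, rel$type), , drop = FALSE]
  rel <- data.frame(id = seq_len(nrow(rel)) - 1L, rel,
                    stringsAsFactors = FALSE)
  rownames(rel) <- NULL
  annotated_document(doc$doc_id, doc$text, doc$entities, rel)
}
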