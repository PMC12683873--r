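# Hand-built worked examples used across the suite.
#
# d1: a two-state narrative with onset time, scope, shared primary
#     position and a negated second state.
#     "6年前双下肢疼痛，无肿胀。"
#     offsets: 6年前[0,3) 双[3,4) 下肢[4,6) 疼痛[6,8) ，[8] 无[9,10)
#              肿胀[10,12) 。[12]
d1_document <- function(with_gold = FALSE) {
  ents <- data.frame(
    id = 0:5,
    label = c("Time", "Pos_SCP", "Pos_Pri", "State", "Neg", "State"),
    start = c(0L, 3L, 4L, 6L, 9L, 10L),
    end = c(3L, 4L, 6L, 8L, 10L, 12L),
    stringsAsFactors = FALSE)
  rels <- if (with_gold) {
    data.frame(id = 0:5,
               subject_id = c(2L, 3L, 3L, 5L, 5L, 5L),
               object_id = c(1L, 0L, 2L, 0L, 2L, 4L),
               type = c("SSCP", "STi", "SPri", "STi", "SPri", "SN"),
               stringsAsFactors = FALSE)
  } else {
    NULL
  }
  if (is.null(rels)) annotated_document("d1", "6年前双下肢疼痛，无肿胀。", ents)
  else annotated_document("d1", "6年前双下肢疼痛，无肿胀。", ents, rels)
}

# d2: the compound pulse record "脉弦细弱。" -- one primary position
# (the pulse) shared by three single-character states.
d2_document <- function(with_gold = FALSE) {
  ents <- data.frame(
    id = 0:3,
    label = c("Pos_Pri", "State", "State", "State"),
    start = 0:3, end = 1:4, stringsAsFactors = FALSE)
  rels <- if (with_gold) {
    data.frame(id = 0:2, subject_id = 1:3, object_id = 0L,
               type = "SPri", stringsAsFactors = FALSE)
  } else NULL
  if (is.null(rels)) annotated_document("d2", "脉弦细弱。", ents)
  else annotated_document("d2", "脉弦细弱。", ents, rels)
}

# d3: maximize-coverage example "左手小指疼痛。" -- the progressive
# position is annotated whole, the scope qualifier attaches to it.
d3_document <- function() {
  annotated_document("d3", "左手小指疼痛。", data.frame(
    id = 0:2, label = c("Pos_SCP", "Pos_Pri", "State"),
    start = c(0L, 1L, 4L), end = c(1L, 4L, 6L), stringsAsFactors = FALSE))
}

# independent brute-force P/R/F1 over explicit key sets: nested loops
# and exact tuple comparison, no set machinery shared with the package
oracle_prf_keys <- function(gold_keys, pred_keys) {
  n_match <- 0L
  for (g in gold_keys) {
    for (p in pred_keys) {
      if (identical(g, p)) {
        n_match <- n_match + 1L
        break
      }
    }
  }
  p <- if (length(pred_keys)) n_match / length(pred_keys) else 0
  r <- if (length(gold_keys)) n_match / length(gold_keys) else 0
  list(precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

entity_triples <- function(doc) {
  e <- doc$entities
  lapply(seq_len(nrow(e)), function(i)
    list(doc$doc_id, e$start[i], e$end[i], e$label[i]))
}

# random sub-annotation of a document: keep each entity independently
subsample_entities <- function(doc, keep_prob) {
  e <- doc$entities
  keep <- stats::runif(nrow(e)) < keep_prob
  annotated_document(doc$doc_id, doc$text, e[keep, , drop = FALSE])
}
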