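test_that("neighbour lookup respects span order and sentence bounds", {
  d1 <- d1_document()
  pain <- d1$entities[d1$entities$text == "疼痛", ]
  nb <- neighbor_entities(d1, pain)
  expect_equal(nb$left$text, "下肢")
  expect_equal(nb$right$text, "无")  # comma does not hide the neighbour

  d2 <- d2_document()
  xian <- d2$entities[d2$entities$text == "弦", ]
  nb <- neighbor_entities(d2, xian)
  expect_equal(nb$left$text, "脉")
  expect_equal(nb$right$text, "细")

  single <- annotated_document("s", "头晕。", data.frame(
    id = 0L, label = "Symp_S", start = 0L, end = 2L))
  nb <- neighbor_entities(single, 0L)
  expect_null(nb$left)
  expect_null(nb$right)

  # a neighbour beyond the sentence boundary is reported absent
  two <- annotated_document("t", "口干。头晕。", data.frame(
    id = 0:2, label = c("Pos_Pri", "State", "Symp_S"),
    start = c(0L, 1L, 3L), end = c(1L, 2L, 5L)))
  nb <- neighbor_entities(two, 1L)
  expect_null(nb$right)
})

test_that("rule 1 resolves the three neighbour cases", {
  d1 <- d1_document()
  pain <- d1$entities[d1$entities$text == "疼痛", ]
  r <- rule1_position_for_state(d1, pain)
  expect_equal(r$type, "SPri")
  expect_equal(r$object_id, 2L)  # 下肢

  # all three pulse states scan left to the shared primary
  d2 <- d2_document()
  for (id in 1:3) {
    r <- rule1_position_for_state(d2, id)
    expect_equal(r$type, "SPri")
    expect_equal(r$object_id, 0L)
  }

  # both neighbours primary: the left one wins
  both <- annotated_document("b", "口干脉。", data.frame(
    id = 0:2, label = c("Pos_Pri", "State", "Pos_Pri"),
    start = 0:2, end = 1:3))
  r <- rule1_position_for_state(both, 1L)
  expect_equal(r$object_id, 0L)

  # only the right neighbour primary
  right <- annotated_document("r", "干脉。", data.frame(
    id = 0:1, label = c("State", "Pos_Pri"), start = 0:1, end = 1:2))
  r <- rule1_position_for_state(right, 0L)
  expect_equal(r$object_id, 1L)

  # subordinate found first on the leftward scan
  sub <- annotated_document("s", "痰质稠。", data.frame(
    id = 0:2, label = c("Pos_Pri", "Pos_Sub", "State"),
    start = 0:2, end = 1:3))
  r <- rule1_position_for_state(sub, 2L)
  expect_equal(r$type, "SSub")
  expect_equal(r$object_id, 1L)

  expect_error(rule1_position_for_state(d1, 0L), "not a State")
})

test_that("rule 2 attaches scopes rightward to the first position head", {
  d1 <- d1_document()
  r <- rule2_scope_attachment(d1, 1L)  # 双
  expect_equal(r$subject_id, 2L)       # 下肢
  expect_equal(r$type, "SSCP")

  d3 <- d3_document()
  r <- rule2_scope_attachment(d3, 0L)  # 左
  expect_equal(r$subject_id, 1L)       # 手小指

  # stacked scopes each attach to the same head
  st <- annotated_document("st", "左右下肢疼痛。", data.frame(
    id = 0:3, label = c("Pos_SCP", "Pos_SCP", "Pos_Pri", "State"),
    start = c(0L, 1L, 2L, 4L), end = c(1L, 2L, 4L, 6L)))
  r0 <- rule2_scope_attachment(st, 0L)
  r1 <- rule2_scope_attachment(st, 1L)
  expect_equal(r0$subject_id, 2L)
  expect_equal(r1$subject_id, 2L)

  # clause boundary stops the scan
  cb <- annotated_document("cb", "左，下肢疼痛。", data.frame(
    id = 0:2, label = c("Pos_SCP", "Pos_Pri", "State"),
    start = c(0L, 2L, 4L), end = c(1L, 4L, 6L)))
  expect_equal(nrow(rule2_scope_attachment(cb, 0L)), 0L)
})

test_that("rule 3 negates states up to the next clause delimiter", {
  d1 <- d1_document()
  r <- rule3_negation_scope(d1, 4L)  # 无
  expect_equal(r$subject_id, 5L)     # 肿胀 only
  expect_equal(r$type, "SN")

  # enumeration mark does not stop the scan
  en <- annotated_document("en", "无头晕、心悸，乏力。", data.frame(
    id = 0:3, label = c("Neg", "Symp_S", "Symp_S", "Symp_S"),
    start = c(0L, 1L, 4L, 7L), end = c(1L, 3L, 6L, 9L)))
  r <- rule3_negation_scope(en, 0L)
  expect_equal(sort(r$subject_id), c(1L, 2L))  # 乏力 is past the comma

  # negation immediately before a delimiter has empty scope
  em <- annotated_document("em", "无，头晕。", data.frame(
    id = 0:1, label = c("Neg", "Symp_S"), start = c(0L, 2L),
    end = c(1L, 4L)))
  expect_equal(nrow(rule3_negation_scope(em, 0L)), 0L)
})

test_that("rule 4 partitions states between consecutive time expressions", {
  d1 <- d1_document()
  r <- rule4_time_scope(d1, 0L)
  expect_equal(sort(r$subject_id), c(3L, 5L))
  expect_true(all(r$type == "STi"))

  two <- annotated_document("tw", "3天前头晕。昨日乏力，心悸。", data.frame(
    id = 0:4, label = c("Time", "Symp_S", "Time", "Symp_S", "Symp_S"),
    start = c(0L, 3L, 6L, 8L, 11L), end = c(3L, 5L, 8L, 10L, 13L)))
  r1 <- rule4_time_scope(two, 0L)
  r2 <- rule4_time_scope(two, 2L)
  expect_equal(r1$subject_id, 1L)
  expect_equal(sort(r2$subject_id), c(3L, 4L))

  # states before the first time get nothing from it
  pre <- annotated_document("pr", "头晕。昨日乏力。", data.frame(
    id = 0:2, label = c("Symp_S", "Time", "Symp_S"),
    start = c(0L, 3L, 5L), end = c(2L, 5L, 7L)))
  r <- rule4_time_scope(pre, 1L)
  expect_equal(r$subject_id, 2L)
})

test_that("rule 5 links clause attributes to every co-clausal state", {
  cond <- annotated_document("c", "活动时疼痛。", data.frame(
    id = 0:1, label = c("Cond", "State"), start = c(0L, 3L),
    end = c(3L, 5L)))
  r <- rule5_clause_attributes(cond, 0L)
  expect_equal(r$type, "SC")
  expect_equal(r$subject_id, 1L)

  # a trend between two states covers both
  tr <- annotated_document("t", "头晕加重乏力。", data.frame(
    id = 0:2, label = c("Symp_S", "Trend", "Symp_S"),
    start = c(0L, 2L, 4L), end = c(2L, 4L, 6L)))
  r <- rule5_clause_attributes(tr, 1L)
  expect_equal(sort(r$subject_id), c(0L, 2L))
  expect_true(all(r$type == "STr"))

  # attribute alone in its clause yields nothing
  alone <- annotated_document("a", "加重，头晕。", data.frame(
    id = 0:1, label = c("Trend", "Symp_S"), start = c(0L, 3L),
    end = c(2L, 5L)))
  expect_equal(nrow(rule5_clause_attributes(alone, 0L)), 0L)
})

test_that("the full rule engine reproduces the worked fixtures", {
  ed1 <- extract_relations(d1_document())
  expect_equal(nrow(ed1$relations), 6L)
  expect_equal(sort(table(ed1$relations$type), decreasing = TRUE),
               sort(table(c("SPri", "SPri", "SSCP", "SN", "STi", "STi")),
                    decreasing = TRUE))
  expect_equal(nrow(validate_document(ed1)), 0L)

  ed2 <- extract_relations(d2_document())
  expect_equal(nrow(ed2$relations), 3L)
  expect_true(all(ed2$relations$type == "SPri"))
  expect_true(all(ed2$relations$object_id == 0L))

  none <- annotated_document("n", "昨日。", data.frame(
    id = 0L, label = "Time", start = 0L, end = 2L))
  expect_equal(nrow(extract_relations(none)$relations), 0L)
})

test_that("extraction is invariant to entity input order", {
  docs <- generate_corpus(synth_config(seed = 31, n_docs = 15))
  for (doc in docs) {
    perm <- annotated_document(
      doc$doc_id, doc$text,
      doc$entities[rev(seq_len(nrow(doc$entities))), , drop = FALSE])
    a <- extract_relations(doc)$relations
    b <- extract_relations(perm)$relations
    expect_identical(a[, c("subject_id", "object_id", "type")],
                     b[, c("subject_id", "object_id", "type")])
  }
})

test_that("each state and scope yields at most one rule-1/rule-2 relation", {
  docs <- generate_corpus(synth_config(seed = 77, n_docs = 25,
                                       adversarial_rate = 0.4))
  for (doc in docs) {
    rel <- extract_relations(doc)$relations
    r1 <- rel[rel$type %in% c("SPri", "SSub", "SSCP"), ]
    # per State subject at most one rule-1 position relation
    states <- doc$entities$id[doc$entities$label == "State"]
    counts <- table(r1$subject_id[r1$subject_id %in% states &
                                    r1$type != "SSCP"])
    expect_true(all(counts <= 1L))
    scopes <- doc$entities$id[doc$entities$label == "Pos_SCP"]
    counts2 <- table(r1$object_id[r1$object_id %in% scopes])
    expect_true(all(counts2 <= 1L))
  }
})

test_that("every extracted relation satisfies the constraint matrix", {
  docs <- generate_corpus(synth_config(seed = 13, n_docs = 25,
                                       adversarial_rate = 0.3))
  for (doc in docs) {
    expect_equal(nrow(validate_document(extract_relations(doc),
                                        warnings = FALSE)), 0L)
  }
})

test_that("subordinate chaining adds SPri links from Pos_Sub when enabled", {
  doc <- annotated_document("ch", "痰质稠。", data.frame(
    id = 0:2, label = c("Pos_Pri", "Pos_Sub", "State"),
    start = 0:2, end = 1:3))
  plain <- extract_relations(doc)$relations
  expect_false(any(plain$type == "SPri"))
  chained <- extract_relations(
    doc, rule_config(chain_subordinate_to_primary = TRUE))$relations
  expect_true(any(chained$type == "SPri" & chained$subject_id == 1L &
                    chained$object_id == 0L))
})
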