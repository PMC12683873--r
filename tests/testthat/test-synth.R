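test_that("generation is fully deterministic under a fixed seed", {
  cfg <- synth_config(seed = 99, n_docs = 30)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_annotations(a, f1)
  write_annotations(b, f2)
  expect_identical(readLines(f1, warn = FALSE), readLines(f2, warn = FALSE))
  expect_identical(generate_document(cfg, 7)[], generate_document(cfg, 7)[])
})

test_that("every generated document passes validation", {
  docs <- generate_corpus(synth_config(seed = 2, n_docs = 40))
  for (doc in docs) {
    expect_equal(nrow(validate_document(doc, warnings = FALSE)), 0L)
  }
})

test_that("the minimal grammar yields one primary, one state, one SPri", {
  cfg <- synth_config(seed = 7, n_docs = 1,
                      sentences_per_doc = c(1L, 1L),
                      clauses_per_sentence = c(1L, 1L),
                      p_time = 0, p_neg = 0, p_scope = 0, p_sub = 0,
                      symp_s_probability = 0,
                      p_attr = c(Cond = 0, Freq = 0, Sev_Qual = 0,
                                 Sev_Quant = 0, Trend = 0))
  doc <- generate_document(cfg, 1)
  expect_equal(doc$entities$label, c("Pos_Pri", "State"))
  expect_equal(substr(doc$text, nchar(doc$text), nchar(doc$text)), "。")
  expect_equal(doc$relations$type, "SPri")
})

test_that("clean-mode extraction reproduces construction gold exactly", {
  docs <- generate_corpus(synth_config(seed = 12, n_docs = 150))
  pred <- lapply(docs, extract_relations)
  s <- strict_relation_prf(docs, pred)
  expect_equal(c(s$precision, s$recall, s$f1), c(1, 1, 1))
})

test_that("clean synthetic documents normalize to one row per root plus scope branches", {
  # the only branch points a clean construction can produce are primary
  # positions carrying several stacked scope qualifiers: each extra
  # scope forks one extra path, hence one extra row
  docs <- generate_corpus(synth_config(seed = 44, n_docs = 25))
  saw_branch <- FALSE
  for (doc in docs) {
    n_roots <- sum(doc$entities$label %in% c("State", "Symp_S"))
    rel <- doc$relations
    extra <- 0L
    for (p in unique(rel$object_id[rel$type == "SPri"])) {
      k <- sum(rel$type == "SSCP" & rel$subject_id == p)
      extra <- extra + max(0L, k - 1L)
    }
    saw_branch <- saw_branch || extra > 0L
    expect_equal(nrow(normalize_document(doc)), n_roots + extra)
  }
  expect_true(saw_branch)  # the sample exercises the branching case
})

test_that("the corpus histogram covers the entity types actually emitted", {
  docs <- generate_corpus(synth_config(seed = 8, n_docs = 50))
  h <- attr(docs, "histogram")
  expect_named(h, entity_types(), ignore.order = TRUE)
  expect_equal(sum(h), sum(vapply(docs, function(d) nrow(d$entities),
                                  integer(1))))
  expect_gt(h[["State"]], 0)
  expect_gt(h[["Pos_Pri"]], 0)
})

test_that("n_docs = 0 gives an empty corpus and zero clauses error", {
  expect_length(generate_corpus(synth_config(seed = 1, n_docs = 0)), 0L)
  expect_error(synth_config(seed = 1, clauses_per_sentence = c(0L, 0L)))
})

test_that("adversarial injection logs perturbations and lowers recall", {
  cfg <- synth_config(seed = 5, n_docs = 120, adversarial_rate = 0.5)
  docs <- generate_corpus(cfg)
  logs <- do.call(rbind, lapply(docs, attr, "perturbations"))
  expect_gt(nrow(logs), 0L)
  expect_true(all(logs$kind %in% c("attr_shift", "state_pos_swap",
                                   "stack_time")))
  # documents remain structurally valid
  for (doc in docs[1:20]) {
    expect_equal(nrow(validate_document(doc, warnings = FALSE)), 0L)
  }
  s <- strict_relation_prf(docs, lapply(docs, extract_relations))
  expect_lt(s$recall, 1)
})

test_that("a condition shifted across the clause boundary breaks recall", {
  # gold semantics: the condition modifies the pulse state it was
  # generated with; after the shift it sits in the next clause
  gold_rel <- data.frame(id = 0L, subject_id = 1L, object_id = 2L,
                         type = "SC")
  shifted <- annotated_document("mv", "脉弦，活动时头晕。", data.frame(
    id = 0:3, label = c("Pos_Pri", "State", "Cond", "Symp_S"),
    start = c(0L, 1L, 3L, 6L), end = c(1L, 2L, 6L, 8L)),
    rbind(gold_rel,
          data.frame(id = 1L, subject_id = 1L, object_id = 0L,
                     type = "SPri")))
  pred <- extract_relations(shifted)
  s <- strict_relation_prf(list(shifted), list(pred))
  expect_lt(s$recall, 1)  # SC(弦 -> 活动时) is unreachable for rule 5
  expect_true(any(pred$relations$type == "SC" &
                    pred$relations$subject_id == 3L))
})

test_that("adversarial rate zero is the identity", {
  cfg0 <- synth_config(seed = 21, n_docs = 5, adversarial_rate = 0)
  docs <- generate_corpus(cfg0)
  d <- docs[[1]]
  out <- inject_adversarial(d, cfg0)
  core <- function(x) list(x$doc_id, x$text, x$entities, x$relations)
  expect_identical(core(out), core(d))
  expect_equal(nrow(attr(out, "perturbations")), 0L)
})

test_that("the ASCII lexicon generates valid documents too", {
  cfg <- synth_config(seed = 3, n_docs = 10, lexicon = ascii_lexicon())
  docs <- generate_corpus(cfg)
  for (doc in docs) {
    expect_equal(nrow(validate_document(doc, warnings = FALSE)), 0L)
  }
  s <- strict_relation_prf(docs, lapply(docs, extract_relations))
  expect_equal(s$f1, 1)
})

test_that("lexicon surfaces may not contain delimiters", {
  lex <- default_lexicon()
  lex$State <- c(lex$State, "疼，痛")
  expect_error(synth_config(lexicon = lex), "delimiter")
})
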