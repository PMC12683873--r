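#' Default Chinese lexicon for the generator
#'
#' Typed surface strings for every entity type, drawn from common
#' present-illness phrasing (pain, swelling, pulse qualities,
#' anatomical sites, scope qualifiers, negators, onset times,
#' conditions, frequencies, severities, trends). No surface contains a
#' clause delimiter.
#'
#' @return Named list, one character vector per entity type label.
#' @export
default_lexicon <- function() {
  list(
    State = c("疼痛", "肿胀", "弦", "细", "弱", "模糊", "干", "麻木", "酸软"),
    Pos_Pri = c("下肢", "手小指", "脉", "口", "眼", "头", "腰", "膝", "咽"),
    Pos_SCP = c("双", "左", "右", "两侧"),
    Pos_Sub = c("皮肤", "关节", "质"),
    Symp_S = c("头晕", "心悸", "恶寒", "恶心", "乏力", "咳嗽"),
    Neg = c("无", "未见", "否认"),
    Time = c("6年前", "3天前", "1月前", "2周前", "昨日"),
    Cond = c("活动时", "在下蹲或按压时", "受凉后", "夜间"),
    Freq = c("反复", "偶有", "时有"),
    Sev_Qual = c("明显", "轻度", "剧烈"),
    Sev_Quant = c("约5次", "38.5℃", "约200ml"),
    Trend = c("加重", "减轻")
  )
}

#' ASCII placeholder lexicon
#'
#' Same shape as [default_lexicon()] with ASCII surfaces, convenient
#' when debugging offset arithmetic.
#'
#' @return Named list, one character vector per entity type label.
#' @export
ascii_lexicon <- function() {
  list(
    State = c("pain", "swell", "numb", "dry"),
    Pos_Pri = c("leg", "arm", "eye", "head"),
    Pos_SCP = c("both", "left", "right"),
    Pos_Sub = c("skin", "joint"),
    Symp_S = c("dizzy", "cough", "nausea"),
    Neg = c("no", "denies"),
    Time = c("6yago", "3dago", "1mago"),
    Cond = c("onmove", "atnight"),
    Freq = c("often", "rarely"),
    Sev_Qual = c("mild", "severe"),
    Sev_Quant = c("x5", "38C"),
    Trend = c("worse", "better")
  )
}

check_lexicon <- function(lexicon, cfg_seg = segmentation_config()) {
  stopifnot(is.list(lexicon),
            length(lexicon$State) > 0L, length(lexicon$Pos_Pri) > 0L)
  for (lab in names(lexicon)) {
    for (s in lexicon[[lab]]) {
      if (any(strsplit(s, "")[[1]] %in% cfg_seg$clause_delims)) {
        stop(sprintf("lexicon surface '%s' contains a delimiter", s))
      }
    }
  }
  invisible(lexicon)
}

#' Generator configuration
#'
#' Controls the seeded generator of synthetic present-illness
#' documents. Sentences are sequences of clauses joined by the
#' full-width comma and terminated by the full-width period; each
#' clause realizes either the position+state pattern
#' `[Neg?][Pos_SCP*][Pos_Pri][Pos_Sub?][State][attr*]` or the
#' standalone-symptom pattern `[Neg?][Symp_S][attr*]`, and a sentence
#' may open with a `Time` expression governing everything until the
#' next one. Default emission probabilities roughly mirror the
#' relative per-type annotation shares observed in fine-grained TCM
#' EMR annotation (states and primary positions dominant; quantitative
#' severity rare).
#'
#' @param seed Integer seed; every document is derived
#'   deterministically from it.
#' @param n_docs Number of documents.
#' @param sentences_per_doc,clauses_per_sentence Inclusive integer
#'   ranges, length 2.
#' @param p_time Probability that a sentence opens with a `Time`.
#' @param p_neg Probability of a clause-initial negator.
#' @param p_scope Probability of each successive scope qualifier
#'   (geometric, capped at 2).
#' @param p_sub Probability of a subordinate position.
#' @param symp_s_probability Probability that a clause is a standalone
#'   symptom rather than position+state.
#' @param p_attr Named numeric vector of per-clause emission
#'   probabilities for `Cond`, `Freq`, `Sev_Qual`, `Sev_Quant`,
#'   `Trend`.
#' @param adversarial_rate Fraction of clauses perturbed by
#'   [inject_adversarial()]; 0 generates clean, rule-recoverable
#'   documents.
#' @param chain_subordinate Derive gold `SPri` links from `Pos_Sub` to
#'   its `Pos_Pri` (progressive-annotation semantics)? Off by default
#'   to match the plain rule engine.
#' @param lexicon Typed surface lists, see [default_lexicon()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_docs = 10L,
                         sentences_per_doc = c(1L, 4L),
                         clauses_per_sentence = c(1L, 4L),
                         p_time = 0.5,
                         p_neg = 0.25,
                         p_scope = 0.3,
                         p_sub = 0.15,
                         symp_s_probability = 0.2,
                         p_attr = c(Cond = 0.15, Freq = 0.12,
                                    Sev_Qual = 0.15, Sev_Quant = 0.04,
                                    Trend = 0.1),
                         adversarial_rate = 0,
                         chain_subordinate = FALSE,
                         lexicon = default_lexicon()) {
  probs <- c(p_time, p_neg, p_scope, p_sub, symp_s_probability, p_attr,
             adversarial_rate)
  stopifnot(all(probs >= 0 & probs <= 1),
            length(sentences_per_doc) == 2L,
            length(clauses_per_sentence) == 2L,
            sentences_per_doc[1] >= 1L, clauses_per_sentence[1] >= 1L,
            sentences_per_doc[1] <= sentences_per_doc[2],
            clauses_per_sentence[1] <= clauses_per_sentence[2],
            all(c("Cond", "Freq", "Sev_Qual", "Sev_Quant", "Trend") %in%
                  names(p_attr)))
  check_lexicon(lexicon)
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 clauses_per_sentence = as.integer(clauses_per_sentence),
                 p_time = p_time, p_neg = p_neg, p_scope = p_scope,
                 p_sub = p_sub, symp_s_probability = symp_s_probability,
                 p_attr = p_attr, adversarial_rate = adversarial_rate,
                 chain_subordinate = isTRUE(chain_subordinate),
                 lexicon = lexicon),
            class = "synth_config")
}

sample_int_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

pick <- function(surfaces) surfaces[[sample.int(length(surfaces), 1L)]]

# A token plan is a data frame of (label, text, role) where role marks
# the structural slot; delimiters are rendered between/after clauses.
plan_clause <- function(cfg) {
  lex <- cfg$lexicon
  tokens <- list()
  add <- function(label) {
    tokens[[length(tokens) + 1L]] <<- data.frame(
      label = label, text = pick(lex[[label]]), stringsAsFactors = FALSE)
  }
  has_neg <- stats::runif(1) < cfg$p_neg
  if (has_neg) add("Neg")
  if (stats::runif(1) < cfg$symp_s_probability &&
      length(lex$Symp_S)) {
    add("Symp_S")
    kind <- "symp"
    n_scope <- 0L; has_sub <- FALSE
  } else {
    kind <- "state"
    n_scope <- 0L
    while (n_scope < 2L && stats::runif(1) < cfg$p_scope) {
      add("Pos_SCP"); n_scope <- n_scope + 1L
    }
    add("Pos_Pri")
    has_sub <- stats::runif(1) < cfg$p_sub && length(lex$Pos_Sub) > 0L
    if (has_sub) add("Pos_Sub")
    add("State")
  }
  attrs <- names(cfg$p_attr)[stats::runif(length(cfg$p_attr)) < cfg$p_attr]
  # a subordinate-bearing clause always carries a trailing attribute so
  # the state's right-hand context stays inside its own clause and the
  # rule engine reproduces the construction's gold relations
  if (has_sub && length(attrs) == 0L) {
    attrs <- pick(names(cfg$p_attr))
  }
  for (a in attrs) if (length(cfg$lexicon[[a]])) add(a)
  plan <- do.call(rbind, tokens)
  plan$clause_kind <- kind
  plan
}

# render a full token plan (with delimiter rows label == ".delim") into
# text + entity table; non-delimiter tokens become entities in order
render_plan <- function(plan, doc_id) {
  pos <- 0L
  ids <- integer(nrow(plan))
  starts <- integer(nrow(plan))
  ends <- integer(nrow(plan))
  next_id <- 0L
  for (i in seq_len(nrow(plan))) {
    w <- nchar(plan$text[i])
    starts[i] <- pos
    ends[i] <- pos + w
    pos <- pos + w
    if (plan$label[i] != ".delim") {
      ids[i] <- next_id
      next_id <- next_id + 1L
    } else ids[i] <- NA_integer_
  }
  keep <- plan$label != ".delim"
  entities <- data.frame(id = ids[keep], label = plan$label[keep],
                         start = starts[keep], end = ends[keep],
                         text = plan$text[keep], stringsAsFactors = FALSE)
  list(text = paste(plan$text, collapse = ""), entities = entities)
}

delim_row <- function(ch) {
  data.frame(label = ".delim", text = ch, clause_kind = NA_character_,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic annotated document
#'
#' Builds a present-illness narrative from the position+state grammar
#' and attaches gold relations derived from the construction trace
#' (never by running the rule engine, which keeps the oracle test
#' non-circular): the state relates to its subordinate position if one
#' was emitted, else to its primary; every scope attaches to the
#' clause's primary; the negator covers its clause's state; each
#' attribute covers its clause's state; each time expression covers
#' every state up to the next time. With a positive
#' `adversarial_rate` the clean document is then perturbed by
#' [inject_adversarial()].
#'
#' @param cfg A [synth_config()].
#' @param doc_index 1-based document index; combined with `cfg$seed`
#'   for per-document determinism.
#' @return A `tcm_document` that passes [validate_document()].
#' @export
generate_document <- function(cfg, doc_index = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(as.integer((as.numeric(cfg$seed) * 10007 +
                         as.numeric(doc_index)) %% 2147483647))
  n_sent <- sample_int_range(cfg$sentences_per_doc)
  plan <- list()
  for (s in seq_len(n_sent)) {
    n_clause <- sample_int_range(cfg$clauses_per_sentence)
    if (stats::runif(1) < cfg$p_time) {
      plan[[length(plan) + 1L]] <- data.frame(
        label = "Time", text = pick(cfg$lexicon$Time),
        clause_kind = NA_character_, stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_clause)) {
      plan[[length(plan) + 1L]] <- plan_clause(cfg)
      if (k < n_clause) plan[[length(plan) + 1L]] <- delim_row("，")
    }
    plan[[length(plan) + 1L]] <- delim_row("。")
  }
  plan <- do.call(rbind, plan)
  if (is.null(plan) || !any(plan$label != ".delim")) {
    stop("degenerate configuration: no clauses generated")
  }
  rendered <- render_plan(plan, doc_index)
  ents <- rendered$entities
  rels <- derive_gold(ents, chain = cfg$chain_subordinate)
  doc <- annotated_document(paste0("synth-", doc_index), rendered$text,
                            ents, rels)
  if (cfg$adversarial_rate > 0) doc <- inject_adversarial(doc, cfg)
  doc
}

# gold relations from the construction trace: entities arrive in
# surface order, one clause at a time, so clause membership can be
# recovered from the entity order and labels alone (the plan emits
# Neg/scopes/positions before the clause's single state)
derive_gold <- function(ents, chain = FALSE) {
  rel <- list(no_rel())
  n <- nrow(ents)
  # clause grouping: a new clause starts at Neg, at the first scope of
  # a run, or directly at Pos_Pri/Symp_S when no prefix was emitted --
  # equivalently, whenever the previous clause already has its state.
  clause_of <- integer(n)
  cl <- 0L
  state_seen <- TRUE
  for (i in seq_len(n)) {
    lab <- ents$label[i]
    if (lab == "Time") {
      clause_of[i] <- NA_integer_
      next
    }
    starts_clause <- state_seen &&
      lab %in% c("Neg", "Pos_SCP", "Pos_Pri", "Symp_S")
    if (starts_clause) {
      cl <- cl + 1L
      state_seen <- FALSE
    }
    clause_of[i] <- cl
    if (lab %in% c("State", "Symp_S")) state_seen <- TRUE
  }
  for (c_id in unique(clause_of[!is.na(clause_of)])) {
    idx <- which(clause_of == c_id)
    labs <- ents$label[idx]
    root <- idx[labs %in% c("State", "Symp_S")][1]
    pri <- idx[labs == "Pos_Pri"]
    sub <- idx[labs == "Pos_Sub"]
    add <- function(s, o, tp) {
      rel[[length(rel) + 1L]] <<- rel_row(ents$id[s], ents$id[o], tp)
    }
    if (ents$label[root] == "State") {
      if (length(sub)) {
        add(root, sub[1], "SSub")
        if (chain && length(pri)) add(sub[1], pri[1], "SPri")
      } else if (length(pri)) {
        add(root, pri[1], "SPri")
      }
    }
    for (sc in idx[labs == "Pos_SCP"]) {
      head <- c(pri, sub)
      head <- head[head > sc]
      if (length(head)) add(min(head), sc, "SSCP")
    }
    for (ng in idx[labs == "Neg"]) add(root, ng, "SN")
    for (at in idx[labs %in% names(rule5_type_map)]) {
      add(root, at, rule5_type_map[[ents$label[at]]])
    }
  }
  # time scopes: every state/symptom after a time and before the next
  times <- which(ents$label == "Time")
  roots <- which(ents$label %in% c("State", "Symp_S"))
  for (k in seq_along(times)) {
    lo <- ents$end[times[k]]
    hi <- if (k < length(times)) ents$start[times[k + 1L]]
      else max(ents$end) + 1L
    for (rt in roots[ents$start[roots] >= lo & ents$start[roots] < hi]) {
      rel[[length(rel) + 1L]] <- rel_row(ents$id[rt], ents$id[times[k]],
                                         "STi")
    }
  }
  rel <- do.call(rbind, rel)
  rel <- rel[order(rel$subject_id, rel$object_id, rel$type), , drop = FALSE]
  rel <- data.frame(id = seq_len(nrow(rel)) - 1L, rel,
                    stringsAsFactors = FALSE)
  rownames(rel) <- NULL
  rel
}

#' Generate a synthetic corpus
#'
#' `n_docs` documents, each deterministic in `cfg$seed` and its index.
#' The corpus-level entity-type histogram is attached as the
#' `"histogram"` attribute.
#'
#' @param cfg A [synth_config()].
#' @return List of `tcm_document` objects.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  docs <- lapply(seq_len(cfg$n_docs), function(i) generate_document(cfg, i))
  labs <- unlist(lapply(docs, function(d) d$entities$label))
  hist <- table(factor(labs, levels = entity_types()))
  attr(docs, "histogram") <- hist
  docs
}

#' Inject rule-breaking perturbations into a clean document
#'
#' Stress-tests the rule engine by perturbing a clean synthetic
#' document while keeping the gold relations aligned with the intended
#' semantics, so that rule/gold divergence becomes measurable. Each
#' clause is independently perturbed with probability
#' `cfg$adversarial_rate` by one of: `attr_shift` (an attribute moves
#' into the following clause; Rule 5 then misses it), `state_pos_swap`
#' (a primary position and its state swap order; Rule 1's right-
#' neighbour case still recovers this one) or `stack_time` (a second
#' time expression is inserted directly after an existing one; Rule 4
#' then attributes the following states to the wrong time). The
#' perturbation log is attached as the `"perturbations"` attribute.
#' Uses the current RNG stream.
#'
#' @param doc A clean `tcm_document` whose relations are construction
#'   gold.
#' @param cfg A [synth_config()]; only `adversarial_rate` and
#'   `lexicon` are used.
#' @return A perturbed `tcm_document`.
#' @export
inject_adversarial <- function(doc, cfg) {
  stopifnot(inherits(doc, "tcm_document"))
  rate <- cfg$adversarial_rate
  log <- data.frame(kind = character(0), entity_id = integer(0),
                    stringsAsFactors = FALSE)
  if (rate <= 0) {
    attr(doc, "perturbations") <- log
    return(doc)
  }
  toks <- doc_tokens(doc)
  # candidates are keyed by entity id so earlier edits cannot invalidate
  # the positions of later ones
  cand_df <- function(kind, ids) {
    if (length(ids)) data.frame(kind = kind, id = ids,
                                stringsAsFactors = FALSE) else NULL
  }
  cand <- rbind(
    cand_df("attr_shift", toks$id[toks$label %in% names(rule5_type_map)]),
    cand_df("state_pos_swap",
            toks$id[toks$label == "Pos_Pri" &
                      c(toks$label[-1], "") == "State"]),
    cand_df("stack_time", toks$id[toks$label == "Time"]))
  next_id <- max(c(doc$entities$id, -1L)) + 1L
  for (k in seq_len(NROW(cand))) {
    if (stats::runif(1) >= rate) next
    i <- match(cand$id[k], toks$id)
    kind <- cand$kind[k]
    if (kind == "attr_shift") {
      after <- which(seq_len(nrow(toks)) > i & toks$label == ".delim")
      if (!length(after)) next
      row <- toks[i, , drop = FALSE]
      toks <- toks[-i, , drop = FALSE]
      j <- min(after) - 1L  # delimiter index after removing the token
      toks <- rbind(toks[seq_len(j), , drop = FALSE], row,
                    toks[seq_len(nrow(toks)) > j, , drop = FALSE])
    } else if (kind == "state_pos_swap") {
      if (i >= nrow(toks) || toks$label[i + 1L] != "State") next
      toks[c(i, i + 1L), ] <- toks[c(i + 1L, i), ]
    } else {
      extra <- setdiff(cfg$lexicon$Time, toks$text[i])
      if (!length(extra)) next
      row <- data.frame(label = "Time", text = pick(extra), id = next_id,
                        stringsAsFactors = FALSE)
      next_id <- next_id + 1L
      toks <- rbind(toks[seq_len(i), , drop = FALSE], row,
                    toks[seq_len(nrow(toks)) > i, , drop = FALSE])
    }
    log <- rbind(log, data.frame(kind = kind, entity_id = cand$id[k],
                                 stringsAsFactors = FALSE))
  }
  doc <- retokenize(doc, toks)
  attr(doc, "perturbations") <- log
  doc
}

# token view of a document: entities plus uncovered characters (each
# uncovered run becomes one ".delim" literal token)
doc_tokens <- function(doc) {
  e <- sorted_entities(doc)
  toks <- list()
  pos <- 0L
  for (i in seq_len(nrow(e))) {
    if (e$start[i] > pos) {
      toks[[length(toks) + 1L]] <- data.frame(
        label = ".delim", text = substr0(doc$text, pos, e$start[i]),
        id = NA_integer_, stringsAsFactors = FALSE)
    }
    toks[[length(toks) + 1L]] <- data.frame(
      label = e$label[i], text = e$text[i], id = e$id[i],
      stringsAsFactors = FALSE)
    pos <- e$end[i]
  }
  if (pos < nchar(doc$text)) {
    toks[[length(toks) + 1L]] <- data.frame(
      label = ".delim", text = substr0(doc$text, pos, nchar(doc$text)),
      id = NA_integer_, stringsAsFactors = FALSE)
  }
  do.call(rbind, toks)
}

# rebuild the document text and entity offsets from a token plan;
# entity ids, labels, texts and all relations are preserved
retokenize <- function(doc, toks) {
  pos <- 0L
  starts <- integer(nrow(toks)); ends <- integer(nrow(toks))
  for (i in seq_len(nrow(toks))) {
    starts[i] <- pos
    pos <- pos + nchar(toks$text[i])
    ends[i] <- pos
  }
  keep <- toks$label != ".delim"
  entities <- data.frame(id = toks$id[keep], label = toks$label[keep],
                         start = starts[keep], end = ends[keep],
                         text = toks$text[keep], stringsAsFactors = FALSE)
  annotated_document(doc$doc_id, paste(toks$text, collapse = ""),
                     entities, doc$relations)
}
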