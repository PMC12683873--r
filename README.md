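# tcmnorm

Fine-grained annotation, rule-based relation extraction and
normalization of symptom information in Chinese present-illness
narratives from traditional Chinese medicine (TCM) electronic medical
records.

## The problem

TCM diagnosis leans on the full symptom picture, but present-illness
narratives express that picture compactly: a compound record such as
脉弦细弱 ("stringy, thready, weak pulse") nests three symptoms in four
characters; a negated enumeration like 无肿胀 attaches one negator to
later states; a single onset time governs every symptom that follows
it. Coarse symptom tagging either loses this structure or produces
overlapping, nested spans.

`tcmnorm` implements a fine-grained alternative for annotators and
clinical-NLP researchers:

* **Schema** — 12 entity types (the position triad `Pos_SCP` /
  `Pos_Pri` / `Pos_Sub`, symptom elements `State` and `Symp_S`, and the
  modifiers `Time`, `Cond`, `Neg`, `Freq`, `Sev_Qual`, `Sev_Quant`,
  `Trend`) and 10 directed relation types (`SPri`, `SSub`, `SSCP`,
  `SN`, `STi`, `SC`, `SF`, `SQual`, `SQuant`, `STr`) with a fixed
  endpoint-constraint matrix, plus validators for the no-overlap /
  no-nesting annotation principles.
* **Rule engine** — five deterministic relation-extraction rules driven
  by clause ("，") and sentence ("。") segmentation: position
  attachment for states, rightward scope attachment, clause-bounded
  negation scope, time ranges that run to the next time expression, and
  clause-local attribute linking.
* **Normalization** — recursive position-path expansion plus per-root
  attribute maps, yielding one standardized symptom row per state and
  path with fixed columns (time, scope, primary, subordinate,
  state/symptom, negation, condition, frequency, qualitative and
  quantitative severity, trend; `-` when absent).
* **Evaluation** — strict span-level precision/recall/F1
  (`P = |y¹∩y²|/|y²|`, `R = |y¹∩y²|/|y¹|`, `F1 = 2PR/(P+R)`), micro and
  per-type, pairwise inter-annotator agreement, and the per-sentence
  annotation-rate (TCM-SIU) metric.
* **I/O** — doccano-style relation-export JSONL in and out, normalized
  rows as TSV.
* **Synthetic corpus** — a seeded generator of grammar-true narratives
  with construction-derived gold relations (plus an adversarial mode
  that breaks the rules' assumptions on purpose), so the entire
  pipeline is testable without access to clinical data.
* **Baseline tagger** — greedy longest-match dictionary tagging for
  end-to-end runs from raw text.

## Worked example

```r
library(tcmnorm)

# "6 years ago, pain in both lower limbs, no swelling."
doc <- annotated_document(
  "d1", "6年前双下肢疼痛，无肿胀。",
  data.frame(id = 0:5,
             label = c("Time", "Pos_SCP", "Pos_Pri", "State", "Neg", "State"),
             start = c(0, 3, 4, 6, 9, 10),
             end   = c(3, 4, 6, 8, 10, 12)))

extracted <- extract_relations(doc)
extracted$relations
#>   id subject_id object_id type
#> 1  0          2         1 SSCP
#> 2  1          3         0  STi
#> 3  2          3         2 SPri
#> 4  3          5         0  STi
#> 5  4          5         2 SPri
#> 6  5          5         4   SN

normalize_document(extracted)[, c("time", "position_scope",
  "position_primary", "state_or_symptom", "negation")]
#>    time position_scope position_primary state_or_symptom negation
#> 1 6年前             双             下肢             疼痛        -
#> 2 6年前             双             下肢             肿胀       无
```

The six relations are exactly what the five rules derive: both states
attach to the shared primary 下肢 (the leftward scan crosses the
comma), the scope 双 attaches rightward to 下肢, the negator covers
only 肿胀 (its clause), and the onset time governs both states. The
normalized table then splits the narrative into two standardized
symptom rows, the second carrying the negation.

The same machinery splits the compound pulse record:

```r
pulse <- annotated_document("d2", "脉弦细弱。", data.frame(
  id = 0:3, label = c("Pos_Pri", "State", "State", "State"),
  start = 0:3, end = 1:4))
normalize_document(extract_relations(pulse))[, c("position_primary",
                                                 "state_or_symptom")]
#>   position_primary state_or_symptom
#> 1               脉               弦
#> 2               脉               细
#> 3               脉               弱
```

## Command line

A thin wrapper over the same functions ships in `exec/tcmnorm`:

```sh
tcmnorm synth --n 500 --seed 42 -o synth.jsonl
tcmnorm extract-relations synth.jsonl -o pred.jsonl
tcmnorm normalize pred.jsonl -o rows.tsv
tcmnorm evaluate --gold synth.jsonl --pred pred.jsonl --level relations
tcmnorm iaa --a ann1.jsonl --b ann2.jsonl --level entities
```

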