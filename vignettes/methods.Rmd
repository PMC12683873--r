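---
title: "Fine-grained symptom annotation, rule-based extraction and normalization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-grained symptom annotation, rule-based extraction and normalization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmnorm)
```

## The annotation model

A present-illness narrative in a TCM medical record is a sequence of
sentences terminated by the full-width period 。, each a sequence of
clauses separated by the full-width comma ，. The schema decomposes
symptom mentions into twelve entity types. Two carry the symptom
itself: a `State` (弦, 疼痛) cannot express a symptom alone and must
combine with a position, while a `Symp_S` (头晕) is complete by
itself. The position triad supplies the subject of a state: `Pos_Pri`
is the primary subject (an anatomical part, organ, or conceptual
position such as the pulse 脉), `Pos_SCP` delimits its range (左, 双),
and `Pos_Sub` is a subordinate aspect sitting between primary and
state (quantity, colour, quality — the 质 in 痰质稠). The remaining
seven types are modifiers: onset `Time` of a symptom group, triggering
`Cond`, `Neg`, `Freq`, qualitative and quantitative severity
(`Sev_Qual`, `Sev_Quant`) and `Trend`.

Ten directed relation types connect them, each named subject_object
and constrained at both ends (`relation_types()` returns the matrix).
Apart from the three position relations (`SPri`, `SSub`, `SSCP`),
every relation takes a `State` or `Symp_S` subject. Two structural
principles are enforced by `validate_document()` rather than assumed:
entity spans may neither overlap nor nest, and relations must resolve
and satisfy the constraint matrix. Violations are returned as data,
never thrown, so a corpus with isolated errors can still be inspected
and repaired.

Offsets are 0-based, half-open counts of Unicode code points. That
matches the export convention of span-annotation tools and keeps each
Chinese character atomic; byte offsets would make every span
encoding-dependent.

## The five extraction rules

The rules exploit the strong positional regularity of present-illness
prose. All scanning is over entities sorted by `(start, end)`;
determinism and input-order independence follow from that sort.

1. **Position for a state.** If both neighbours of a `State` are
   `Pos_Pri`, it relates to the left one; if only the right neighbour
   is, to the right one; otherwise the scan walks leftward to the
   first position entity, emitting `SPri`/`SSub`/`SSCP` by its type.
   The leftward scan crosses clause commas — a shared primary is
   typically written once for several states (脉弦，细，弱) — but by
   default stops at the sentence boundary: cross-sentence attachment
   of a bare state to a far-away position is clinically implausible.
   The bound is a package decision exposed in `rule_config()`, since
   the rule statement itself is silent about 。.
2. **Scope attachment.** A `Pos_SCP` looks rightward for the first
   `Pos_Pri` or `Pos_Sub`, which becomes the subject of `SSCP`.
   Intervening scope qualifiers are skipped, so stacked scopes
   (左右下肢) each attach to the same head; the scan stops at the
   clause boundary by default. Both choices are configurable; the rule
   text does not address either situation.
3. **Negation scope.** A `Neg` covers every `State`/`Symp_S` strictly
   to its right up to the next ， or 。. The enumeration mark 、 is
   deliberately not a stop: a negated enumeration (无头晕、心悸)
   negates all listed symptoms.
4. **Time scope.** A `Time` governs every `State`/`Symp_S` from its
   end up to the start of the next `Time`, crossing clause and
   sentence boundaries — onset times scope whole symptom groups.
   States before the first time expression receive no time. The range
   is measured from the entity's end rather than its start; with
   non-overlapping spans the two choices only differ for states inside
   the time expression, which the no-overlap principle excludes.
5. **Clause attributes.** `Cond`, `Trend`, `Freq`, `Sev_Qual` and
   `Sev_Quant` each relate to every `State`/`Symp_S` in their own
   clause.

`extract_relations()` unions the rule outputs, de-duplicates on
(subject, object, type), and *replaces* any pre-existing relations:
merging predictions into gold silently would corrupt evaluation, so
preserving gold is left to the caller.

One asymmetry deserves note. Manual annotation follows a progressive
order subordinate → primary → scope, so gold corpora contain `SPri`
relations with `Pos_Sub` subjects; the five rules as stated never
produce them. `rule_config(chain_subordinate_to_primary = TRUE)` adds
that chaining; it is off by default to keep the engine faithful to the
printed rules, and the synthetic generator mirrors the same switch so
that gold and engine stay comparable either way.

## Normalization

Rows are built per root (`State` or `Symp_S`, in document order).
`position_paths()` performs a depth-first recursion over position
relations with a visited set; every branch point multiplies paths, and
each maximal path becomes one output row — this is what resolves
symptom nesting (one row per single symptom) and symptom discontinuity
(the shared position is repeated into every row). `attribute_map()`
collects modifier texts per relation type, joining multiple values of
one type with `;` in document order. Absent cells hold `-`.

Decisions where the method description is silent:

* A state whose path lacks a `Pos_Pri` (an orphan subordinate) still
  emits its partial path rather than being dropped.
* Negation is kept as surface text, not collapsed to a boolean — the
  distinction between 无 and 否认 can matter downstream.
* `Symp_S` roots are normalized too, with empty position columns.
* Identical duplicate rows arising from redundant gold relations are
  not de-duplicated; no information is invented or removed.
* The TSV column order (doc_id, time, scope, primary, subordinate,
  state/symptom, negation, condition, frequency, qualitative severity,
  quantitative severity, trend) is fixed by this package; output is
  TSV because cell values can contain the full-width comma.

## Scoring

All scoring is strict: an entity counts as correct only if both
boundaries and the type agree; a relation only if both endpoint
entities (by span and label) and the relation type agree. With
reference set $y^1$ and prediction set $y^2$,

$$R = \frac{|y^1 \cap y^2|}{|y^1|}, \quad
  P = \frac{|y^1 \cap y^2|}{|y^2|}, \quad
  F_1 = \frac{2PR}{P+R}.$$

Because the intersection is symmetric, swapping the two sets leaves
F1 unchanged while P and R trade places — the property that makes the
pairwise score usable as an inter-annotator agreement. Zero
denominators use the convention P (resp. R) = 0 for an empty
prediction (resp. reference) set and F1 = 0 when P + R = 0. Micro
scores pool keys over documents and are therefore invariant to how
the same annotations are partitioned into documents; both properties
are exercised in the test suite against a brute-force nested-loop
oracle.

`annotation_rate()` implements the symptom-information-utilization
metric: per sentence, the fraction of characters covered by entity
spans, averaged over sentences. A sentence unit includes its
terminating delimiter, and delimiters count in the denominator — the
metric asks how much of the written text the scheme can use, and the
delimiters were written. This choice is stated here because the
metric's verbal definition does not settle it.

## The synthetic generator

The withheld clinical corpus cannot ship, so the package generates
grammar-true stand-ins. A document is a sequence of sentences; each
sentence optionally opens with a `Time` and contains clauses of the
pattern `[Neg?][Pos_SCP*][Pos_Pri][Pos_Sub?][State][attr*]` or
`[Neg?][Symp_S][attr*]`, joined by ， and closed by 。. Gold relations
are derived from the construction trace — never by running the
extractor, which would make the oracle test circular.

Default emission probabilities (`p_time = 0.5`, `p_neg = 0.25`,
`p_scope = 0.3`, `p_sub = 0.15`, `symp_s_probability = 0.2`, attribute
probabilities 0.04–0.15) were chosen once so that the generated
per-type histogram is dominated by states and primary positions with
negation and time common and quantitative severity rare, the ranking
observed in fine-grained TCM EMR annotation; they are free parameters
of the generator, not estimates of the real corpus's co-occurrence
structure. Documents default to 1–4 sentences of 1–4 clauses. Every
document is deterministic in `(seed, doc_index)`.

One construction guard keeps clean-mode generation inside the rules'
reach: a clause that ends `[Pos_Sub][State]` with no trailing
attribute, followed in the same sentence by a clause that opens with a
`Pos_Pri`, would trigger rule 1's right-neighbour case and attach the
state across the clause boundary, contradicting the construction's
intent. The generator therefore always emits at least one trailing
attribute after a subordinate-bearing state. With that guard, rule
extraction reproduces construction gold with micro P = R = F1 = 1.0 —
the suite checks 150 documents routinely and the acceptance script
1,000, sizes chosen to exercise all grammar branches many times while
keeping a full run in tens of seconds on one CPU.

`inject_adversarial()` deliberately breaks the assumptions while
keeping gold aligned with the intended semantics: an attribute moved
into the following clause (rule 5 misses it), a `[Pos_Pri][State]`
pair swapped (rule 1's right-neighbour case still recovers it), and a
second time expression stacked directly after an existing one (rule 4
then misattributes the following states). At a perturbation rate of
0.5 the engine's micro F1 drops to roughly 0.7, making the
degradation measurable rather than assumed.

What passing the clean-mode oracle shows — and what it does not: the
engine implements the five rules exactly on text that obeys the
position+state grammar. Real narratives contain typos, free-order
descriptions, long parenthetical insertions and relations that only
medical knowledge can resolve; the synthetic corpus does not model
those, so clean-mode F1 = 1.0 is a correctness check of the
implementation, not a performance claim about clinical text.

## The baseline tagger

`longest_match_tag()` is a greedy longest-match dictionary scan,
sufficient to run the pipeline end-to-end from raw text and faithful
to the maximize-coverage annotation principle (手小指 beats 手 at the
same position). It is explicitly not a learned NER model; on text
whose surface forms are in the dictionary it recovers gold entities
exactly, and on anything else it degrades like any gazetteer.

## Degenerate inputs and tie-breaks

* Empty text yields empty clause/sentence span sets; a trailing
  segment without a final delimiter is still a span.
* Entities tie-broken by id after `(start, end)` when sorting; in a
  valid document spans are disjoint so the tie-break never fires.
* Duplicate relations collapse at construction with a warning;
  duplicate `(start, end, label)` entities are validation errors.
* An entity containing a delimiter character is a warning
  ("suspicious span"), not an error — segmentation-based rules will
  behave oddly around it, but the annotation itself may be intended.
* A document id that looks like an integer is written back to JSONL
  as an integer, keeping round-trips byte-identical.

## Known limitations

* The rules are clause-geometric; they cannot recover relations that
  require semantic inference, and the rule-1 sentence bound and
  rule-2 clause bound are heuristics exposed as configuration rather
  than truths.
* Normalized states are surface strings; mapping them to standard
  terminologies is future work outside this package's scope.
* The generator's probabilities are not fitted to any real corpus;
  only the type ranking, not the joint distribution, is emulated.
* Discontinuous and fuzzy entity spans are unsupported by design.
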