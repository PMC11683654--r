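---
title: "Ontology-enhanced rare-disease mining: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-enhanced rare-disease mining: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raremine)
```

## The problem and the model

Rare diseases are the central entity type of this package: conditions
affecting fewer than roughly 1 in 2000 individuals, frequently absent from
coded fields, and documented mostly in prose. The package implements a
pipeline that extracts rare-disease entities and their relations to other
medical concepts from free text and assembles the results into a typed
knowledge graph. A large language model does the linguistically hard parts,
but it is deliberately boxed in: ontologies supply the medical knowledge
the model may lack, prompts are assembled from a fixed section skeleton,
and the model's output is filtered against hard constraints (closed type
systems, endpoint resolution, the rule that an anaphora antecedent must be
a rare disease).

The staged design follows a chain-of-thought decomposition. Entity
extraction runs as three sub-steps — dictionary matching, term expansion,
typed extraction — so that external knowledge can be injected exactly where
it helps: lexicon definitions at the matching step, rare-disease
name/definition knowledge at the typing step, association triples at the
relation step. The final entity set is the model's step-3 output;
dictionary matches are hints, not guarantees, which keeps the evaluation an
honest measurement of the end-to-end system rather than of the dictionary.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `max_tokens` (segment budget) | 2000 | tokens | fits an 8000-token context with ~1000 instruction tokens and response headroom |
| `bridge_tokens` (window width) | 1000 | tokens | half a segment budget on each side of a boundary; covers any relation whose endpoints sit in adjacent segments' flanks |
| `budget_tokens` (instruction budget) | 1000 | tokens | prompt skeleton + slots, excluding the segment text |
| `negation.window_tokens` | 5 | word tokens | typical scope of clinical negation cues; clause boundaries (`.`, `;`) always terminate scope |
| exemplars `k` | 5 | documents | few-shot prompting sweet spot; sampled once per run, seeded |
| `temperature` | 0 | — | most stable output; recorded for live adapters, ignored by the mock |
| calibration mode | `both` | — | the zero-relation rule motivates the step; the model then confirms survivors |

The token counter is a whitespace tokenizer (maximal non-whitespace runs).
Token budgets here are calibration constants, not hard API limits, and the
whitespace count is a stable, dependency-free proxy that over-counts
slightly relative to byte-pair encodings — a conservative direction for
budget checks. The tokenizer is pluggable at the `count_tokens()` seam.

## Numerical and procedural choices

- **Normalization.** One string-equality notion everywhere: case-fold,
  trim, collapse internal whitespace (`normalize_name()`). Scoring uses
  exact-after-normalization matching; no fuzzy matching, so measured
  differences are attributable to the pipeline rather than to a similarity
  threshold.
- **Matching.** Dictionary scanning is case-insensitive, word-boundary
  anchored (alphanumeric/non-alphanumeric transitions), longest-match-wins,
  left to right, non-overlapping. Negated matches are kept and flagged
  rather than dropped — the flag is surfaced to the model, which decides.
- **Splitting.** Corpus splits are a seeded shuffle followed by a
  contiguous partition with largest-remainder apportionment (ties to the
  earlier part). 1040 documents at 6:2:2 give exactly 624/208/208; 7 give
  4/2/1.
- **Duplicate keys.** Lexicon ties resolve first-seen-wins (logged);
  node-type conflicts in the graph resolve rare_disease > disease >
  symptom_and_sign; multi-link anaphors resolve to the textually nearest
  preceding antecedent, with a warning.
- **Scoring.** Per document, predicted and gold items pair greedily on
  exact (normalized name, type) keys — equivalent to per-key
  `min(count_pred, count_gold)` and, by an exchange argument on equal-key
  multisets, to the optimal bipartite matching (the test suite verifies
  this against an explicit maximum-matching oracle). Micro-averaged overall
  scores pool counts across types. The overall F1 is the arithmetic mean of
  entity-overall and relation-overall F1; overall P and R are the same
  means of their components, so reported overall rows are reproducible
  arithmetic. Rounding happens only at report time, half away from zero, to
  one decimal.
- **Empty predictions.** Precision over zero predictions is reported as 0
  with an `empty_pred` flag rather than NaN.
- **JSON robustness.** Model responses pass through an extraction ladder:
  fenced block, first balanced object, bracket-balancing repair of a
  truncated object, then a typed parse error carrying the raw text.
  Retries apply only to transport failures, never to parse failures.

## The mock backend and what the tests can show

Every rendered prompt begins with a machine-readable marker line (stage,
document id, character span, segment/bridge kind). The mock backend routes
on this marker and answers from gold annotations restricted to the span,
optionally corrupted: per-occurrence entity drops, type confusions,
relation drops, spurious additions, each driven by an RNG stream derived
deterministically from (oracle seed, marker), so identical inputs always
produce identical responses and results are reproducible per seed.

The synthetic generator emulates the statistical shape of a rare-disease
abstract corpus: documents of 5–10 gold mentions in 2–3-sentence
paragraphs, entity occurrences approximately 34% rare_disease, 40%
symptom_and_sign, 15% disease, 11% anaphor, a relation mix dominated by
`produces`, anaphors inserted immediately after a rare-disease sentence in
the same paragraph, negation sentences whose mention is gold-excluded, and
a configurable fraction of relations rendered across adjacent paragraph
boundaries. Two structural guarantees make outcomes analytic: every gold
mention participates in at least one relation in its document (so
calibration is the identity on gold), and name-level relation triples are
unique within a document (so triple deduplication is lossless). Under zero
corruption the pipeline is then a *fixed point*: entity and relation
precision, recall and F1 are exactly 100. Under an entity-drop probability
p, entity recall is Binomial(n, 1−p)/n — the calibration tests assert
agreement within three binomial standard errors — and a relation with a
dropped endpoint is unrecoverable, which bounds relation recall by the
fraction of gold relations whose endpoint names both survive.

What passing these tests shows is that the machinery around the model —
segmentation, prompting, parsing, filtering, deduplication, bridging,
calibration, graph construction, scoring — is lossless and correctly
calibrated. What they cannot show is extraction quality on real clinical
language: the generator's sentences are templatic, its negations are
lexical, and its anaphors are adjacent to their antecedents. Real-model
performance is a property of the backend plugged into the `complete()`
contract, not of this package's logic.

Test and acceptance runs use scaled-down study sizes chosen to exercise
every code path: 100-document corpora, a 12-token segment budget (which
forces sentence-level segments so that bridge windows are genuinely
needed), and 24-token bridge windows. The same invariants hold at the
default 2000/1000-token settings; the small settings simply make
segmentation and bridging non-trivial on short synthetic documents.

## Design decisions on genuinely open points

- **Ontology dialects.** Full OWL parsing is out of scope; sources are
  accepted as OBO term stanzas or a compiled 4-column TSV (id, name,
  pipe-separated synonyms, definition; associations as
  disease/frequency/phenotype rows). Only names, definitions and triples
  are consumed downstream, which these dialects capture completely.
- **Synonym indexing** is on by default and switchable
  (`include_synonyms = FALSE`) since preferred-name-only matching is a
  defensible alternative.
- **Negated candidates** are kept and flagged (toggleable by filtering the
  match frame) rather than silently discarded.
- **Calibration** exposes `rule`, `llm`, `both` and `none`; `both` is the
  default. Statistical corruption experiments in the tests use `llm` so
  that measured recall isolates the induced entity loss instead of
  compounding it with rule-based pruning of relation-orphaned survivors.
- **Bridge windows** re-extract relations only; entities fed to a bridge
  call are those from the flanking segments whose spans fall inside the
  window. Re-running entity extraction there would double-count
  occurrences.
- **Invalid model output** (unknown entity or relation types, unresolved
  endpoints) is dropped with a warning, never coerced — silent coercion
  would corrupt the confusion matrices.
- **Exemplars** for the relation stage reuse the same sampled documents as
  the entity stage; budget overflow drops exemplars from the end, then
  truncates knowledge slots, and never touches the segment text.
- **Isolated nodes** are excluded from the exported graph, consistent with
  calibration's premise that relationless entities are likely irrelevant.

## Known limitations

- No discontinuous or nested spans; no cross-document coreference; no
  entity normalization to ontology identifiers beyond the knowledge-slot
  lookup.
- Negation handling is a cue list with a token window — deliberately not a
  full NegEx/ConText implementation (no post-position cues, uncertainty or
  experiencer handling).
- The sentence splitter is a punctuation heuristic; pathological
  unsplittable text is hard-wrapped at the token level with a warning.
- Relation scoring does not condition on entity-extraction correctness;
  this is the intended reading of the benchmark's protocol and means
  entity and relation scores are not independent measurements.
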