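---
title: "Methods: entity extraction, guideline graph and report auditing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entity extraction, guideline graph and report auditing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleaudit)
```

# The problem

Incidentally detected pulmonary nodules carry consensus follow-up
recommendations (the Fleischner Society scheme) that depend on four
attributes of the finding: the nodule's composition (solid, part-solid,
ground-glass), its size, whether it is solitary or one of several, and the
patient's risk stratum. Radiology reports record these attributes in free
text, and the recommendation the radiologist actually writes into the
impression may agree with, omit, or contradict what the guideline
prescribes. `noduleaudit` implements the full audit loop:

1. extract the eight entity types (location, shape, nodule name, solidity,
   quantity, risk level, size, follow-up recommendation) from free text
   with a BiLSTM+CRF sequence labeler;
2. normalize surface forms to a canonical catalog and fill the five query
   slots — presence (a), solidity (b), size (c), quantity (d), risk (e);
3. query a knowledge graph encoding the guideline decision table for the
   recommendation level (one of nine classes, L1–L9);
4. compare the level written in the impression with the generated level
   and report per-level and overall matching rates.

# Sequence labeling model

The labeler is a linear-chain conditional random field over a
bidirectional LSTM encoder. For a token sequence $x_{1:T}$ with tag path
$y_{1:T}$ the path score is

$$ s(x, y) = \sum_{t=1}^{T} e_t(y_t) + A_{\mathrm{START}, y_1}
   + \sum_{t=2}^{T} A_{y_{t-1}, y_t} + A_{y_T, \mathrm{STOP}}, $$

where $e_t \in \mathbb{R}^{K}$ are the emission scores produced by a
linear projection of the concatenated forward/backward hidden states and
$A$ is the learned transition matrix augmented with virtual START/STOP
states. Training minimizes the negative log-likelihood
$\log Z(x) - s(x, y^\*)$ with the forward algorithm computing $\log Z$ in
log space; decoding is exact Viterbi.

Design choices:

* **Hard BIO mask.** Transitions that would produce an invalid BIO
  sequence (`I-X` after `O`, after a different type, or at the start) are
  fixed at $-\infty$ in the transition matrix rather than repaired after
  decoding, so every decoded path is valid by construction. Masked
  entries receive no gradient.
* **Tie-breaking.** Exact score ties during Viterbi backtracking resolve
  toward the lowest tag index, making decoding fully deterministic.
* **Tokenization.** Text containing CJK codepoints is tokenized per
  character — the standard choice for Chinese clinical text, which lacks
  whitespace word boundaries; otherwise tokens are words, numeric size
  expressions (`7mm`, `0.8cm`, `10×8mm`) and punctuation marks. Offsets
  are 0-based and end-exclusive, which stays unambiguous for CJK text.
* **Embeddings from scratch.** No pretrained vectors are assumed:
  reliable clinical word vectors are scarce for the report languages this
  pipeline targets, and the templated vocabulary is small.
* **Hyperparameters** (all in `ner_hyperparams()`): embedding 32, hidden
  64 per direction, one BiLSTM layer, dropout 0.3 on the concatenated
  hidden states, Adam at 0.003 with batches of 8 sequences, at most 30
  epochs with early stopping after 5 epochs without validation
  improvement. The model selected is the one with the best validation
  entity-level micro-F1. This capacity is deliberately modest: the
  synthetic vocabulary has a few hundred token types, and a larger
  encoder only slows CPU training without measurable benefit here.
  Training is single-threaded and deterministic given the seed.

The compiled core (RcppArmadillo) implements the encoder, the CRF
forward-backward gradients, backpropagation through time and Adam; its
gradients are verified against central finite differences, and its
Viterbi against the pure-R reference decoder and against exhaustive path
enumeration on small instances.

**Metric conventions.** Per-type *accuracy* is token-level tag accuracy
over tokens whose gold tag belongs to the type (total accuracy over all
tokens); *precision/recall/F1* are entity-level over exact (span, type)
matches, with precision defined as 0 when nothing is predicted. The
*number* column counts the catalog's distinct entities per type
(37/11/13/7/6/14/9, totalling 97).

# Canonical catalog and slot filling

The catalog (`default_vocabulary()`) maps 97 surface forms to canonical
values: 37 locations, 11 shapes, 13 nodule names (including absence
phrasings), 7 solidity forms → {SOLID, PART_SOLID, GROUND_GLASS}, 6
quantity forms → {SINGLE, MULTIPLE}, 14 risk descriptions → {LOW, HIGH},
and 9 follow-up recommendation texts → L1–L9. Size is free-form and
parsed numerically: centimetres are converted (×10) and two-axis
expressions (`10×8mm`) take the mean of the axes, the usual convention
for nodule diameter. Matching is case-insensitive on tokenized keys, so
surface forms survive the token/offset round trip.

Slot filling (`assemble_state()`) aggregates a report's mentions into one
state under a "most suspicious nodule" policy: the largest size wins,
MULTIPLE beats SINGLE, HIGH beats LOW. Solidity conflicts keep the first
mention (ordering solidity classes by suspicion is not clinically
well-founded) and warn. Missing quantity defaults to SINGLE, missing risk
to LOW, missing solidity to SOLID and missing size to the smallest bin —
each the least-escalating branch of the guideline, each logged as a
warning. Size bins are solidity-dependent: solid nodules use <6 mm,
6–8 mm (inclusive, matching the guideline's "6–8 mm" phrasing), >8 mm;
subsolid nodules use <6 mm and ≥6 mm.

# The guideline graph

The decision table (`default_rules()`) is the single point of truth and is
user-replaceable via YAML. Each rule contributes the chain

```
nodule_name -has-> solidity -has_an_attribute-> size_bin
  -has_an_attribute-> quantity -has_an_attribute-> risk_level
  -follow_up_is-> followup
```

and rules sharing a slot prefix share nodes, so the graph is a prefix
tree: every complete state selects exactly one root-to-leaf path. Because
distinct chains may pass through the same slot value (two SINGLE quantity
nodes under different solidity/size prefixes), chain-node labels are
path-qualified (`"SOLID|LT6|SINGLE"`) to keep (category, label) unique
while the plain value lives in a `value` attribute; standalone canonical
concept nodes carry the `same_as` edges from the 49 surface forms of the
graph's entity categories. Rules with risk `ANY` use a single `ANY` risk
node matched by both risk levels. The default graph has 104 nodes; the
node count is emergent from the configuration (catalog sizes and rule
granularity), not a target.

`validate_graph()` checks structural consistency: every one of the 28
valid states reaches exactly one follow-up node, each terminal has
exactly one `follow_up_is` edge, `follow_up_is` edges end only at
follow-up nodes, `same_as` edges run surface → canonical, every canonical
value appears, and all nine levels are reachable. Deleting any single
`follow_up_is` edge fails validation (tested exhaustively). Export is
available as Cypher (one `CREATE` per node, `MATCH … CREATE` per
relationship, with exactly the four relationship types `has`,
`has_an_attribute`, `follow_up_is`, `same_as`) and as GraphML.

An independent nested-conditional oracle (`oracle_recommend()`), written
without reference to the rule table or graph code, provides ground truth:
graph query and oracle agree on the full state enumeration, and both are
surjective onto the nine levels.

# Synthetic corpus

Real hospital report corpora are not redistributable, so the generator
(`generate_corpus()`) emulates their statistical structure with known
ground truth:

* **States.** A report is nodule-free with probability 0.04 (exercising
  the not-applicable path); otherwise its recommendation level is drawn
  with the heavily skewed weights of a large hospital audit (77% "no
  routine follow up"), the state uniformly among states mapping to that
  level, and the size uniformly within its bin, rounded to 0.1 mm.
* **Text.** Findings are assembled from sentence templates — a nodule
  sentence (quantity, solidity, name, location), a size sentence
  rendered in one of four numeric formats to exercise the parser, a
  shape sentence, a risk sentence — shuffled together with 1–2 distractor
  sentences. Several distractors deliberately contain catalog surface
  forms in non-entity roles ("multiple prior studies", "low risk of
  motion artifact", "solid organs", "no ground glass opacity in the
  remaining lung"), so context-free dictionary matching produces false
  positives and the sequence model has something real to learn.
* **Impressions.** Per level, the impression carries the correct
  recommendation text with probability `p_correct`, none with `p_omit`,
  and a different level's with `p_wrong`. The default `p_correct` values
  are the published per-level matching rates; the residual mass is split
  80/20 between omission and error, since omission is the reported
  failure mode at the lowest level. All rendered text is annotated with
  gold BIO tags over findings + impression.

What passing tests on this corpus do **not** show: robustness to
paraphrase outside the template grammar, negation and uncertainty
("cannot exclude"), comparisons with prior imaging, multi-nodule reports
with per-nodule descriptions, or genuinely out-of-vocabulary clinical
terminology. The generator bounds what the end-to-end numbers mean.

# Audit conventions

A report matches when the written level equals the generated level (same
canonical class, i.e. same follow-up frequency and method). A missing
written recommendation is a mismatch at every level L1–L9 — including "no
routine follow up required", which must still be stated; this convention
is what makes the lowest level the worst-matching one in practice. For
nodule-free reports (generated level NOT_APPLICABLE) writing nothing is
correct conduct, so a missing recommendation counts as a match there.
When an impression contains several conflicting follow-up phrases the
most escalated level is kept (and logged). Fuzzy interval matching
("review in 10 months" vs "CT review at 12 months") is out of scope and
surfaces as a mismatch.

# Problem sizes and numerics

The test suite trains on a 2,000/500/500 synthetic split (a scaled-down
analogue of the published 24k/12k/12k design at the same 50/25/25
ratios), audits 5,000 generated reports against 3-standard-deviation
binomial bands, and verifies the CRF primitives against exhaustive path
enumeration on 200 random instances of length ≤ 6 with ≤ 5 tags at
tolerance 1e-6. Splitting uses largest-remainder allocation within each
stratum (proportions honoured to ±1 report; strata under 4 reports go
wholly to train with a warning). The stratum function is pluggable; on
synthetic data the natural stratum is the report's follow-up level, the
distribution the audit depends on. Log-space arithmetic is used
throughout the CRF; forbidden transitions are −∞ at the R interface and a
large negative constant in the compiled core to keep IEEE arithmetic
finite. Parsed sizes are rounded to 4 decimals so that centimetre
renderings cannot straddle a bin boundary by a floating-point ulp.

# Limitations

* One aggregated state per report; per-nodule recommendation lists are
  future work.
* The graph encodes one decision table; site-specific policies are
  supported only via replacement YAML rules.
* Per-report latency is recorded (attribute `seconds_per_report` on
  `recommend()` output) but is hardware-dependent and not asserted.
* The published knowledge-graph node inventory is not reproduced; the
  node count here follows from the catalog and rule configuration.
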