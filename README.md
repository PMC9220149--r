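# noduleaudit

Automated quality auditing of pulmonary-nodule radiology reports.

Incidental pulmonary nodules carry consensus follow-up recommendations
(the Fleischner Society scheme) determined by four attributes: nodule
composition (solid / part-solid / ground-glass), size, multiplicity, and
patient risk. Radiology reports describe these attributes in free text,
and the follow-up advice the radiologist writes into the impression may
agree with, omit, or contradict what the guideline prescribes.
`noduleaudit` closes that loop for quality management:

1. **Entity extraction** — a bidirectional LSTM + linear-chain CRF
   sequence labeler (trained from scratch, compiled core in
   RcppArmadillo) tags eight entity types in BIO scheme: location, shape,
   nodule name, solidity, quantity, risk level, size, and follow-up
   recommendation. The CRF path score is
   `s(x,y) = Σ_t e_t(y_t) + A_START,y1 + Σ_t A_{y_{t-1},y_t} + A_{y_T,STOP}`,
   trained by exact NLL (forward algorithm) and decoded by Viterbi under
   a hard BIO transition mask.
2. **Normalization and slot filling** — surface forms map to a canonical
   catalog (97 entities: 37 locations, 11 shapes, 13 names, 7 solidity,
   6 quantity, 14 risk, 9 follow-up); sizes are parsed to millimetres;
   mentions are aggregated into the five query slots
   (presence, solidity, size, quantity, risk) under a
   "most suspicious nodule" policy.
3. **Guideline graph** — the decision table is compiled into a property
   graph (nodule_name → solidity → size bin → quantity → risk →
   follow-up, with `has`, `has_an_attribute`, `follow_up_is`, `same_as`
   relationships); querying a validated graph maps every complete state
   to exactly one of nine recommendation levels (L1–L9). Export to
   Cypher (Neo4j) or GraphML.
4. **Audit** — the level written in the impression is compared with the
   generated level per report; per-level and overall matching rates come
   out as a tidy table.

A seeded synthetic-corpus generator produces fully annotated report
corpora with known nodule states and controllable impression-writing
behavior, standing in for hospital corpora that cannot be redistributed.
See `vignette source in vignettes/noduleaudit-methods.Rmd` for the model,
the conventions, and what synthetic results do and do not show.

## Worked example

```r
library(noduleaudit)

corp  <- generate_corpus(400, seed = 42)        # synthetic annotated corpus
split <- split_corpus(corp$reports, seed = 7)   # stratified 50/25/25
ann   <- corp$annotations

model <- ner_train(ann[split$subset == "train", ],
                   ann[split$subset == "validation", ], seed = 1)
model
#> <ner_model: BiLSTM + CRF>
#>   vocab 298 tokens, 17 tags; embed 32, hidden 64/direction
#>   trained 8 epoch(s); best epoch 8, validation F1 1.0000

test <- ann[split$subset == "test", ]
evaluate_ner(test, predict_tags(model, test))
#> # A tibble: 9 × 6
#>   entity_type accuracy precision recall    f1 number
#> 1 LOCATION       1             1  1     1         37
#> 2 SHAPE          1             1  1     1         11
#> 3 NODULE_NAME    1             1  1     1         13
#> 4 SOLIDITY       1             1  1     1          7
#> 5 QUANTITY       1             1  1     1          6
#> 6 RISK_LEVEL     1             1  1     1         14
#> 7 SIZE           0.962         1  0.936 0.967     NA
#> 8 FOLLOWUP       1             1  1     1          9
#> 9 Total          0.999         1  0.993 0.996     97

graph   <- build_guideline_graph()              # validated decision-table graph
recs    <- recommend(graph, reports = corp$reports, model = model)
written <- extract_written_level(corp$reports, model)
audit_corpus(audit_reports(recs[c("report_id", "level")], written))
#> <audit_table>
#> # A tibble: 10 × 5
#>    level          level_label                  n_reports n_matched matching_rate
#>  1 L1             No routine follow up requir…       312       278         0.891
#>  2 L2             CT review at 12 months              25        25         1
#>  3 L3             CT review between 6 and 12 …        19        18         0.947
#>  ...
#> 10 NOT_APPLICABLE Not applicable: no pulmonar…        20        20         1
#> overall matching rate: 91.25% (365 / 400)
```

Reading the output: per-type rows mirror the standard NER report
(entity-level precision/recall/F1, token-level accuracy; `number` is the
catalog's distinct-entity count per type, totalling 97). The audit table
groups reports by the system-generated level; `matching_rate` is the
fraction whose written recommendation equals it. The first level's rate
is lowest by construction of the writing-behavior model — report writers
tend to omit "no routine follow up required" — and the overall rate is
the count-weighted mean of the per-level rates.

A thin command-line wrapper with the same pipeline stages
(`generate`, `train`, `evaluate`, `recommend`, `audit`, `export-graph`,
`validate-graph`) is installed under `inst/cli/noduleaudit`.

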