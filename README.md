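# oncotimelines

Extract patient-level systemic anticancer therapy (SACT) timelines from
free-text clinical notes.

Oncology patients accumulate hundreds of notes across care settings, and
the *order* in which chemotherapy, endocrine, targeted, and immunotherapy
agents were given — far more than mere exposure — is what matters for
care and research. That ordering lives in narrative text. This package
turns a patient's chart into a deduplicated timeline of triples

```
<event, relation, date>      e.g.  ['carboplatin', 'contains-1', '2013-10-24']
```

where `contains-1` means the drug was administered on the date named by
the time expression, and `begins-on` / `ends-on` mark regimen
boundaries. The pipeline is the standard architecture for this task:

1. **SACT event mentions** — a dictionary tagger (`tag_events_lexicon()`)
   or a trainable BIO sequence labeler (`train_event_tagger()`,
   `tag_events_model()`), with a plug-in contract for external taggers;
2. **time expression mentions** — a date grammar (`detect_timex()`)
   normalized against the document creation time
   (`normalize_timex("yesterday", as.Date("2022-04-29"))` →
   `"2022-04-28"`);
3. **pairwise temporal relations** — every event-time pair within a
   60-token window is classified as CONTAINS / BEGINS-ON / ENDS-ON /
   OVERLAP / BEFORE (or NONE) by trigger rules, a trainable linear
   model, or a plug-in (`classify_relations()`), plus a date-subsection
   heading rule;
4. **summarization** — deduplication and conflict resolution into one
   timeline per patient (`summarize_timelines()`);
5. **evaluation** — per-patient F1 macro-averaged across patients at
   four granularities: strict, relaxed-to-day, relaxed-to-month
   (headline), relaxed-to-year (`evaluate_timelines()`).

A two-step few-shot prompting variant (`run_llm_pipeline()`) extracts
triples sentence by sentence through any `prompt -> completion` backend
and validates/corrects relation directionality (a reversed
`<event, CONTAINS, time>` is corrected to `contains-1`).

Because the clinical corpora for this task are access-restricted, the
package ships a synthetic EMR generator (`generate_corpus()`) that emits
multi-note patients with aligned gold mentions, gold pairwise relations,
and gold timelines — including the documented failure modes (date-headed
subsections, hedged statements, cross-disease confounders, deictic
dates) — so every stage has a closed, no-download test oracle.

## Worked example

```r
library(oncotimelines)

corpus <- generate_corpus(n_patients = 10, notes_per_patient = 4,
                          noise = noise_config(p_heading = 0.3, seed = 42))
cat(corpus$notes$text[2])
#> Oncology follow-up visit.
#> First dose of carboplatin on 3/16/2035.
#> April 2035:
#> 1 cycle of carboplatin.

res <- run_pipeline(corpus, pipeline_config(regime = "subtask2",
                                            classifier = "rules"))
head(res$timelines, 5)
#> # A tibble: 5 x 4
#>   patient_id event       relation   date
#>   <chr>      <chr>       <chr>      <chr>
#> 1 pat001     carboplatin begins-on  2035-03-16
#> 2 pat001     carboplatin contains-1 2035-03-16
#> 3 pat001     carboplatin contains-1 2035-04
#> 4 pat001     carboplatin contains-1 2035-04-06
#> 5 pat001     carboplatin contains-1 2035-04-27

evaluate_timelines(res$timelines, corpus$timelines)
#> Patient-level timeline evaluation (macro F1 across 10 patients)
#>   strict            F1 = 1.000  (P = 1.000, R = 1.000)
#>   relaxed-to-day    F1 = 1.000  (P = 1.000, R = 1.000)
#>   relaxed-to-month  F1 = 1.000  (P = 1.000, R = 1.000)  [headline]
#>   relaxed-to-year   F1 = 1.000  (P = 1.000, R = 1.000)
```

The first rows read: carboplatin *began on* 2035-03-16, was
*administered on* that date and on 2035-04-06 and 2035-04-27, and one
administration is known only to month precision (`2035-04`) because the
note recorded it under an `April 2035:` subsection heading. On this
clean synthetic corpus the rule pipeline reconstructs every gold
timeline exactly; `res$report` gives per-stage counts (mentions, pairs,
labels, drops) satisfying the pipeline's conservation identities.
`tidy()` / `glance()` return the per-patient and macro score tables, and
`autoplot()` / `plot_timeline()` draw them. A thin command-line wrapper
with `synth` / `extract` / `evaluate` subcommands is installed at
`inst/cli/oncotimelines.R`.

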