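---
title: "Extracting patient-level anticancer therapy timelines from clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting patient-level anticancer therapy timelines from clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotimelines)
library(dplyr)
```

## The problem

Systemic anticancer therapy (SACT) — cytotoxic chemotherapy, endocrine,
targeted, and immunotherapy agents — is usually given as sequences and
combinations of drugs whose *ordering* matters clinically far more than
mere exposure. That ordering is rarely recoverable from structured data,
but it is described at length in the free-text notes of a patient's
chart. The extraction task is therefore: given all notes of a patient
(each with a document creation time, *DocTime*), produce a deduplicated
patient-level timeline of triples

```
<event, relation, date>     e.g.  ['carboplatin', 'contains-1', '2013-10-24']
```

where `contains-1` means the drug was administered on that date, and
`begins-on` / `ends-on` mark regimen boundaries. Two regimes are
standard: with gold event/time mentions supplied (*subtask1*) and fully
automatic (*subtask2*).

This package implements the full pipeline as composable data-frame
functions, together with a synthetic note generator that serves as a
closed test oracle, so every stage can be validated without access to
restricted clinical corpora.

## The pipeline model

1. **Event mentions.** A dictionary tagger (case-insensitive,
   longest-match, punctuation-stripped lookup of `sact_lexicon()`
   phrases over whitespace tokens) or a trainable BIO sequence labeler
   (`train_event_tagger()`). The labeler is a ridge-penalized
   multinomial logistic model over sparse token-local features
   (lowercased form, 3-character affixes, word shape, neighbors within
   ±2 tokens); any external tagger can be plugged in through the same
   predict-spans contract (`predict_bio()`).
2. **Time mentions.** A grammar of nine pattern classes
   (`timex_patterns()`): absolute days in three notations, month-year,
   bare month, bare year, deictic expressions, day/week/month offsets,
   and `last <weekday>`. `normalize_timex()` maps each surface to an
   ISO-style value at its intrinsic granularity (`YYYY`, `YYYY-MM`,
   `YYYY-MM-DD`); deictic and offset forms are resolved against
   DocTime, everything outside the grammar returns `NA` (unknown).
3. **Pairing.** Every event-time pair within 60 whitespace tokens
   (nearest edges, `window_config()`) becomes a classification instance
   whose window text marks the pair with `<e>…</e>` and `<t>…</t>`,
   crossing sentence boundaries, with 10 tokens of padding context.
4. **Relation classification.** Pairwise labels are CONTAINS,
   BEGINS-ON, ENDS-ON, OVERLAP, BEFORE, plus an artifact-internal NONE
   negative class. Three interchangeable classifiers: trigger rules,
   a trainable linear model, or a user plug-in function.
5. **Summarization.** `summarize_timelines()` drops unknown dates and
   OVERLAP/BEFORE labels, inverts CONTAINS to `contains-1`, lowercases
   event strings, deduplicates, and sorts.
6. **Evaluation.** `evaluate_timelines()` scores per-patient
   precision/recall/F1 at four granularities (strict, relaxed-to-day,
   -month, -year) and macro-averages F1 across patients;
   relaxed-to-month is the headline score.

A two-step prompting variant (`run_llm_pipeline()`) replaces steps 3–4:
each sentence containing an event is sent to a text-generation backend
with a 12-exemplar prompt asking for triples, then each extracted time
expression is normalized with a second 5-exemplar prompt. The backend is
any `prompt -> completion` function; the package ships a scripted,
deterministic mock (`backend_gold_mock()`) for testing. One sentence is
sent per call — multi-sentence inputs measurably degrade extraction
quality in this family of tasks, so batching is deliberately not
implemented.

## Rule classifier design

The trigger inventory is deliberately small and documented:
begin triggers (*started, starting, begin(s), began, initiated, first
dose, cycle 1*) → BEGINS-ON; end triggers (*completed, finished, last
dose, final cycle, discontinued, stopped*) → ENDS-ON; administration
triggers (*received, given, administered, on, treated with*) →
CONTAINS; precedence BEGINS-ON > ENDS-ON > CONTAINS, because start/stop
statements are more specific than administration statements. Two
negative guards keep Cartesian pairing honest:

* a detectable time expression *between* the pair forces NONE (a drug is
  never linked past a nearer date to a farther one);
* a sentence boundary between the pair forces NONE, except the
  `<event> … Last dose : <time>` pattern, where the event precedes a
  time expression directly preceded by an end trigger.

Trigger scanning is restricted to the sentence fragments adjacent to the
pair (six tokens before the earlier mention, three after the later one),
so triggers from neighboring statements cannot leak in.

A separate, optional **date-heading rule** (`apply_date_heading_rule()`,
on by default in the rule pipeline, off for model pipelines) handles the
common formatting where a date or date range is a subsection heading
(`"July 2055:"`) and every event until the next heading belongs to it;
each section event is paired with each heading date as a CONTAINS
candidate. Heading-formatted sections are a dominant false-negative
source for window classifiers, which is why the rule exists and why the
generator can simulate the phenomenon.

## Trainable stand-ins

The trainable tagger and relation classifier are ridge-penalized
multinomial logistic models (glmnet) over sparse indicator features.
They exist so the pipeline's architecture — train on gold annotations,
predict, summarize — is exercised end to end on a CPU in seconds; a
finetuned neural encoder can be substituted through the plug-in
contracts without touching any other stage. Numerical notes:

* Fits use an explicit descending lambda path ending at the requested
  penalty (default `1e-2`); glmnet's automatic path is poorly scaled
  for pure ridge (`alpha = 0`) and can diverge at a single small
  lambda.
* Unobserved BIO classes are dropped before fitting (single-token drug
  names mean "I" may never occur).
* Relation features: bag of tokens between and before the pair, marker
  order, bucketed token distance, trigger indicators, and a
  sentence-boundary flag. NONE negatives are synthesized from unlabeled
  in-window pairs, downsampled to twice the positive count under the
  configuration seed.
* Everything is deterministic given the data and seed; two training
  runs produce identical predictions.

## Evaluation conventions

Both timelines are mapped to sets of `(event, relation, date)` keys;
for the relaxed settings dates are first truncated
(`truncate_date()`), and sets are deduplicated after truncation.
Documented decisions, fixed here because community evaluators differ on
(or do not publish) these conventions:

* both timelines empty → (1, 1, 1): a correct "no SACT" prediction is
  not penalized; exactly one empty → (0, 0, 0);
* the relation label is always part of the match key, at every
  granularity;
* a coarse date (`"2055"`) under a finer granularity matches only the
  identical coarse value — string equality after truncation is
  deterministic and symmetric;
* STRICT and relaxed-to-day differ only for coarse-dated entries:
  STRICT compares the full value verbatim, DAY truncates (identity for
  day-granularity values);
* aggregate F1 is *not* guaranteed monotone across granularities
  because truncation merges entries; the per-entry guarantee (a strict
  match stays matched after truncation) is property-tested instead.

## The synthetic generator

`generate_corpus()` emulates the structure of an annotated oncology
corpus: multi-patient, multi-note charts describing drug regimens in
cycles (default interval 21 days, the usual 3-week cycle spacing), with
begin/administration/end statements in templated clinical phrasings,
absolute dates in three notations, deictic and offset dates, date-headed
subsections, hedged treatment statements, and cross-disease confounder
sentences. Dates are drawn from 2010–2060 so nothing resembles real
PHI. Alongside the notes it emits gold standoff mentions, gold pairwise
TLINKs, and the gold timelines implied by them; by construction every
gold TLINK's time expression normalizes to its timeline date, so the
pipeline run with gold mentions and gold labels reproduces the gold
timelines exactly at any noise level — the oracle-identity property the
test suite asserts.

Noise semantics (`noise_config()`):

* `p_hedge` renders an administration fact in uncertainty phrasing
  ("We had attempted to treat him with …") that contains no trigger.
  Hedged facts keep their gold TLINK and timeline entry — uncertainty
  blocks *extraction*, not annotation — so increasing `p_hedge`
  depresses rule-pipeline recall, mirroring the hedging row of the
  error taxonomy this generator models.
* `p_heading` moves administration facts into month-granularity heading
  sections; with the heading rule disabled these become recall losses.
* `p_confounder` adds an annotated-free sentence with a non-target
  disease drug and a date (a precision hazard: the drug string is in
  the lexicon).
* `p_relative_date` renders dates as deictic/offset expressions when
  the note's DocTime allows it.

What the generator does **not** emulate — and hence what green tests do
not certify about real notes: real lexical variety and misspellings,
abbreviation ambiguity, brand/generic synonymy (Arimidex vs
anastrozole stay distinct events), regimen-to-component expansion
(FOLFOX is one event, never oxaliplatin + 5-FU + leucovorin),
coreference, interval semantics ("July through December" is two
endpoint mentions, not an expanded range), and DocTime-relative event
classification. Scores on generated corpora are upper bounds that
validate mechanics, not clinical performance.

## Problem sizes and runtime

The shipped tests and the acceptance script use desk-scale corpora
chosen to finish in minutes on one CPU while still exercising every
phenomenon: 50 patients × 5 notes for the clean end-to-end run, 25/10
patients for train/held-out splits of the learned components, 10 seeds
× 3 noise levels for the degradation sweeps, 1,000 random timeline
pairs against the brute-force comparison oracle, and 500 random mention
layouts against the brute-force pairer.

## Known limitations

* The time grammar covers the pattern classes above only; two-digit
  years, seasons, durations, and quantified intervals normalize to
  unknown by design.
* Slash dates are read month-first (US convention) — day-first corpora
  need a pattern-table override.
* "last week" resolves to DocTime − 7 days at day granularity rather
  than an ISO week interval: the final timeline needs point dates.
* The rule classifier's guards assume dates accompany their statements;
  prose that separates a drug from its date by several dated sentences
  is deliberately left unlinked.
* Event strings are normalized by lowercasing only; no synonym mapping.
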