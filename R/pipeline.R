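#' Configuration for the end-to-end extraction pipeline
#'
#' Two regimes mirror the two evaluation settings of the timeline task:
#' `"subtask1"` consumes gold EVENT/TIMEX3 mentions (supplied as an
#' annotations list) and only classifies and summarizes; `"subtask2"` is
#' fully automatic, running a mention tagger and the time-expression
#' grammar first. Both share the windowing, classification,
#' normalization, and summarization path.
#'
#' @param regime `"subtask1"` or `"subtask2"`.
#' @param tagger `"lexicon"` or `"model"` (subtask2 only).
#' @param tagger_model A `sact_tagger`, required when `tagger = "model"`.
#' @param lexicon Lexicon for the dictionary tagger.
#' @param classifier `"rules"`, `"model"`, `"oracle"` (gold TLINK labels;
#'   requires annotations), or a plug-in function.
#' @param relation_model A `sact_relation_model` when
#'   `classifier = "model"`.
#' @param window A [window_config()].
#' @param heading_rule Whether to add date-subsection-heading CONTAINS
#'   candidates; defaults to `TRUE` for the rule classifier and `FALSE`
#'   otherwise.
#' @param seed Integer seed for any stochastic component.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(regime = c("subtask2", "subtask1"),
                            tagger = c("lexicon", "model"),
                            tagger_model = NULL,
                            lexicon = sact_lexicon(),
                            classifier = "rules",
                            relation_model = NULL,
                            window = window_config(),
                            heading_rule = NULL,
                            seed = 1L) {
  regime <- match.arg(regime)
  tagger <- match.arg(tagger)
  if (is.null(heading_rule)) heading_rule <- identical(classifier, "rules")
  structure(list(regime = regime, tagger = tagger,
                 tagger_model = tagger_model, lexicon = lexicon,
                 classifier = classifier, relation_model = relation_model,
                 window = window, heading_rule = heading_rule,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the timeline extraction pipeline over a corpus
#'
#' Orchestrates mention acquisition (gold or automatic), pairwise window
#' generation, relation classification, date-heading candidates, time
#' normalization, and patient-level summarization, returning the
#' timelines and a run report with per-stage counts satisfying the
#' conservation identities `pairs = labeled_none + labeled_non_none` and
#' `triples = kept + dropped_unknown_date + dropped_label`.
#'
#' @param notes Notes tibble (`patient_id`, `note_id`, `doctime`,
#'   `text`), or a `sact_corpus` (its gold annotations are used when the
#'   regime needs them).
#' @param config A [pipeline_config()].
#' @param annotations Gold annotations (list with `mentions` and
#'   `tlinks`) for subtask1 or the oracle classifier.
#' @return A list: `timelines` and `report` (class `sact_run_report`).
#' @export
run_pipeline <- function(notes, config = pipeline_config(),
                         annotations = NULL) {
  if (inherits(notes, "sact_corpus")) {
    annotations <- annotations %||%
      list(mentions = notes$mentions, tlinks = notes$tlinks)
    notes <- notes$notes
  }
  assert_cols(notes, c("patient_id", "note_id", "doctime", "text"),
              "`notes`")
  needs_gold <- config$regime == "subtask1" ||
    identical(config$classifier, "oracle")
  if (needs_gold && is.null(annotations)) {
    abort(sprintf("regime '%s' requires gold annotations", config$regime))
  }
  set.seed(config$seed)

  if (config$regime == "subtask1") {
    mentions <- annotations$mentions
    events <- dplyr::filter(mentions, .data$mention_type == "EVENT")
    timexes <- dplyr::filter(mentions, .data$mention_type == "TIMEX3")
  } else {
    events <- if (config$tagger == "lexicon") {
      tag_events_lexicon(notes, config$lexicon)
    } else {
      if (is.null(config$tagger_model)) {
        abort("tagger = 'model' requires `tagger_model`")
      }
      tag_events_model(notes, config$tagger_model)
    }
    timexes <- detect_timex(notes)
  }

  instances <- make_window_instances(notes, events, timexes, config$window)
  labeled <- if (identical(config$classifier, "oracle")) {
    label_with_gold(instances, annotations$tlinks)
  } else {
    classify_relations(instances, config$classifier, config$relation_model)
  }
  n_pairs <- nrow(labeled)
  n_none <- sum(labeled$label == "NONE")

  heading <- NULL
  if (isTRUE(config$heading_rule)) {
    heading <- apply_date_heading_rule(notes, events)
  }
  n_heading <- if (is.null(heading)) 0L else nrow(heading)
  combined <- dplyr::bind_rows(
    dplyr::filter(labeled, .data$label != "NONE"),
    heading
  )

  triples <- assemble_triples(combined, notes)
  timelines <- summarize_timelines(triples,
                                   patients = unique(notes$patient_id))
  drops <- attr(timelines, "drop_counts")
  report <- structure(list(
    n_notes = nrow(notes),
    n_patients = dplyr::n_distinct(notes$patient_id),
    n_event_mentions = nrow(events),
    n_timex_mentions = nrow(timexes),
    pairs_in = n_pairs,
    labeled_none = n_none,
    labeled_non_none = n_pairs - n_none,
    heading_candidates = n_heading,
    triples_in = nrow(triples),
    dropped_unknown_date = unname(drops[["unknown_date"]]),
    dropped_label = unname(drops[["dropped_label"]]),
    kept = nrow(triples) - unname(drops[["unknown_date"]]) -
      unname(drops[["dropped_label"]]),
    final_entries = nrow(timelines)
  ), class = "sact_run_report")
  list(timelines = timelines, report = report)
}

#' @export
print.sact_run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  for (nm in names(x)) cat(sprintf("  %-22s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Serialize and restore a run report
#'
#' @param report A `sact_run_report`.
#' @param path JSON file path.
#' @return `read_run_report()` returns the restored report.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  x <- jsonlite::read_json(path)
  structure(lapply(x, as.integer), class = "sact_run_report")
}
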