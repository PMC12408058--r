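#' Assemble instance-level triples from labeled instances
#'
#' Converts each non-NONE labeled instance into a raw
#' `<event, relation, time>` triple: the event text is lowercased and the
#' time expression is normalized against the note's document creation
#' time. Times the normalizer cannot resolve pass through as `NA` dates
#' for the summarizer to drop (and count).
#'
#' @param instances A labeled instance tibble (with `label`).
#' @param notes The notes tibble (`patient_id`, `note_id`, `doctime`).
#' @return A tibble of raw triples: `patient_id`, `note_id`, `event_text`,
#'   `label`, `date`.
#' @export
assemble_triples <- function(instances, notes) {
  assert_cols(notes, c("patient_id", "note_id", "doctime"), "`notes`")
  if (nrow(instances) == 0) {
    return(tibble::tibble(patient_id = character(), note_id = character(),
                          event_text = character(), label = character(),
                          date = character()))
  }
  assert_cols(instances, c("note_id", "event_surface", "timex_surface",
                           "label"), "`instances`")
  kept <- dplyr::filter(instances, .data$label != "NONE")
  kept <- dplyr::left_join(
    kept, dplyr::select(notes, "patient_id", "note_id", "doctime"),
    by = "note_id"
  )
  tibble::tibble(
    patient_id = kept$patient_id,
    note_id = kept$note_id,
    event_text = tolower(kept$event_surface),
    label = kept$label,
    date = normalize_timex(kept$timex_surface, kept$doctime)
  )
}

#' Summarize raw triples into one patient's timeline
#'
#' Deduplication and conflict resolution for a single patient:
#' unresolvable (`NA`) dates are dropped, OVERLAP and BEFORE labels are
#' dropped (they carry no anchorable point-date semantics for the final
#' timeline), CONTAINS is inverted to `contains-1` and BEGINS-ON/ENDS-ON
#' map to `begins-on`/`ends-on`, identical `(event, relation, date)`
#' entries are merged, and coexisting begin/end/administration entries
#' for the same event and date are all kept (restarts and same-day
#' start-plus-administration statements are clinically real). Entries are
#' sorted by event then date.
#'
#' @param triples Raw triples from [assemble_triples()], all with one
#'   `patient_id`.
#' @return A timeline tibble: `patient_id`, `event`, `relation`, `date`.
#' @export
summarize_patient <- function(triples) {
  assert_cols(triples, c("patient_id", "event_text", "label", "date"),
              "`triples`")
  if (dplyr::n_distinct(triples$patient_id) > 1) {
    abort("summarize_patient() received triples from multiple patients")
  }
  summarize_timelines(triples)
}

#' Summarize raw triples into patient timelines
#'
#' Applies [summarize_patient()]'s rules per patient. Patients present in
#' `patients` but contributing no surviving entries are retained in the
#' `"patients"` attribute so that empty timelines round-trip through
#' [write_timelines()] and are scored by [evaluate_timelines()].
#'
#' @param triples Raw triples for any number of patients.
#' @param patients Optional character vector of the full patient universe.
#' @return A timeline tibble with attribute `"patients"`, plus attribute
#'   `"drop_counts"` (named counts of dropped unknown-date and
#'   OVERLAP/BEFORE triples).
#' @export
summarize_timelines <- function(triples, patients = NULL) {
  assert_cols(triples, c("patient_id", "event_text", "label", "date"),
              "`triples`")
  n_unknown <- sum(is.na(triples$date))
  kept <- dplyr::filter(triples, !is.na(.data$date))
  n_label <- sum(kept$label %in% c("OVERLAP", "BEFORE"))
  kept <- dplyr::mutate(kept, relation = tlink_to_relation(.data$label))
  kept <- dplyr::filter(kept, !is.na(.data$relation))
  out <- kept |>
    dplyr::transmute(.data$patient_id, event = tolower(.data$event_text),
                     .data$relation, .data$date) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$patient_id, .data$event, .data$date,
                   .data$relation)
  attr(out, "patients") <- sort(union(patients %||% character(),
                                      unique(triples$patient_id)))
  attr(out, "drop_counts") <- c(unknown_date = n_unknown,
                                dropped_label = n_label)
  out
}
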