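#' Read a corpus of clinical notes from a manifest
#'
#' The on-disk corpus layout is a tab-separated manifest with columns
#' `patient_id`, `note_id`, `doctime`, `path`, plus one UTF-8 plain-text
#' file per note (paths resolved relative to the manifest). The document
#' creation time must be ISO `"YYYY-MM-DD"`; any other dialect is an
#' error. Notes are returned ordered by patient, then doctime, then
#' note id.
#'
#' @param path Path to the manifest file, or to a directory containing
#'   `notes.tsv`.
#' @return A tibble of notes: `patient_id`, `note_id`, `doctime` (`Date`),
#'   `text`.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "notes.tsv")
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  manifest <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  assert_cols(manifest, c("patient_id", "note_id", "doctime", "path"),
              "manifest")
  if (nrow(manifest) == 0) {
    return(tibble::tibble(patient_id = character(), note_id = character(),
                          doctime = as.Date(character()), text = character()))
  }
  dup <- duplicated(manifest[c("patient_id", "note_id")])
  if (any(dup)) {
    abort(sprintf("duplicate (patient_id, note_id): (%s, %s)",
                  manifest$patient_id[dup][1], manifest$note_id[dup][1]))
  }
  bad <- !stringr::str_detect(manifest$doctime, "^\\d{4}-\\d{2}-\\d{2}$")
  doctime <- as.Date(manifest$doctime, format = "%Y-%m-%d")
  bad <- bad | is.na(doctime)
  if (any(bad)) {
    abort(sprintf(
      "unparseable doctime %s for note %s (expected ISO YYYY-MM-DD)",
      manifest$doctime[bad][1], manifest$note_id[bad][1]))
  }
  files <- file.path(dirname(path), manifest$path)
  missing <- !file.exists(files)
  if (any(missing)) {
    abort(sprintf("missing note file for note %s: %s",
                  manifest$note_id[missing][1], files[missing][1]))
  }
  text <- purrr::map_chr(files, function(f) {
    paste(readr::read_lines(f, progress = FALSE), collapse = "\n")
  })
  tibble::tibble(
    patient_id = manifest$patient_id, note_id = manifest$note_id,
    doctime = doctime, text = text
  ) |>
    dplyr::arrange(.data$patient_id, .data$doctime, .data$note_id)
}

#' Write a corpus (and optional gold data) to a directory
#'
#' Inverse of [read_corpus()]: writes `notes.tsv` plus one text file per
#' note under `txt/`, and optionally the standoff annotations and gold
#' timelines alongside.
#'
#' @param notes A notes tibble (`patient_id`, `note_id`, `doctime`, `text`).
#' @param dir Output directory (created if needed).
#' @param annotations Optional list with `mentions` and `tlinks` tibbles,
#'   written to `annotations.json` via [write_annotations()].
#' @param timelines Optional timeline tibble, written to `timelines.json`
#'   via [write_timelines()].
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(notes, dir, annotations = NULL, timelines = NULL) {
  assert_cols(notes, c("patient_id", "note_id", "doctime", "text"), "`notes`")
  dir.create(file.path(dir, "txt"), recursive = TRUE, showWarnings = FALSE)
  rel <- file.path("txt", paste0(notes$note_id, ".txt"))
  purrr::walk2(notes$text, file.path(dir, rel), function(txt, f) {
    writeLines(txt, f, useBytes = TRUE)
  })
  manifest <- tibble::tibble(
    patient_id = notes$patient_id, note_id = notes$note_id,
    doctime = format(notes$doctime, "%Y-%m-%d"), path = rel
  )
  readr::write_tsv(manifest, file.path(dir, "notes.tsv"), progress = FALSE)
  if (!is.null(annotations)) {
    write_annotations(annotations, file.path(dir, "annotations.json"))
  }
  if (!is.null(timelines)) {
    write_timelines(timelines, file.path(dir, "timelines.json"))
  }
  invisible(dir)
}

#' Read standoff annotations for a loaded corpus
#'
#' Annotations are a JSON object keyed by note id; each note holds
#' `mentions` (records `id`, `type`, `start`, `end` with 0-based half-open
#' character spans) and `tlinks` (records `event_id`, `timex_id`, `label`).
#' Spans are validated against the note text and mention surfaces are
#' materialized from it, so the surface-equals-slice invariant holds by
#' construction. TLINK labels outside the pairwise label set
#' (CONTAINS, BEGINS-ON, ENDS-ON, OVERLAP, BEFORE) and references to
#' unknown mention ids are hard errors.
#'
#' @param path Path to the annotations JSON file.
#' @param notes The notes tibble the annotations refer to.
#' @return A list with tibbles `mentions` (`note_id`, `mention_id`,
#'   `mention_type`, `start`, `end`, `surface`) and `tlinks` (`note_id`,
#'   `event_id`, `timex_id`, `label`).
#' @export
read_annotations <- function(path, notes) {
  assert_cols(notes, c("note_id", "text"), "`notes`")
  raw <- jsonlite::read_json(path)
  mentions <- list(); tlinks <- list()
  for (nid in names(raw)) {
    if (!nid %in% notes$note_id) {
      abort(sprintf("annotations reference unknown note_id %s", nid))
    }
    text <- notes$text[match(nid, notes$note_id)]
    ms <- purrr::map(raw[[nid]]$mentions, function(m) {
      tibble::tibble(note_id = nid, mention_id = as.character(m$id),
                     mention_type = as.character(m$type),
                     start = as.integer(m$start), end = as.integer(m$end))
    })
    ms <- dplyr::bind_rows(ms)
    if (nrow(ms) > 0) {
      bad_type <- !ms$mention_type %in% c("EVENT", "TIMEX3")
      if (any(bad_type)) {
        abort(sprintf("mention %s in note %s has unknown type %s",
                      ms$mention_id[bad_type][1], nid,
                      ms$mention_type[bad_type][1]))
      }
      oob <- ms$start < 0 | ms$start >= ms$end | ms$end > nchar(text)
      if (any(oob)) {
        abort(sprintf("mention %s in note %s has out-of-bounds span [%d,%d)",
                      ms$mention_id[oob][1], nid, ms$start[oob][1],
                      ms$end[oob][1]))
      }
      ms$surface <- slice_span(text, ms$start, ms$end)
      mentions[[nid]] <- ms
    }
    tl <- purrr::map(raw[[nid]]$tlinks, function(t) {
      tibble::tibble(note_id = nid, event_id = as.character(t$event_id),
                     timex_id = as.character(t$timex_id),
                     label = as.character(t$label))
    })
    tl <- dplyr::bind_rows(tl)
    if (nrow(tl) > 0) {
      bad_lab <- !tl$label %in% TLINK_LABELS
      if (any(bad_lab)) {
        abort(sprintf("TLINK in note %s has label %s outside the label set",
                      nid, tl$label[bad_lab][1]))
      }
      known <- if (is.null(mentions[[nid]])) character() else
        mentions[[nid]]$mention_id
      bad_ref <- !(tl$event_id %in% known) | !(tl$timex_id %in% known)
      if (any(bad_ref)) {
        abort(sprintf("TLINK in note %s references unknown mention id", nid))
      }
      tlinks[[nid]] <- tl
    }
  }
  mentions <- dplyr::bind_rows(mentions)
  if (nrow(mentions) == 0) mentions <- empty_mentions()
  tlinks <- dplyr::bind_rows(tlinks)
  if (nrow(tlinks) == 0) {
    tlinks <- tibble::tibble(note_id = character(), event_id = character(),
                             timex_id = character(), label = character())
  }
  list(mentions = mentions, tlinks = tlinks)
}

#' @rdname read_annotations
#' @param annotations A list with `mentions` and `tlinks` tibbles.
#' @export
write_annotations <- function(annotations, path) {
  mentions <- annotations$mentions
  tlinks <- annotations$tlinks
  nids <- unique(c(mentions$note_id, tlinks$note_id))
  out <- setNames(purrr::map(nids, function(nid) {
    ms <- dplyr::filter(mentions, .data$note_id == nid)
    tl <- dplyr::filter(tlinks, .data$note_id == nid)
    list(
      mentions = purrr::pmap(
        ms[c("mention_id", "mention_type", "start", "end")],
        function(mention_id, mention_type, start, end) {
          list(id = mention_id, type = mention_type, start = start, end = end)
        }),
      tlinks = purrr::pmap(
        tl[c("event_id", "timex_id", "label")],
        function(event_id, timex_id, label) {
          list(event_id = event_id, timex_id = timex_id, label = label)
        })
    )
  }), nids)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read and write patient timeline files
#'
#' Timelines are exchanged as a JSON object mapping each patient id to a
#' list of three-element `[event, relation, date]` records. Only the
#' summarized relation vocabulary (`contains-1`, `begins-on`, `ends-on`)
#' is allowed, events must be nonempty lowercase strings, and dates must
#' be valid `"YYYY"`, `"YYYY-MM"`, or `"YYYY-MM-DD"` values; anything else
#' is a hard error naming the offending record. A patient may be present
#' with an empty list. Writing then reading is the identity.
#'
#' @param path Path of the timelines JSON file.
#' @return For `read_timelines()`, a tibble (`patient_id`, `event`,
#'   `relation`, `date`) carrying the full patient universe (including
#'   patients with empty timelines) in attribute `"patients"`.
#' @export
read_timelines <- function(path) {
  raw <- jsonlite::read_json(path)
  entries <- purrr::imap(raw, function(lst, pid) {
    if (length(lst) == 0) return(NULL)
    rows <- purrr::map(lst, function(e) {
      if (length(e) != 3) {
        abort(sprintf("patient %s: timeline record does not have 3 elements",
                      pid))
      }
      tibble::tibble(patient_id = pid, event = as.character(e[[1]]),
                     relation = as.character(e[[2]]),
                     date = as.character(e[[3]]))
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(entries)
  if (nrow(out) == 0) out <- empty_timeline()
  validate_timeline_entries(out)
  attr(out, "patients") <- names(raw) %||% character()
  out
}

#' @rdname read_timelines
#' @param timelines A timeline tibble (`patient_id`, `event`, `relation`,
#'   `date`).
#' @param patients Optional character vector of all patient ids to emit
#'   (so patients with empty timelines appear with an empty list).
#'   Defaults to attribute `"patients"` of `timelines`, or the patients
#'   present in it.
#' @export
write_timelines <- function(timelines, path, patients = NULL) {
  validate_timeline_entries(timelines)
  patients <- patients %||% attr(timelines, "patients") %||%
    unique(timelines$patient_id)
  patients <- union(patients, timelines$patient_id)
  out <- setNames(purrr::map(patients, function(pid) {
    e <- dplyr::filter(timelines, .data$patient_id == pid)
    purrr::pmap(e[c("event", "relation", "date")],
                function(event, relation, date) list(event, relation, date))
  }), patients)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

validate_timeline_entries <- function(timelines) {
  assert_cols(timelines, c("patient_id", "event", "relation", "date"),
              "`timelines`")
  if (nrow(timelines) == 0) return(invisible(timelines))
  bad <- !timelines$relation %in% TIMELINE_RELATIONS
  if (any(bad)) {
    abort(sprintf(
      "patient %s: relation '%s' not in {contains-1, begins-on, ends-on}",
      timelines$patient_id[bad][1], timelines$relation[bad][1]))
  }
  bad <- is.na(timelines$event) | timelines$event == "" |
    timelines$event != tolower(timelines$event)
  if (any(bad)) {
    abort(sprintf("patient %s: event '%s' must be nonempty and lowercase",
                  timelines$patient_id[bad][1], timelines$event[bad][1]))
  }
  ok_date <- valid_normalized_date(timelines$date)
  if (any(!ok_date)) {
    abort(sprintf("patient %s: '%s' is not a valid normalized date",
                  timelines$patient_id[!ok_date][1],
                  timelines$date[!ok_date][1]))
  }
  invisible(timelines)
}

valid_normalized_date <- function(date) {
  !is.na(date) & (
    stringr::str_detect(date, "^\\d{4}$") |
      (stringr::str_detect(date, "^\\d{4}-\\d{2}$") &
         as.integer(substr(date, 6, 7)) %in% 1:12) |
      (stringr::str_detect(date, "^\\d{4}-\\d{2}-\\d{2}$") &
         !is.na(as.Date(date, format = "%Y-%m-%d")))
  )
}
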