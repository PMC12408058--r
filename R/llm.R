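STEP1_SYSTEM <- paste(
  "You are a helpful assistant for oncologists.",
  "You will read the given PATIENT EHR and summarize the patient's",
  "chemotherapy treatment TIMELINES.",
  "Please only output TIMELINES in the requested format.",
  "Please do not include any other text or reasoning, do not include",
  "timelines for any other treatments besides chemotherapy.",
  "Please do not use any labels other than the ones given in the",
  "examples, i.e., BEGINS-ON, ENDS-ON, CONTAINS.",
  "Here are some examples.")

STEP2_SYSTEM <- paste(
  "You are asked to decide the date of a time expression.",
  'If today was %s, what would the date of "%s" be?',
  'Please only output the date in the format of "YYYY-MM-DD".',
  'Answer "Unknown" if you don\'t know.',
  "Here are some examples.")

STEP1_WHITELIST <- c("BEGINS-ON", "ENDS-ON", "CONTAINS")

read_exemplars <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  inp <- stringr::str_match(lines, "^Input: (.*)$")[, 2]
  out <- stringr::str_match(lines, "^Output: (.*)$")[, 2]
  tibble::tibble(input = inp[!is.na(inp)], output = out[!is.na(out)])
}

#' Few-shot prompt templates for the two prompting steps
#'
#' Step 1 extracts `<event, relation, time>` triples from one sentence;
#' its template embeds 4 exemplars for each of the three whitelisted
#' relation labels (12 in total). Step 2 resolves one time expression
#' against the document creation time; its template embeds 5 exemplars.
#' Exemplars ship as editable plain-text fixture files (`Input:` /
#' `Output:` line pairs) of synthetic sentences; pass your own file to
#' replace them. Deviating exemplar counts are an error.
#'
#' @param step 1 or 2.
#' @param exemplars_path Optional path to an exemplar file.
#' @return A list of class `prompt_template`.
#' @export
prompt_template <- function(step, exemplars_path = NULL) {
  stopifnot(step %in% c(1L, 2L))
  path <- exemplars_path %||% system.file(
    "extdata", sprintf("exemplars_step%d.txt", step),
    package = "oncotimelines")
  ex <- read_exemplars(path)
  if (step == 1L) {
    labels <- toupper(stringr::str_match(
      ex$output, "'\\s*,\\s*'([^']+)'\\s*,")[, 2])
    labels[labels %in% c("CONTAINS-1", "CONTAINS")] <- "CONTAINS"
    counts <- table(factor(labels, levels = STEP1_WHITELIST))
    if (nrow(ex) != 12 || any(counts != 4)) {
      abort("step-1 template requires 4 exemplars per label (12 total)")
    }
  } else if (nrow(ex) != 5) {
    abort("step-2 template requires 5 exemplars")
  }
  structure(list(step = step, exemplars = ex,
                 label_whitelist = if (step == 1L) STEP1_WHITELIST else NULL),
            class = "prompt_template")
}

render_exemplars <- function(ex) {
  paste(sprintf("Input: %s\nOutput: %s", ex$input, ex$output),
        collapse = "\n\n")
}

#' Build the step-1 (triple extraction) prompt for one sentence
#'
#' @param sentence One complete sentence containing at least one SACT
#'   event mention.
#' @param template A step-1 [prompt_template()].
#' @return The prompt string.
#' @export
build_step1_prompt <- function(sentence, template = prompt_template(1L)) {
  stopifnot(inherits(template, "prompt_template"), template$step == 1L)
  paste0(STEP1_SYSTEM, "\n\n", render_exemplars(template$exemplars),
         "\n\nInput: ", sentence, "\nOutput:")
}

#' Build the step-2 (time normalization) prompt
#'
#' @param timex_surface The time expression to resolve.
#' @param doctime The note's document creation time (`Date`).
#' @param template A step-2 [prompt_template()].
#' @return The prompt string.
#' @export
build_step2_prompt <- function(timex_surface, doctime,
                               template = prompt_template(2L)) {
  stopifnot(inherits(template, "prompt_template"), template$step == 2L)
  head <- sprintf(STEP2_SYSTEM, format(doctime, "%Y-%m-%d"), timex_surface)
  paste0(head, "\n\n", render_exemplars(template$exemplars),
         "\n\nInput: If today was ", format(doctime, "%Y-%m-%d"),
         ', what would the date of "', timex_surface, '" be?\nOutput:')
}

#' Select the complete sentences that contain event mentions
#'
#' Splits a note into sentences on `.`, `!`, `?`, and newline, guarding
#' common abbreviations (Dr., Mr., Ms., vs., e.g., i.e., No.) and never
#' placing a boundary inside a mention span. Returns each sentence
#' containing at least one EVENT mention, once.
#'
#' @param notes Notes tibble (`note_id`, `text`).
#' @param events EVENT mention tibble.
#' @return A tibble: `note_id`, `sentence_id`, `start`, `end`, `text`.
#' @export
select_sentences <- function(notes, events) {
  assert_cols(notes, c("note_id", "text"), "`notes`")
  out <- purrr::map2(notes$note_id, notes$text, function(nid, text) {
    ev <- dplyr::filter(events, .data$note_id == nid)
    if (nrow(ev) == 0) return(NULL)
    bounds <- sentence_bounds(text, ev)
    sent <- tibble::tibble(
      start = bounds$start, end = bounds$end,
      text = stringr::str_trim(slice_span(text, bounds$start, bounds$end))
    )
    has_event <- purrr::map_lgl(seq_len(nrow(sent)), function(i) {
      any(ev$start >= sent$start[i] & ev$end <= sent$end[i])
    })
    sent <- sent[has_event & sent$text != "", , drop = FALSE]
    if (nrow(sent) == 0) return(NULL)
    sent$note_id <- nid
    sent
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(note_id = character(), sentence_id = character(),
                          start = integer(), end = integer(),
                          text = character()))
  }
  out <- dplyr::distinct(out, .data$note_id, .data$text, .keep_all = TRUE)
  tibble::tibble(note_id = out$note_id,
                 sentence_id = paste0("s", seq_len(nrow(out))),
                 start = out$start, end = out$end, text = out$text)
}

ABBREVIATIONS <- c("Dr", "Mr", "Mrs", "Ms", "vs", "e.g", "i.e", "No")

sentence_bounds <- function(text, mentions) {
  term <- stringr::str_locate_all(text, "[.!?\n]")[[1]]
  if (nrow(term) == 0) {
    return(tibble::tibble(start = 0L, end = nchar(text)))
  }
  pos <- term[, 1]  # 1-based position of the terminator
  ok <- purrr::map_lgl(pos, function(p) {
    ch <- substr(text, p, p)
    if (ch == ".") {
      prev <- substr(text, max(1, p - 4), p - 1)
      if (any(stringr::str_detect(
        prev, paste0("(^|\\s)", stringr::str_replace_all(ABBREVIATIONS,
                                                         "\\.", "\\\\."),
               "$")))) {
        return(FALSE)
      }
    }
    # never split inside a mention span (0-based half-open)
    !any(mentions$start < p & mentions$end > p - 1)
  })
  cuts <- pos[ok]
  starts <- c(0L, cuts)
  ends <- c(cuts, nchar(text))
  keep <- starts < ends
  tibble::tibble(start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]))
}

#' Parse a step-1 completion into triple candidates
#'
#' Total parser for the list-of-triples output syntax
#' (`['taxol', 'contains-1', '2013-08-08']`, one per line, quotes
#' optional). Labels are case-folded; a `contains` label in
#' `<event, relation, time>` order has the wrong directionality for the
#' output convention and is corrected to `contains-1` (idempotent);
#' labels outside `{contains-1, contains, begins-on, ends-on}` and lines
#' that do not parse are dropped and counted, never raised.
#'
#' @param completion The raw completion string.
#' @return A list: `triples` (tibble `event`, `relation`, `time_surface`),
#'   `n_lines`, `n_dropped`, `n_corrected`, `dropped` (the unparsed or
#'   off-whitelist lines).
#' @export
parse_step1_output <- function(completion) {
  lines <- stringr::str_split(completion %||% "", "\n")[[1]]
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != ""]
  rx <- paste0("\\[\\s*['\"]?([^'\",\\]]+?)['\"]?\\s*,",
               "\\s*['\"]?([^'\",\\]]+?)['\"]?\\s*,",
               "\\s*['\"]?([^'\"\\]]+?)['\"]?\\s*\\]")
  m <- stringr::str_match(lines, rx)
  parsed <- !is.na(m[, 1])
  event <- stringr::str_trim(tolower(m[, 2]))
  relation <- stringr::str_trim(tolower(m[, 3]))
  time_surface <- stringr::str_trim(m[, 4])
  corrected <- parsed & relation == "contains"
  relation[corrected] <- "contains-1"
  keep <- parsed & relation %in% TIMELINE_RELATIONS & event != "" &
    time_surface != ""
  dropped <- lines[!keep]
  list(
    triples = tibble::tibble(event = event[keep],
                             relation = relation[keep],
                             time_surface = time_surface[keep]),
    n_lines = length(lines),
    n_dropped = sum(!keep),
    n_corrected = sum(corrected & keep),
    dropped = dropped
  )
}

#' Parse a step-2 completion into a normalized date
#'
#' Accepts the first well-formed `YYYY-MM-DD`, `YYYY-MM`, or `YYYY` token
#' anywhere in the completion; `"Unknown"` or no match yields `NA`.
#' Total: never raises.
#'
#' @param completion The raw completion string.
#' @return A normalized date string or `NA`.
#' @export
parse_step2_output <- function(completion) {
  x <- completion %||% ""
  # lookarounds keep fragments of malformed tokens (e.g. "2013-13-40")
  # from being read as coarser dates
  for (rx in c("\\b\\d{4}-\\d{2}-\\d{2}\\b(?!-)",
               "\\b\\d{4}-\\d{2}\\b(?!-)",
               "(?<![-\\d])(19|20)\\d{2}\\b(?!-)")) {
    hit <- stringr::str_extract(x, rx)
    if (!is.na(hit) && valid_normalized_date(hit)) return(hit)
  }
  NA_character_
}

#' Run the two-step prompting pipeline over a corpus
#'
#' For every event-bearing sentence: build the step-1 prompt, call the
#' backend, and parse triples; for every triple, normalize its time
#' expression with a step-2 prompt. The resulting triples feed the same
#' summarization path as the classifier pipeline. A backend exception is
#' recorded per sentence and the run continues.
#'
#' @param notes Notes tibble (`patient_id`, `note_id`, `doctime`, `text`).
#' @param events EVENT mentions used for sentence selection (gold or
#'   tagged).
#' @param backend A function `prompt -> completion string` (see
#'   [backend_gold_mock()] for a scripted example).
#' @param template1,template2 Step templates from [prompt_template()].
#' @return A list: `timelines` (tibble with the patient universe
#'   attribute) and `report` (prompt, drop, correction, and failure
#'   counts).
#' @export
run_llm_pipeline <- function(notes, events, backend,
                             template1 = prompt_template(1L),
                             template2 = prompt_template(2L)) {
  stopifnot(is.function(backend))
  assert_cols(notes, c("patient_id", "note_id", "doctime", "text"),
              "`notes`")
  sentences <- select_sentences(notes, events)
  n_prompts <- 0L; n_failures <- 0L
  n_lines <- 0L; n_dropped <- 0L; n_corrected <- 0L
  triple_rows <- list()
  for (i in seq_len(nrow(sentences))) {
    note <- notes[match(sentences$note_id[i], notes$note_id), ]
    prompt <- build_step1_prompt(sentences$text[i], template1)
    n_prompts <- n_prompts + 1L
    completion <- tryCatch(backend(prompt), error = function(e) NULL)
    if (is.null(completion)) {
      n_failures <- n_failures + 1L
      next
    }
    parsed <- parse_step1_output(completion)
    n_lines <- n_lines + parsed$n_lines
    n_dropped <- n_dropped + parsed$n_dropped
    n_corrected <- n_corrected + parsed$n_corrected
    tr <- parsed$triples
    if (nrow(tr) == 0) next
    tr$date <- purrr::map_chr(tr$time_surface, function(surf) {
      p2 <- build_step2_prompt(surf, note$doctime, template2)
      n_prompts <<- n_prompts + 1L
      comp2 <- tryCatch(backend(p2), error = function(e) NULL)
      if (is.null(comp2)) {
        n_failures <<- n_failures + 1L
        return(NA_character_)
      }
      parse_step2_output(comp2)
    })
    tr$patient_id <- note$patient_id
    tr$note_id <- note$note_id
    triple_rows[[length(triple_rows) + 1L]] <- tr
  }
  triples <- dplyr::bind_rows(triple_rows)
  raw <- if (nrow(triples) == 0) {
    tibble::tibble(patient_id = character(), event_text = character(),
                   label = character(), date = character())
  } else {
    tibble::tibble(
      patient_id = triples$patient_id,
      event_text = triples$event,
      label = relation_to_tlink(triples$relation),
      date = triples$date
    )
  }
  timelines <- summarize_timelines(raw, patients = unique(notes$patient_id))
  list(
    timelines = timelines,
    report = list(prompts_issued = n_prompts, step1_lines = n_lines,
                  parse_drops = n_dropped, corrections = n_corrected,
                  backend_failures = n_failures,
                  triples_kept = nrow(triples))
  )
}

#' A scripted mock backend that answers from gold annotations
#'
#' Builds a deterministic backend for testing and benchmarking the
#' prompting pipeline without any language model: step-1 prompts are
#' answered by looking up the input sentence in the corpus's gold TLINKs
#' (emitting the whitelisted triples whose two mentions lie inside the
#' sentence, in the list-of-triples syntax) and step-2 prompts by the
#' package's own grammar normalizer. With `reversed_contains = TRUE` the
#' mock emits the wrong-directionality `CONTAINS` label that the parser
#' is expected to correct; with `junk = TRUE` it emits unparseable text.
#'
#' @param corpus A `sact_corpus` from [generate_corpus()].
#' @param reversed_contains Emit `CONTAINS` instead of `CONTAINS-1`.
#' @param junk Emit unparseable completions for step 1.
#' @return A function `prompt -> completion`.
#' @export
backend_gold_mock <- function(corpus, reversed_contains = FALSE,
                              junk = FALSE) {
  stopifnot(inherits(corpus, "sact_corpus"))
  notes <- corpus$notes
  events <- dplyr::filter(corpus$mentions, .data$mention_type == "EVENT")
  sentences <- select_sentences(notes, events)
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(sentences))) {
    nid <- sentences$note_id[i]
    s0 <- sentences$start[i]; s1 <- sentences$end[i]
    ms <- dplyr::filter(corpus$mentions, .data$note_id == nid,
                        .data$start >= s0, .data$end <= s1)
    tl <- dplyr::filter(corpus$tlinks, .data$note_id == nid,
                        .data$event_id %in% ms$mention_id,
                        .data$timex_id %in% ms$mention_id,
                        .data$label %in% c("CONTAINS", "BEGINS-ON",
                                           "ENDS-ON"))
    if (nrow(tl) == 0) next
    lab <- ifelse(tl$label == "CONTAINS",
                  if (reversed_contains) "CONTAINS" else "CONTAINS-1",
                  tl$label)
    esurf <- tolower(ms$surface[match(tl$event_id, ms$mention_id)])
    tsurf <- ms$surface[match(tl$timex_id, ms$mention_id)]
    assign(sentences$text[i],
           paste(sprintf("['%s', '%s', '%s']", esurf, lab, tsurf),
                 collapse = "\n"),
           envir = lookup)
  }
  function(prompt) {
    m <- stringr::str_match_all(
      prompt, "Input: If today was (\\d{4}-\\d{2}-\\d{2}), what would the date of \"(.*)\" be\\?")[[1]]
    if (nrow(m) > 0) {
      # the final Input line is the query; earlier ones are exemplars
      val <- normalize_timex(m[nrow(m), 3], as.Date(m[nrow(m), 2]))
      return(if (is.na(val)) "Unknown" else val)
    }
    if (junk) return("no triples here, sorry!")
    last <- stringr::str_match_all(prompt, "Input: ([^\n]*)\n")[[1]]
    sent <- last[nrow(last), 2]
    get0(sent, envir = lookup, ifnotfound = "")
  }
}
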