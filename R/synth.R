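SACT_DISPLAY <- c(
  carboplatin = "carboplatin", taxol = "Taxol", folfox = "FOLFOX",
  oxaliplatin = "oxaliplatin", `5-fu/leucovorin` = "5-FU/leucovorin",
  ipilimumab = "ipilimumab", anastrozole = "anastrozole",
  gemcitabine = "gemcitabine", cisplatin = "cisplatin",
  paclitaxel = "paclitaxel", tamoxifen = "tamoxifen",
  letrozole = "letrozole", avastin = "Avastin", xeliri = "XELIRI"
)
CONFOUNDER_DISPLAY <- c(cytoxan = "Cytoxan", fludarabine = "fludarabine",
                        rituxan = "Rituxan")

#' Noise configuration for the synthetic corpus generator
#'
#' Controls how often the generator exercises the documented failure
#' modes of timeline extractors: hedged treatment statements (uncertainty
#' phrasing with no begin/end/administration trigger, which plain trigger
#' rules cannot see), date-headed subsections (the date appears as a
#' heading line, not in the event's sentence), cross-disease confounder
#' sentences (drug plus date for a non-target disease, annotated with no
#' gold link), and deictic/relative date rendering.
#'
#' @param p_hedge Probability a cycle-administration statement is rendered
#'   hedged. Hedged statements keep their gold TLINK and timeline entry.
#' @param p_heading Probability a note renders its administration facts
#'   under date subsection headings (month granularity).
#' @param p_confounder Probability a note carries a confounder sentence
#'   (drug string present, no gold annotation).
#' @param p_relative_date Probability a date is rendered as a deictic or
#'   offset expression relative to the note's creation time.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(p_hedge = 0, p_heading = 0, p_confounder = 0,
                         p_relative_date = 0, seed = 1L) {
  p <- c(p_hedge, p_heading, p_confounder, p_relative_date)
  if (any(p < 0 | p > 1)) abort("noise probabilities must be in [0, 1]")
  structure(list(p_hedge = p_hedge, p_heading = p_heading,
                 p_confounder = p_confounder,
                 p_relative_date = p_relative_date, seed = as.integer(seed)),
            class = "noise_config")
}

#' Regimen model for the synthetic corpus generator
#'
#' Patients receive one or two regimens of one or two drugs given in
#' cycles at a fixed interval (default 21 days, the usual 3-week cycle
#' spacing), with optional start and end statements, an occasional
#' generic "chemotherapy" administration, occasional OVERLAP/BEFORE
#' side relations (which the summarizer must drop), and a chance that a
#' fact is restated in a later note (which the summarizer must
#' deduplicate).
#'
#' @param drugs Named character vector mapping lexicon keys to display
#'   forms; defaults to the built-in pool.
#' @param n_regimens_range,n_drugs_range,n_cycles_range Integer ranges
#'   sampled per patient/regimen.
#' @param interval_days Days between cycles.
#' @param start_years Calendar year range for regimen starts (kept away
#'   from the present so no real-looking dates are produced).
#' @param p_begin,p_end,p_generic,p_minor,p_repeat Probabilities of a
#'   begin statement, end statement, generic chemotherapy fact,
#'   OVERLAP/BEFORE side relation, and fact restatement.
#' @return A list of class `regimen_model`.
#' @export
regimen_model <- function(drugs = SACT_DISPLAY,
                          n_regimens_range = c(1L, 2L),
                          n_drugs_range = c(1L, 2L),
                          n_cycles_range = c(3L, 6L),
                          interval_days = 21L,
                          start_years = c(2011L, 2058L),
                          p_begin = 0.8, p_end = 0.5, p_generic = 0.4,
                          p_minor = 0.15, p_repeat = 0.25) {
  stopifnot(interval_days >= 1, n_cycles_range[1] >= 1)
  structure(list(drugs = drugs, n_regimens_range = n_regimens_range,
                 n_drugs_range = n_drugs_range,
                 n_cycles_range = n_cycles_range,
                 interval_days = as.integer(interval_days),
                 start_years = start_years, p_begin = p_begin, p_end = p_end,
                 p_generic = p_generic, p_minor = p_minor,
                 p_repeat = p_repeat),
            class = "regimen_model")
}

rint <- function(range) sample(seq(range[1], range[2]), 1L)

# --- sentence rendering -----------------------------------------------------

# A rendered sentence: text plus 0-based spans (relative to the sentence)
# of the event and time mentions it asserts.
render_date_expr <- function(date, doctime, relative) {
  diff <- as.integer(doctime - date)
  if (relative && diff >= 0 && diff <= 35) {
    if (diff == 0) return("today")
    if (diff == 1) return("yesterday")
    if (diff == 7) return("last week")
    if (diff < 7) {
      return(paste("last", WEEKDAYS[as.integer(format(date, "%u"))]))
    }
    if (diff %% 7 == 0 && diff <= 28) {
      return(sprintf("%d weeks ago", diff %/% 7))
    }
    return(sprintf("%d days ago", diff))
  }
  style <- sample(3L, 1L)
  switch(style,
    format(date, "%Y-%m-%d"),
    sprintf("%d/%d/%d", as.integer(format(date, "%m")),
            as.integer(format(date, "%d")), as.integer(format(date, "%Y"))),
    sprintf("%s %d, %d", MONTHS[as.integer(format(date, "%m"))],
            as.integer(format(date, "%d")), as.integer(format(date, "%Y")))
  )
}

# Assemble text from parts; roles "event"/"timex" are recorded as spans.
build_parts <- function(parts) {
  text <- ""
  events <- list(); timexes <- list()
  for (p in parts) {
    s <- nchar(text)
    text <- paste0(text, p$text)
    if (identical(p$role, "event")) {
      events[[length(events) + 1L]] <- c(s, nchar(text))
    } else if (identical(p$role, "timex")) {
      timexes[[length(timexes) + 1L]] <- c(s, nchar(text))
    }
  }
  list(text = text, events = events, timexes = timexes)
}

pl <- function(text) list(text = text, role = "plain")
ev <- function(text) list(text = text, role = "event")
tx <- function(text) list(text = text, role = "timex")

render_fact_sentence <- function(drug, label, expr, cycle = NA, hedged = FALSE) {
  if (hedged) {
    joiner <- if (stringr::str_detect(expr, "^[A-Z0-9]")) " around " else " "
    return(build_parts(list(
      pl("We had attempted to treat him with "), ev(drug), pl(joiner),
      tx(expr), pl("; however, the session was interrupted.")
    )))
  }
  if (label == "BEGINS-ON") {
    v <- sample(3L, 1L)
    parts <- switch(v,
      list(pl("Started "), ev(drug), pl(" on "), tx(expr), pl(".")),
      list(ev(drug), pl(" was initiated on "), tx(expr), pl(".")),
      list(pl("First dose of "), ev(drug), pl(" on "), tx(expr), pl("."))
    )
  } else if (label == "ENDS-ON") {
    v <- sample(3L, 1L)
    parts <- switch(v,
      list(pl("Completed "), ev(drug), pl(" on "), tx(expr), pl(".")),
      list(pl("Last dose of "), ev(drug), pl(" : "), tx(expr), pl(".")),
      list(ev(drug), pl(" was discontinued on "), tx(expr), pl("."))
    )
  } else if (label == "CONTAINS") {
    v <- if (!is.na(cycle) && cycle >= 2) sample(3L, 1L) else sample(2L, 1L)
    parts <- switch(v,
      list(pl("Received "), ev(drug), pl(" on "), tx(expr), pl(".")),
      list(ev(drug), pl(" was administered on "), tx(expr), pl(".")),
      list(pl(sprintf("Cycle %d of ", cycle)), ev(drug), pl(" given on "),
           tx(expr), pl("."))
    )
  } else if (label == "OVERLAP") {
    parts <- list(pl("During "), tx(expr), pl(", "), ev(drug),
                  pl(" therapy was ongoing."))
  } else {  # BEFORE
    parts <- list(pl("Therapy with "), ev(drug), pl(" occurred before "),
                  tx(expr), pl("."))
  }
  build_parts(parts)
}

render_combined_contains <- function(drugs, expr) {
  build_parts(list(
    pl("Received "), ev(drugs[1]), pl(" and "), ev(drugs[2]),
    pl(" on "), tx(expr), pl(".")
  ))
}

INTRO_SENTENCES <- c("Oncology follow-up visit.",
                     "Patient seen in clinic for routine review.",
                     "Interval history reviewed with the patient.")

# --- patient/corpus generation ---------------------------------------------

gen_patient_facts <- function(model) {
  facts <- list()
  for (r in seq_len(rint(model$n_regimens_range))) {
    keys <- sample(names(model$drugs), rint(model$n_drugs_range))
    start <- as.Date(sprintf("%d-01-01", rint(model$start_years))) +
      sample.int(330L, 1L)
    n_cycles <- rint(model$n_cycles_range)
    dates <- start + (seq_len(n_cycles) - 1L) * model$interval_days
    for (k in keys) {
      d <- unname(model$drugs[[k]])
      if (stats::runif(1) < model$p_begin) {
        facts[[length(facts) + 1L]] <- list(drug = d, label = "BEGINS-ON",
                                            date = start, cycle = NA)
      }
      for (i in seq_along(dates)) {
        facts[[length(facts) + 1L]] <- list(drug = d, label = "CONTAINS",
                                            date = dates[i], cycle = i)
      }
      if (stats::runif(1) < model$p_end) {
        facts[[length(facts) + 1L]] <- list(drug = d, label = "ENDS-ON",
                                            date = dates[n_cycles],
                                            cycle = NA)
      }
      if (stats::runif(1) < model$p_minor) {
        lab <- sample(c("OVERLAP", "BEFORE"), 1L)
        facts[[length(facts) + 1L]] <- list(drug = d, label = lab,
                                            date = sample(dates, 1L),
                                            cycle = NA)
      }
    }
    if (stats::runif(1) < model$p_generic) {
      facts[[length(facts) + 1L]] <- list(drug = "chemotherapy",
                                          label = "CONTAINS", date = start,
                                          cycle = NA)
    }
  }
  dplyr::bind_rows(purrr::map(facts, tibble::as_tibble))
}

#' Generate a synthetic oncology corpus with aligned gold data
#'
#' Emits multi-note patients whose notes describe drug regimens in
#' templated clinical phrasings (begin, cycle administration, end, date
#' subsection headings, hedged statements, cross-disease confounders,
#' deictic dates), together with gold standoff mentions, gold pairwise
#' TLINKs, and the gold patient timelines implied by them. Every gold
#' timeline entry is supported by at least one gold TLINK whose time
#' expression normalizes (via [normalize_timex()]) to the entry's date,
#' so the generator is a closed oracle for every pipeline stage.
#' Deterministic given the seed in `noise`.
#'
#' @param n_patients Number of patients (>= 1).
#' @param notes_per_patient Notes per patient.
#' @param model A [regimen_model()].
#' @param noise A [noise_config()].
#' @return An object of class `sact_corpus`: a list with tibbles `notes`,
#'   `mentions`, `tlinks`, `timelines` (gold, with the patient universe
#'   in its `"patients"` attribute), and `sentences` (the per-sentence
#'   noise-phenomenon log used by [corruption_report()]).
#' @export
generate_corpus <- function(n_patients = 10L, notes_per_patient = 4L,
                            model = regimen_model(), noise = noise_config()) {
  if (n_patients < 1) abort("n_patients must be >= 1")
  set.seed(noise$seed)
  pieces <- purrr::map(seq_len(n_patients), function(i) {
    pid <- sprintf("pat%03d", i)
    facts <- gen_patient_facts(model)
    render_patient(pid, facts, notes_per_patient, model, noise)
  })
  finish_corpus(pieces, noise)
}

finish_corpus <- function(pieces, noise) {
  notes <- dplyr::bind_rows(purrr::map(pieces, "notes"))
  mentions <- dplyr::bind_rows(purrr::map(pieces, "mentions"))
  if (nrow(mentions) == 0) mentions <- empty_mentions()
  tlinks <- dplyr::bind_rows(purrr::map(pieces, "tlinks"))
  sentences <- dplyr::bind_rows(purrr::map(pieces, "sentences"))
  gold_triples <- if (nrow(tlinks) == 0) {
    tibble::tibble(patient_id = character(), event_text = character(),
                   label = character(), date = character())
  } else {
    dplyr::select(tlinks, "patient_id", "event_text", "label", "date")
  }
  timelines <- summarize_timelines(gold_triples,
                                   patients = unique(notes$patient_id))
  tlinks_out <- if (nrow(tlinks) > 0) {
    dplyr::select(tlinks, "note_id", "event_id", "timex_id", "label")
  } else {
    tibble::tibble(note_id = character(), event_id = character(),
                   timex_id = character(), label = character())
  }
  structure(list(notes = notes, mentions = mentions, tlinks = tlinks_out,
                 timelines = timelines, sentences = sentences,
                 noise = noise),
            class = "sact_corpus")
}

render_patient <- function(pid, facts, n_notes, model, noise) {
  if (nrow(facts) == 0) {
    facts <- tibble::tibble(drug = character(), label = character(),
                            date = as.Date(character()), cycle = integer())
  }
  span_start <- if (nrow(facts) > 0) min(facts$date) else
    as.Date("2030-01-01")
  span_end <- if (nrow(facts) > 0) max(facts$date) else span_start + 60
  doctimes <- span_start +
    round(seq(0, as.integer(span_end - span_start) + 14,
              length.out = n_notes))
  doctimes <- as.Date(doctimes, origin = "1970-01-01")
  note_ids <- sprintf("%s_n%02d", pid, seq_len(n_notes))

  # assign each fact to one eligible note (doctime >= fact date), with an
  # optional restatement in a later eligible note
  assignments <- list()
  if (nrow(facts) > 0) {
    facts$hedged <- facts$label == "CONTAINS" &
      stats::runif(nrow(facts)) < noise$p_hedge
    for (i in seq_len(nrow(facts))) {
      elig <- which(doctimes >= facts$date[i])
      if (length(elig) == 0) elig <- n_notes
      first <- elig[sample.int(length(elig), 1L)]
      target <- first
      if (!facts$hedged[i] && length(elig) > 1 &&
          stats::runif(1) < model$p_repeat) {
        later <- elig[elig > first]
        if (length(later) > 0) {
          target <- c(first, later[sample.int(length(later), 1L)])
        }
      }
      for (nt in target) {
        assignments[[length(assignments) + 1L]] <-
          dplyr::mutate(facts[i, ], note = nt)
      }
    }
  }
  assigned <- dplyr::bind_rows(assignments)

  out_notes <- list(); out_mentions <- list(); out_tlinks <- list()
  out_sentences <- list()
  for (nt in seq_len(n_notes)) {
    nid <- note_ids[nt]
    nf <- if (nrow(assigned) > 0) {
      dplyr::arrange(dplyr::filter(assigned, .data$note == nt), .data$date)
    } else assigned
    res <- render_note(nid, doctimes[nt], nf, noise)
    out_notes[[nt]] <- tibble::tibble(patient_id = pid, note_id = nid,
                                      doctime = doctimes[nt],
                                      text = res$text)
    out_mentions[[nt]] <- res$mentions
    if (nrow(res$tlinks) > 0) {
      res$tlinks$patient_id <- pid
      out_tlinks[[nt]] <- res$tlinks
    }
    res$sentences$note_id <- nid
    out_sentences[[nt]] <- res$sentences
  }
  list(notes = dplyr::bind_rows(out_notes),
       mentions = dplyr::bind_rows(out_mentions),
       tlinks = dplyr::bind_rows(out_tlinks),
       sentences = dplyr::bind_rows(out_sentences))
}

# Render one note: a sequence of lines, each carrying mention spans and
# gold TLINKs. Returns text, mention/tlink tibbles, and the sentence log.
render_note <- function(nid, doctime, nf, noise) {
  lines <- list()  # each: list(text, events, timexes, links, flags)
  add_line <- function(built, links = list(), flags = character()) {
    lines[[length(lines) + 1L]] <<-
      list(built = built, links = links, flags = flags)
  }
  add_line(build_parts(list(pl(sample(INTRO_SENTENCES, 1L)))))

  heading_mode <- nrow(nf) > 0 && any(nf$label == "CONTAINS" & !nf$hedged) &&
    stats::runif(1) < noise$p_heading

  plain <- nf
  headed <- nf[0, ]
  if (heading_mode) {
    headed <- dplyr::filter(nf, .data$label == "CONTAINS" & !.data$hedged)
    plain <- dplyr::filter(nf, !(.data$label == "CONTAINS" & !.data$hedged))
  }

  if (nrow(plain) > 0) {
    i <- 1L
    while (i <= nrow(plain)) {
      f <- plain[i, ]
      relative <- stats::runif(1) < noise$p_relative_date
      expr <- render_date_expr(f$date, doctime, relative)
      flags <- c(if (f$hedged) "hedged",
                 if (relative && !stringr::str_detect(expr, "^[A-Z0-9]"))
                   "relative_date")
      # combine two same-date CONTAINS drugs into one sentence sometimes
      if (!f$hedged && f$label == "CONTAINS" && i < nrow(plain)) {
        g <- plain[i + 1L, ]
        if (g$label == "CONTAINS" && !g$hedged && g$date == f$date &&
            g$drug != f$drug && stats::runif(1) < 0.5) {
          built <- render_combined_contains(c(f$drug, g$drug), expr)
          add_line(built,
                   links = list(list(ev = 1L, tx = 1L, label = "CONTAINS",
                                     date = f$date),
                                list(ev = 2L, tx = 1L, label = "CONTAINS",
                                     date = g$date)),
                   flags = flags)
          i <- i + 2L
          next
        }
      }
      built <- render_fact_sentence(f$drug, f$label, expr, f$cycle, f$hedged)
      add_line(built,
               links = list(list(ev = 1L, tx = 1L, label = f$label,
                                 date = f$date)),
               flags = flags)
      i <- i + 1L
    }
  }

  if (nrow(headed) > 0) {
    headed$month <- format(headed$date, "%Y-%m")
    for (mo in unique(headed$month)) {
      grp <- dplyr::filter(headed, .data$month == mo)
      mdate <- grp$date[1]
      head_txt <- sprintf("%s %s", MONTHS[as.integer(format(mdate, "%m"))],
                          format(mdate, "%Y"))
      add_line(build_parts(list(tx(head_txt), pl(":"))),
               links = list(), flags = "heading")
      for (d in unique(grp$drug)) {
        k <- sum(grp$drug == d)
        built <- build_parts(list(
          pl(sprintf("%d cycle%s of ", k, if (k > 1) "s" else "")),
          ev(d), pl(".")
        ))
        # link body event to the heading timex (previous heading line)
        add_line(built,
                 links = list(list(ev = 1L, tx = NA, label = "CONTAINS",
                                   heading = TRUE)),
                 flags = "heading")
      }
    }
  }

  if (stats::runif(1) < noise$p_confounder) {
    cd <- unname(sample(CONFOUNDER_DISPLAY, 1L))
    mdate <- doctime - sample.int(200L, 1L)
    expr <- sprintf("%s %s", MONTHS[as.integer(format(mdate, "%m"))],
                    format(mdate, "%Y"))
    built <- build_parts(list(
      pl("His leukemia was treated with cycles of "), pl(cd),
      pl(" chemotherapy through "), pl(expr), pl(".")
    ))
    add_line(built, links = list(), flags = "confounder")
  }

  # assemble lines into the note text, offsetting spans
  text <- ""
  mention_rows <- list(); tlink_rows <- list(); sent_rows <- list()
  e_counter <- 0L; t_counter <- 0L
  last_heading_timex_id <- NA_character_
  last_heading_surface <- NA_character_
  for (ln in lines) {
    offset <- nchar(text)
    if (offset > 0) {
      text <- paste0(text, "\n")
      offset <- offset + 1L
    }
    text <- paste0(text, ln$built$text)
    ev_ids <- character(length(ln$built$events))
    for (j in seq_along(ln$built$events)) {
      e_counter <- e_counter + 1L
      ev_ids[j] <- paste0("e", e_counter)
      sp <- ln$built$events[[j]]
      mention_rows[[length(mention_rows) + 1L]] <- tibble::tibble(
        note_id = nid, mention_id = ev_ids[j], mention_type = "EVENT",
        start = offset + sp[1], end = offset + sp[2])
    }
    tx_ids <- character(length(ln$built$timexes))
    for (j in seq_along(ln$built$timexes)) {
      t_counter <- t_counter + 1L
      tx_ids[j] <- paste0("t", t_counter)
      sp <- ln$built$timexes[[j]]
      mention_rows[[length(mention_rows) + 1L]] <- tibble::tibble(
        note_id = nid, mention_id = tx_ids[j], mention_type = "TIMEX3",
        start = offset + sp[1], end = offset + sp[2])
    }
    if ("heading" %in% ln$flags && length(tx_ids) > 0) {
      last_heading_timex_id <- tx_ids[1]
      sp <- ln$built$timexes[[1]]
      last_heading_surface <- substr(ln$built$text, sp[1] + 1, sp[2])
    }
    for (lk in ln$links) {
      if (isTRUE(lk$heading)) {
        tid <- last_heading_timex_id
        tsurf <- last_heading_surface
      } else {
        tid <- tx_ids[lk$tx]
        sp <- ln$built$timexes[[lk$tx]]
        tsurf <- substr(ln$built$text, sp[1] + 1, sp[2])
      }
      esp <- ln$built$events[[lk$ev]]
      tlink_rows[[length(tlink_rows) + 1L]] <- tibble::tibble(
        note_id = nid, event_id = ev_ids[lk$ev], timex_id = tid,
        label = lk$label,
        event_text = tolower(substr(ln$built$text, esp[1] + 1, esp[2])),
        date = normalize_timex(tsurf, doctime))
    }
    sent_rows[[length(sent_rows) + 1L]] <- tibble::tibble(
      text = ln$built$text,
      hedged = "hedged" %in% ln$flags,
      heading = "heading" %in% ln$flags,
      confounder = "confounder" %in% ln$flags,
      relative_date = "relative_date" %in% ln$flags)
  }
  mentions <- dplyr::bind_rows(mention_rows)
  if (nrow(mentions) > 0) {
    mentions$surface <- slice_span(text, mentions$start, mentions$end)
  } else {
    mentions <- empty_mentions()
  }
  list(text = text, mentions = mentions,
       tlinks = dplyr::bind_rows(tlink_rows) %||%
         tibble::tibble(),
       sentences = dplyr::bind_rows(sent_rows))
}

#' Count noise phenomena in a generated corpus
#'
#' Summarizes the generator's per-sentence log: how many rendered
#' sentences were hedged, heading-formatted, confounders, or used a
#' relative date expression. Supports stratified error analysis of any
#' extractor run on the corpus. Only corpora produced by
#' [generate_corpus()] (or [demo_corpus()]) carry the log.
#'
#' @param corpus A `sact_corpus` object.
#' @return A one-row tibble of counts: `hedged`, `heading`, `confounder`,
#'   `relative_date`, `n_sentences`.
#' @export
corruption_report <- function(corpus) {
  if (!inherits(corpus, "sact_corpus")) {
    abort("corruption_report() needs a corpus from generate_corpus()")
  }
  s <- corpus$sentences
  tibble::tibble(
    hedged = sum(s$hedged), heading = sum(s$heading),
    confounder = sum(s$confounder),
    relative_date = sum(s$relative_date),
    n_sentences = nrow(s)
  )
}

#' A fixed demonstration corpus with a known 11-entry timeline
#'
#' One patient whose chart shows a generic chemotherapy administration
#' followed by five carboplatin/Taxol cycles, so the gold timeline has
#' eleven `contains-1` entries (one generic plus five dates for each of
#' the two drugs) — the canonical shape of a summarized platinum-doublet
#' course.
#'
#' @param n_notes Number of notes the facts are spread over.
#' @param seed Integer seed for rendering choices.
#' @return A `sact_corpus` object.
#' @export
demo_corpus <- function(n_notes = 3L, seed = 1L) {
  set.seed(seed)
  cycle_dates <- as.Date(c("2013-07-18", "2013-08-08", "2013-08-29",
                           "2013-09-19", "2013-10-24"))
  facts <- dplyr::bind_rows(
    tibble::tibble(drug = "chemotherapy", label = "CONTAINS",
                   date = as.Date("2013-06-20"), cycle = NA_integer_),
    tidyr::expand_grid(drug = c("carboplatin", "Taxol"),
                       date = cycle_dates) |>
      dplyr::mutate(label = "CONTAINS",
                    cycle = rep(seq_along(cycle_dates), 2))
  )
  noise <- noise_config(seed = seed)
  piece <- render_patient("pat001", facts, n_notes,
                          regimen_model(p_repeat = 0), noise)
  finish_corpus(list(piece), noise)
}
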