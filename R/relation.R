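#' Configuration for pairwise window generation
#'
#' An EVENT-TIMEX3 pair becomes a classification instance only when the
#' number of whitespace tokens strictly between the two mentions (nearest
#' edges) is at most `max_token_distance`; the default of 60 tokens covers
#' the overwhelming majority of annotated pairs in clinical text. The
#' rendered window runs from `context_padding` tokens before the earlier
#' mention to `context_padding` tokens after the later one, ignoring
#' sentence boundaries, with the event wrapped in `<e>...</e>` and the
#' time in `<t>...</t>`.
#'
#' @param max_token_distance Maximum inter-mention token distance.
#' @param context_padding Tokens of context kept on each side.
#' @return A list of class `window_config`.
#' @export
window_config <- function(max_token_distance = 60L, context_padding = 10L) {
  stopifnot(max_token_distance >= 1, context_padding >= 0)
  structure(list(max_token_distance = as.integer(max_token_distance),
                 context_padding = as.integer(context_padding)),
            class = "window_config")
}

#' Generate marked context-window instances for EVENT-TIMEX3 pairs
#'
#' Forms the Cartesian pairing of EVENT and TIMEX3 mentions within each
#' note, keeps pairs within the configured token distance, and renders
#' each as a context window with exactly one `<e>...</e>` and one
#' `<t>...</t>` insertion. Pairs whose spans overlap are skipped with a
#' message.
#'
#' @param notes Notes tibble (`note_id`, `text`).
#' @param events,timexes Mention tibbles (`note_id`, `mention_id`,
#'   `start`, `end`, `surface`).
#' @param config A [window_config()].
#' @return A tibble of instances: note and mention identifiers, spans,
#'   surfaces, `token_distance`, and `window_text`.
#' @export
make_window_instances <- function(notes, events, timexes,
                                  config = window_config()) {
  assert_cols(notes, c("note_id", "text"), "`notes`")
  out <- purrr::map2(notes$note_id, notes$text, function(nid, text) {
    ev <- dplyr::filter(events, .data$note_id == nid)
    tx <- dplyr::filter(timexes, .data$note_id == nid)
    if (nrow(ev) == 0 || nrow(tx) == 0) return(NULL)
    toks <- tokenize(text)
    pairs <- tidyr::expand_grid(ei = seq_len(nrow(ev)), ti = seq_len(nrow(tx)))
    es <- ev$start[pairs$ei]; ee <- ev$end[pairs$ei]
    ts <- tx$start[pairs$ti]; te <- tx$end[pairs$ti]
    overlapping <- es < te & ee > ts
    if (any(overlapping)) {
      message(sprintf(
        "make_window_instances: skipping %d overlapping pair(s) in note %s",
        sum(overlapping), nid))
    }
    d <- token_gap(toks, es, ee, ts, te)
    keep <- !overlapping & d <= config$max_token_distance
    if (!any(keep)) return(NULL)
    idx <- which(keep)
    tibble::tibble(
      note_id = nid,
      event_id = ev$mention_id[pairs$ei[idx]],
      event_start = es[idx], event_end = ee[idx],
      event_surface = ev$surface[pairs$ei[idx]],
      timex_id = tx$mention_id[pairs$ti[idx]],
      timex_start = ts[idx], timex_end = te[idx],
      timex_surface = tx$surface[pairs$ti[idx]],
      token_distance = d[idx],
      window_text = purrr::map_chr(idx, function(i) {
        render_window(text, toks, es[i], ee[i], ts[i], te[i],
                      config$context_padding)
      })
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(empty_instances())
  out
}

# Number of whitespace tokens lying strictly between the nearest edges of
# two non-overlapping spans (vectorized over pairs; tokens are ordered and
# non-overlapping, so the tokens inside a gap form a contiguous run).
token_gap <- function(toks, es, ee, ts, te) {
  gap_lo <- pmin(ee, te); gap_hi <- pmax(es, ts)
  first_idx <- findInterval(gap_lo - 0.5, toks$start) + 1L
  last_idx <- findInterval(gap_hi + 0.5, toks$end)
  pmax(0L, last_idx - first_idx + 1L)
}

render_window <- function(text, toks, es, ee, ts, te, padding) {
  first_start <- min(es, ts); last_end <- max(ee, te)
  before <- which(toks$end <= first_start)
  after <- which(toks$start >= last_end)
  w_start <- if (length(before) >= padding && padding > 0) {
    toks$start[before[length(before) - padding + 1L]]
  } else if (padding == 0) first_start else 0L
  w_end <- if (length(after) >= padding && padding > 0) {
    toks$end[after[padding]]
  } else if (padding == 0) last_end else nchar(text)
  # insert markers right-to-left so offsets stay valid
  ins <- tibble::tibble(
    pos = c(es, ee, ts, te),
    tag = c("<e>", "</e>", "<t>", "</t>")
  )
  ins <- ins[order(-ins$pos, -match(ins$tag, c("</e>", "</t>", "<e>", "<t>"))), ]
  marked <- substr(text, w_start + 1L, w_end)
  for (i in seq_len(nrow(ins))) {
    at <- ins$pos[i] - w_start
    marked <- paste0(substr(marked, 1L, at), ins$tag[i],
                     substr(marked, at + 1L, nchar(marked)))
  }
  marked
}

BEGIN_TRIGGERS <- c("started", "starting", "begin", "began", "begins",
                    "initiated", "first dose", "cycle 1")
END_TRIGGERS <- c("completed", "finished", "last dose", "final cycle",
                  "discontinued", "stopped")
ADMIN_TRIGGERS <- c("received", "given", "administered", "on",
                    "treated with")

trigger_rx <- function(triggers) {
  stringr::regex(paste0("\\b(", paste(triggers, collapse = "|"), ")\\b"),
                 ignore_case = TRUE)
}

#' Rule-based temporal relation classification
#'
#' A deterministic, pure function of the marked window text. Trigger
#' lexicons are scanned in the sentence region around the pair:
#' begin triggers (started, began, initiated, first dose, cycle 1) give
#' BEGINS-ON; end triggers (completed, finished, last dose, final cycle,
#' discontinued, stopped) give ENDS-ON; administration triggers (received,
#' given, administered, on, treated with) give CONTAINS; precedence
#' BEGINS-ON > ENDS-ON > CONTAINS when several classes fire. Pairs split
#' across a sentence boundary are labeled NONE unless the time expression
#' directly follows an end trigger (the `"... Last dose : 10/18/2033"`
#' pattern) with no other detectable time expression between the pair.
#' A detectable time expression between the pair also forces NONE, so a
#' drug is not linked past a nearer date to a farther one.
#'
#' @param window_text Character vector of marked windows (each with
#'   exactly one `<e>...</e>` and one `<t>...</t>`).
#' @return A character vector of labels in
#'   `{CONTAINS, BEGINS-ON, ENDS-ON, NONE}`.
#' @export
classify_rule_based <- function(window_text) {
  n <- length(window_text)
  if (n == 0) return(character())
  rx <- rule_regexes()
  w <- window_text
  e_loc <- stringr::str_locate(w, stringr::fixed("<e>"))
  e_end <- stringr::str_locate(w, stringr::fixed("</e>"))
  t_loc <- stringr::str_locate(w, stringr::fixed("<t>"))
  t_end <- stringr::str_locate(w, stringr::fixed("</t>"))
  malformed <- is.na(e_loc[, 1]) | is.na(e_end[, 1]) |
    is.na(t_loc[, 1]) | is.na(t_end[, 1])
  event_first <- !malformed & e_loc[, 1] < t_loc[, 1]

  between <- ifelse(event_first,
                    substr(w, e_end[, 2] + 1L, t_loc[, 1] - 1L),
                    substr(w, t_end[, 2] + 1L, e_loc[, 1] - 1L))
  plain_between <- strip_markers(between)
  cross_sentence <- stringr::str_detect(plain_between, "[.!?\n]")
  timex_between <- stringr::str_detect(plain_between, rx$timex_ci) |
    stringr::str_detect(plain_between, rx$timex_cs)

  # the ~6 tokens immediately preceding <t>, within the same sentence
  pre_t <- strip_markers(substr(w, 1L, t_loc[, 1] - 1L))
  pre_t_tail <- last_tokens_rx(pre_t, 6L)
  end_adjacent <- stringr::str_detect(pre_t_tail, rx$end)

  first_open <- pmin(e_loc[, 1], t_loc[, 1])
  last_close <- pmax(e_end[, 2], t_end[, 2])
  lead <- last_tokens_rx(strip_markers(substr(w, 1L, first_open - 1L)), 6L)
  trail <- first_tokens_rx(strip_markers(substr(w, last_close + 1L,
                                                nchar(w))), 3L)
  region <- paste(lead, plain_between, trail)
  has_begin <- stringr::str_detect(region, rx$begin)
  has_end <- stringr::str_detect(region, rx$end)
  has_admin <- stringr::str_detect(region, rx$admin)

  out <- rep("NONE", n)
  same <- !malformed & !cross_sentence & !timex_between
  # precedence BEGINS-ON > ENDS-ON > CONTAINS within the same sentence
  out[same & has_admin] <- "CONTAINS"
  out[same & has_end] <- "ENDS-ON"
  out[same & has_begin] <- "BEGINS-ON"
  # only the "<event> ... Last dose : <time>" pattern links across a
  # sentence boundary: the event must precede the trigger-adjacent time
  cross_end <- !malformed & cross_sentence & event_first & end_adjacent &
    !timex_between
  out[cross_end] <- "ENDS-ON"
  out
}

# Precompiled regexes shared across instances of one classification call.
rule_regexes <- function() {
  pats <- timex_patterns()
  ci <- paste0("(", paste(pats$regex[!pats$case_sensitive], collapse = ")|("),
               ")")
  cs <- paste0("(", paste(pats$regex[pats$case_sensitive], collapse = ")|("),
               ")")
  list(
    begin = trigger_rx(BEGIN_TRIGGERS),
    end = trigger_rx(END_TRIGGERS),
    admin = trigger_rx(ADMIN_TRIGGERS),
    timex_ci = stringr::regex(ci, ignore_case = TRUE),
    timex_cs = stringr::regex(cs)
  )
}

# Last/first k whitespace tokens of the sentence fragment adjacent to the
# pair (never crossing a sentence boundary), vectorized.
last_tokens_rx <- function(x, k) {
  seg <- stringr::str_extract(x, "[^.!?\n]*$")
  out <- stringr::str_extract(
    seg, sprintf("(\\S+\\s+){0,%d}\\S+\\s*$", k - 1L))
  out[is.na(out)] <- ""
  out
}

first_tokens_rx <- function(x, k) {
  seg <- stringr::str_extract(x, "^[^.!?\n]*")
  out <- stringr::str_extract(
    seg, sprintf("^\\s*\\S+(\\s+\\S+){0,%d}", k - 1L))
  out[is.na(out)] <- ""
  out
}

classify_rule_one <- function(w) classify_rule_based(w)[1]

strip_markers <- function(x) {
  stringr::str_remove_all(x, "</?[et]>")
}

# Last k tokens of x, not crossing a sentence boundary backwards.
tail_tokens <- function(x, k) {
  segs <- stringr::str_split(x, "[.!?\\n]")[[1]]
  toks <- stringr::str_split(stringr::str_squish(segs[length(segs)]), " ")[[1]]
  toks <- toks[toks != ""]
  paste(utils::tail(toks, k), collapse = " ")
}

# First k tokens of x, not crossing a sentence boundary forwards.
head_tokens <- function(x, k) {
  segs <- stringr::str_split(x, "[.!?\\n]")[[1]]
  toks <- stringr::str_split(stringr::str_squish(segs[1]), " ")[[1]]
  toks <- toks[toks != ""]
  paste(utils::head(toks, k), collapse = " ")
}

#' Pair events with date subsection headings
#'
#' Many notes use dates as subsection headings (`"July 2055:"` or
#' `"July 2055 through December 2055:"`) with every event described in the
#' subsection related to the heading date(s). This rule opens a section at
#' any line consisting of one or two detectable time expressions followed
#' by a colon, and pairs every EVENT mention until the next heading (or
#' the end of the note) with each heading date as a CONTAINS candidate.
#'
#' @param notes Notes tibble (`note_id`, `text`).
#' @param events EVENT mention tibble.
#' @return A tibble of candidates: `note_id`, `event_id`, `event_surface`,
#'   `timex_start`, `timex_end`, `timex_surface`, `label` (always
#'   `"CONTAINS"`).
#' @export
apply_date_heading_rule <- function(notes, events) {
  assert_cols(notes, c("note_id", "text"), "`notes`")
  pats <- timex_patterns()
  out <- purrr::map2(notes$note_id, notes$text, function(nid, text) {
    lines <- stringr::str_split(text, "\n")[[1]]
    starts <- c(0L, cumsum(nchar(lines) + 1L))  # line start offsets
    heads <- list()
    for (i in seq_along(lines)) {
      line <- lines[i]
      m <- stringr::str_match(line, "^(.*\\S)\\s*:\\s*(.*)$")
      if (is.na(m[1, 1])) next
      head_txt <- m[1, 2]
      tx <- detect_timex_one(head_txt, pats)
      if (nrow(tx) == 0) next
      # the heading part must be dates only (optionally joined by through/-)
      residue <- head_txt
      for (j in rev(seq_len(nrow(tx)))) {
        residue <- paste0(substr(residue, 1, tx$start[j]),
                          substr(residue, tx$end[j] + 1, nchar(residue)))
      }
      residue <- stringr::str_squish(
        stringr::str_remove_all(residue, "\\b(through|to|until)\\b|-"))
      if (residue != "") next
      tx$start <- tx$start + starts[i]
      tx$end <- tx$end + starts[i]
      heads[[length(heads) + 1L]] <-
        list(line = i, offset = starts[i], timexes = tx)
    }
    if (length(heads) == 0) return(NULL)
    ev <- dplyr::filter(events, .data$note_id == nid)
    if (nrow(ev) == 0) return(NULL)
    head_pos <- purrr::map_int(heads, function(h) h$offset)
    section_end <- c(head_pos[-1], nchar(text) + 1L)
    rows <- purrr::map2(heads, section_end, function(h, send) {
      sstart <- h$offset
      in_sec <- ev[ev$start >= sstart & ev$start < send, , drop = FALSE]
      if (nrow(in_sec) == 0) return(NULL)
      tidyr::expand_grid(ei = seq_len(nrow(in_sec)),
                         ti = seq_len(nrow(h$timexes))) |>
        purrr::pmap(function(ei, ti) {
          tibble::tibble(
            note_id = nid,
            event_id = in_sec$mention_id[ei],
            event_start = in_sec$start[ei], event_end = in_sec$end[ei],
            event_surface = in_sec$surface[ei],
            timex_start = h$timexes$start[ti], timex_end = h$timexes$end[ti],
            timex_surface = h$timexes$surface[ti],
            label = "CONTAINS"
          )
        }) |>
        dplyr::bind_rows()
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      note_id = character(), event_id = character(),
      event_start = integer(), event_end = integer(),
      event_surface = character(), timex_start = integer(),
      timex_end = integer(), timex_surface = character(),
      label = character()))
  }
  out
}

# Sparse textual features for the trainable relation classifier.
instance_features <- function(instances) {
  purrr::pmap(instances[c("window_text", "token_distance")],
              function(window_text, token_distance) {
    w <- window_text
    e_loc <- stringr::str_locate(w, stringr::fixed("<e>"))[1]
    t_loc <- stringr::str_locate(w, stringr::fixed("<t>"))[1]
    between <- classify_region(w)
    btoks <- tolower(unlist(stringr::str_split(stringr::str_squish(between$between), " ")))
    btoks <- btoks[btoks != ""]
    ltoks <- tolower(unlist(stringr::str_split(stringr::str_squish(between$lead), " ")))
    ltoks <- ltoks[ltoks != ""]
    c(
      paste0("bw=", btoks),
      paste0("lw=", ltoks),
      paste0("order=", if (e_loc < t_loc) "et" else "te"),
      paste0("dist=", cut(token_distance, c(-1, 0, 2, 5, 10, 20, 60, Inf))),
      paste0("trig_begin=",
             stringr::str_detect(paste(between$lead, between$between),
                                 trigger_rx(BEGIN_TRIGGERS))),
      paste0("trig_end=",
             stringr::str_detect(paste(between$lead, between$between),
                                 trigger_rx(END_TRIGGERS))),
      paste0("trig_admin=",
             stringr::str_detect(paste(between$lead, between$between),
                                 trigger_rx(ADMIN_TRIGGERS))),
      paste0("cross_sent=",
             stringr::str_detect(between$between, "[.!?\\n]"))
    )
  })
}

classify_region <- function(w) {
  e_loc <- stringr::str_locate(w, stringr::fixed("<e>"))
  e_end <- stringr::str_locate(w, stringr::fixed("</e>"))
  t_loc <- stringr::str_locate(w, stringr::fixed("<t>"))
  t_end <- stringr::str_locate(w, stringr::fixed("</t>"))
  event_first <- e_loc[1] < t_loc[1]
  between <- if (event_first) substr(w, e_end[2] + 1L, t_loc[1] - 1L)
             else substr(w, t_end[2] + 1L, e_loc[1] - 1L)
  first_open <- min(e_loc[1], t_loc[1])
  lead <- tail_tokens(strip_markers(substr(w, 1L, first_open - 1L)), 6L)
  list(lead = lead, between = strip_markers(between))
}

#' Train a feature-based temporal relation classifier
#'
#' Fits a regularized multinomial logistic model over sparse features of
#' the marked window (bag of tokens between and before the pair, marker
#' order, bucketed token distance, trigger indicators, sentence-boundary
#' flag). The NONE negative class must be present in training data for
#' end-to-end use; [make_training_instances()] synthesizes it from
#' unlabeled in-window pairs.
#'
#' @param instances A labeled instance tibble (as from
#'   [make_window_instances()] plus a `label` column).
#' @param lambda Ridge penalty.
#' @param seed Integer seed; training is deterministic given the data.
#' @return An object of class `sact_relation_model`.
#' @export
train_relation_model <- function(instances, lambda = 0.01, seed = 1L) {
  assert_cols(instances, c("window_text", "token_distance", "label"),
              "`instances`")
  if (nrow(instances) == 0) abort("empty instance list")
  bad <- !instances$label %in% TLINK_LABELS_NONE
  if (any(bad)) {
    abort(sprintf("label '%s' outside the label set",
                  instances$label[bad][1]))
  }
  if (dplyr::n_distinct(instances$label) < 2) {
    abort("training data must contain at least two distinct labels")
  }
  set.seed(seed)
  feats <- instance_features(instances)
  vocab <- sort(unique(unlist(feats)))
  x <- feature_matrix(feats, vocab)
  y <- factor(instances$label,
              levels = intersect(TLINK_LABELS_NONE,
                                 unique(instances$label)))
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                        lambda = ridge_path(lambda), standardize = FALSE)
  structure(list(vocab = vocab, fit = fit, lambda = lambda,
                 classes = levels(y), version = "sact_relation/1"),
            class = "sact_relation_model")
}

#' Classify window instances
#'
#' Applies a classifier to window instances and returns them with a
#' `label` column. `classifier = "rules"` uses [classify_rule_based()];
#' `"model"` uses a trained [train_relation_model()] object; a function
#' can be supplied as a plug-in (batch contract: takes the tibble of
#' instances, returns a character vector of labels, one per instance,
#' drawn from the pairwise label set plus NONE — anything else is an
#' error). NONE-labeled instances are retained here and excluded
#' downstream by the summarizer.
#'
#' @param instances An instance tibble from [make_window_instances()].
#' @param classifier `"rules"`, `"model"`, or a plug-in function.
#' @param model A `sact_relation_model`, required when
#'   `classifier = "model"`.
#' @return The instance tibble with a `label` column.
#' @export
classify_relations <- function(instances, classifier = "rules", model = NULL) {
  if (nrow(instances) == 0) {
    instances$label <- character()
    return(instances)
  }
  labels <- if (is.function(classifier)) {
    classifier(instances)
  } else if (identical(classifier, "rules")) {
    classify_rule_based(instances$window_text)
  } else if (identical(classifier, "model")) {
    if (is.null(model)) abort("classifier = 'model' requires `model`")
    predict_relation(model, instances)
  } else {
    abort("`classifier` must be 'rules', 'model', or a function")
  }
  if (length(labels) != nrow(instances) || anyNA(labels)) {
    abort("classifier must return one label per instance")
  }
  bad <- !labels %in% TLINK_LABELS_NONE
  if (any(bad)) {
    abort(sprintf("classifier returned label '%s' outside the label set",
                  labels[bad][1]))
  }
  instances$label <- labels
  instances
}

predict_relation <- function(model, instances) {
  x <- feature_matrix(instance_features(instances), model$vocab)
  as.character(predict(model$fit, newx = x, s = model$lambda,
                       type = "class"))
}
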