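# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's own code paths
# (loops and naive scans instead of vectorized set operations).

# --- timeline comparison oracle --------------------------------------------

bf_truncate <- function(d, g) {
  if (g == "STRICT") return(d)
  w <- c(DAY = 10L, MONTH = 7L, YEAR = 4L)[[g]]
  out <- character(length(d))
  for (i in seq_along(d)) {
    out[i] <- if (nchar(d[i]) > w) substr(d[i], 1L, w) else d[i]
  }
  out
}

bf_compare_patient <- function(pred, gold, g) {
  pk <- character(0)
  for (i in seq_len(nrow(pred))) {
    k <- paste(pred$event[i], pred$relation[i],
               bf_truncate(pred$date[i], g))
    if (!k %in% pk) pk <- c(pk, k)
  }
  gk <- character(0)
  for (i in seq_len(nrow(gold))) {
    k <- paste(gold$event[i], gold$relation[i],
               bf_truncate(gold$date[i], g))
    if (!k %in% gk) gk <- c(gk, k)
  }
  if (length(pk) == 0 && length(gk) == 0) return(c(1, 1, 1))
  tp <- 0
  for (k in pk) if (k %in% gk) tp <- tp + 1
  p <- if (length(pk) == 0) 0 else tp / length(pk)
  r <- if (length(gk) == 0) 0 else tp / length(gk)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(p, r, f)
}

random_timeline <- function(pid, n) {
  events <- c("carboplatin", "taxol", "folfox", "chemotherapy",
              "ipilimumab")
  dates <- c("2013-06-20", "2013-06-21", "2013-07-18", "2013-07",
             "2013", "2014-01-02", "2014-01", "2055")
  tibble::tibble(
    patient_id = pid,
    event = sample(events, n, replace = TRUE),
    relation = sample(c("contains-1", "begins-on", "ends-on"), n,
                      replace = TRUE),
    date = sample(dates, n, replace = TRUE)
  )
}

# --- windowing oracle -------------------------------------------------------

# Naive pairer: counts tokens in the gap by scanning every token.
bf_pair <- function(text, events, timexes, max_dist) {
  m <- gregexpr("\\S+", text)[[1]]
  tok_start <- as.integer(m) - 1L
  tok_end <- tok_start + attr(m, "match.length")
  out <- list()
  for (i in seq_len(nrow(events))) {
    for (j in seq_len(nrow(timexes))) {
      es <- events$start[i]; ee <- events$end[i]
      ts <- timexes$start[j]; te <- timexes$end[j]
      if (es < te && ee > ts) next
      lo <- min(ee, te); hi <- max(es, ts)
      d <- 0L
      for (k in seq_along(tok_start)) {
        if (tok_start[k] >= lo && tok_end[k] <= hi) d <- d + 1L
      }
      if (d <= max_dist) {
        out[[length(out) + 1L]] <-
          data.frame(event_id = events$mention_id[i],
                     timex_id = timexes$mention_id[j], dist = d)
      }
    }
  }
  do.call(rbind, out)
}

# Random token text with non-overlapping single-token mention layout.
random_layout <- function(n_tokens = 120, n_events = 3, n_timexes = 3) {
  words <- replicate(n_tokens,
                     paste(sample(letters, sample(2:8, 1), replace = TRUE),
                           collapse = ""))
  text <- paste(words, collapse = " ")
  m <- gregexpr("\\S+", text)[[1]]
  tok_start <- as.integer(m) - 1L
  tok_end <- tok_start + attr(m, "match.length")
  picks <- sample(n_tokens, n_events + n_timexes)
  mk <- function(ix, type, prefix) {
    if (length(ix) == 0) {
      return(tibble::tibble(note_id = character(), mention_id = character(),
                            mention_type = character(), start = integer(),
                            end = integer(), surface = character()))
    }
    tibble::tibble(
      note_id = "n1",
      mention_id = paste0(prefix, seq_along(ix)),
      mention_type = type,
      start = tok_start[ix], end = tok_end[ix],
      surface = substring(text, tok_start[ix] + 1, tok_end[ix])
    )
  }
  list(text = text,
       events = mk(picks[seq_len(n_events)], "EVENT", "e"),
       timexes = mk(picks[n_events + seq_len(n_timexes)], "TIMEX3", "t"))
}

# --- misc fixtures ----------------------------------------------------------

tiny_notes <- function() {
  tibble::tibble(
    patient_id = c("p1", "p1"),
    note_id = c("n1", "n2"),
    doctime = as.Date(c("2013-05-02", "2013-06-01")),
    text = c("Started carboplatin on 2013-04-10. Received Taxol on 4/17/2013.",
             "Completed carboplatin on May 20, 2013.")
  )
}

gold_events <- function(corpus) {
  dplyr::filter(corpus$mentions, mention_type == "EVENT")
}

gold_timexes <- function(corpus) {
  dplyr::filter(corpus$mentions, mention_type == "TIMEX3")
}
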