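MONTHS <- c("January", "February", "March", "April", "May", "June", "July",
            "August", "September", "October", "November", "December")
WEEKDAYS <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
              "Saturday", "Sunday")

month_rx <- function() paste(MONTHS, collapse = "|")
weekday_rx <- function() paste(WEEKDAYS, collapse = "|")

#' The time-expression pattern inventory
#'
#' The grammar used by [detect_timex()] and [normalize_timex()]. Patterns
#' are tried in priority order (lower = higher priority) and overlapping
#' lower-priority matches are discarded, so `"July 2055"` is one month-year
#' mention rather than a bare month plus a bare year. Absolute classes
#' normalize independently of the document creation time; deictic and
#' offset classes are resolved against it.
#'
#' @return A tibble with columns `pattern_id`, `class`, `regex`,
#'   `granularity`, `anchoring`, `priority`, `case_sensitive`.
#' @export
timex_patterns <- function() {
  tibble::tribble(
    ~pattern_id, ~class, ~regex, ~granularity, ~anchoring, ~priority, ~case_sensitive,
    "iso_day", "absolute-day",
    "\\b\\d{4}-\\d{2}-\\d{2}\\b", "DAY", "none", 1L, FALSE,
    "slash_day", "absolute-day",
    "\\b\\d{1,2}/\\d{1,2}/\\d{4}\\b", "DAY", "none", 1L, FALSE,
    "monthname_day", "absolute-day",
    sprintf("\\b(%s) \\d{1,2},? \\d{4}\\b", month_rx()), "DAY", "none", 1L, FALSE,
    "relative_offset", "relative-offset",
    "\\b\\d+ (day|week|month)s? ago\\b", "DAY", "doctime", 2L, FALSE,
    "weekday_relative", "weekday-relative",
    sprintf("\\blast (%s)\\b", weekday_rx()), "DAY", "doctime", 2L, FALSE,
    "relative_deictic", "relative-deictic",
    "\\b(later today|today|yesterday|tomorrow|last week)\\b", "DAY", "doctime", 3L, FALSE,
    "month_year", "month-year",
    sprintf("\\b(%s) \\d{4}\\b", month_rx()), "MONTH", "none", 4L, FALSE,
    "month_only", "month-year",
    sprintf("\\b(%s)\\b", month_rx()), "MONTH", "doctime-year", 5L, TRUE,
    "year_only", "year-only",
    "\\b(19|20)\\d{2}\\b", "YEAR", "none", 6L, FALSE
  )
}

#' Detect TIMEX3 mentions in note text
#'
#' Scans each note with the pattern inventory of [timex_patterns()] and
#' returns non-overlapping TIMEX3 mentions. Higher-priority (more specific)
#' patterns win overlaps; within a priority, earlier and longer matches win.
#' An interval expression such as `"July through December 2055"` yields two
#' mentions, one per endpoint.
#'
#' @param notes A data frame with at least `note_id` and `text` columns.
#' @return A tibble of mentions: `note_id`, `mention_id`, `mention_type`
#'   (`"TIMEX3"`), `start`, `end` (0-based half-open), `surface`.
#' @examples
#' detect_timex(tibble::tibble(note_id = "n1", text = "Last dose : 10/18/2033."))
#' @export
detect_timex <- function(notes) {
  assert_cols(notes, c("note_id", "text"), "`notes`")
  pats <- timex_patterns()
  out <- purrr::map2(notes$note_id, notes$text, function(id, text) {
    m <- detect_timex_one(text, pats)
    if (nrow(m) == 0) return(NULL)
    m$note_id <- id
    m
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(empty_mentions())
  out <- dplyr::arrange(out, .data$note_id, .data$start)
  tibble::tibble(
    note_id = out$note_id,
    mention_id = paste0("t", seq_len(nrow(out))),
    mention_type = "TIMEX3",
    start = out$start, end = out$end, surface = out$surface
  )
}

detect_timex_one <- function(text, pats) {
  cand <- purrr::pmap(pats, function(pattern_id, class, regex, granularity,
                                     anchoring, priority, case_sensitive) {
    rx <- if (case_sensitive) regex else stringr::regex(regex, ignore_case = TRUE)
    loc <- stringr::str_locate_all(text, rx)[[1]]
    if (nrow(loc) == 0) return(NULL)
    tibble::tibble(
      start = loc[, 1] - 1L, end = loc[, 2],
      priority = priority
    )
  })
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          surface = character()))
  }
  cand <- dplyr::arrange(cand, .data$priority, .data$start,
                         dplyr::desc(.data$end - .data$start))
  keep <- logical(nrow(cand))
  taken_start <- integer(0)
  taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  kept <- cand[keep, , drop = FALSE]
  kept <- dplyr::arrange(kept, .data$start)
  tibble::tibble(
    start = as.integer(kept$start), end = as.integer(kept$end),
    surface = slice_span(text, kept$start, kept$end)
  )
}

#' Normalize a time expression against a document creation time
#'
#' Maps a time-expression surface to an ISO-style value: `"YYYY-MM-DD"`,
#' `"YYYY-MM"`, or `"YYYY"` depending on the intrinsic granularity of the
#' expression. Absolute forms (`"10/18/2033"`, `"2013-06-20"`,
#' `"August 1, 2012"`, `"July 2055"`, `"2055"`) are doctime-invariant;
#' deictic and offset forms (`"yesterday"`, `"last week"`, `"3 weeks ago"`,
#' `"last Thursday"`) are resolved by calendar arithmetic on `doctime`.
#' Slash dates are read month-first (US convention). Anything outside the
#' grammar, or an impossible calendar date, returns `NA` (unknown).
#'
#' @param surface Character vector of time-expression surfaces.
#' @param doctime The document creation time(s), a `Date` (recycled) or a
#'   vector of `Date`s the same length as `surface`.
#' @return A character vector of normalized values; `NA` where the
#'   expression cannot be resolved.
#' @examples
#' normalize_timex("yesterday", as.Date("2022-04-29"))  # "2022-04-28"
#' normalize_timex("July 2055", as.Date("2013-05-02"))  # "2055-07"
#' @export
normalize_timex <- function(surface, doctime) {
  stopifnot(inherits(doctime, "Date"), !anyNA(doctime))
  n <- max(length(surface), length(doctime))
  surface <- rep_len(surface, n)
  doctime <- rep_len(doctime, n)
  purrr::map2_chr(surface, doctime, normalize_timex_one)
}

normalize_timex_one <- function(surface, doctime) {
  s <- stringr::str_squish(surface)
  low <- tolower(s)

  if (stringr::str_detect(s, "^\\d{4}-\\d{2}-\\d{2}$")) {
    return(iso_day(s))
  }
  m <- stringr::str_match(s, "^(\\d{1,2})/(\\d{1,2})/(\\d{4})$")
  if (!is.na(m[1, 1])) {
    return(iso_day(sprintf("%s-%02d-%02d", m[1, 4],
                           as.integer(m[1, 2]), as.integer(m[1, 3]))))
  }
  m <- stringr::str_match(
    low, sprintf("^(%s) (\\d{1,2}),? (\\d{4})$", tolower(month_rx())))
  if (!is.na(m[1, 1])) {
    return(iso_day(sprintf("%s-%02d-%02d", m[1, 4],
                           match(m[1, 2], tolower(MONTHS)),
                           as.integer(m[1, 3]))))
  }
  m <- stringr::str_match(low, sprintf("^(%s) (\\d{4})$", tolower(month_rx())))
  if (!is.na(m[1, 1])) {
    return(sprintf("%s-%02d", m[1, 3], match(m[1, 2], tolower(MONTHS))))
  }
  if (s %in% MONTHS) {  # bare month: anchored to the doctime year
    return(sprintf("%d-%02d", lubridate::year(doctime), match(s, MONTHS)))
  }
  if (stringr::str_detect(s, "^(19|20)\\d{2}$")) {
    return(s)
  }
  if (low %in% c("today", "later today")) return(format(doctime, "%Y-%m-%d"))
  if (low == "yesterday") return(format(doctime - 1L, "%Y-%m-%d"))
  if (low == "tomorrow") return(format(doctime + 1L, "%Y-%m-%d"))
  if (low == "last week") return(format(doctime - 7L, "%Y-%m-%d"))
  m <- stringr::str_match(low, "^(\\d+) (day|week|month)s? ago$")
  if (!is.na(m[1, 1])) {
    k <- as.integer(m[1, 2])
    d <- switch(m[1, 3],
      day = doctime - k,
      week = doctime - 7L * k,
      month = doctime %m-% lubridate::period(k, "months")
    )
    return(format(d, "%Y-%m-%d"))
  }
  m <- stringr::str_match(low, sprintf("^last (%s)$", tolower(weekday_rx())))
  if (!is.na(m[1, 1])) {
    target <- match(m[1, 2], tolower(WEEKDAYS))  # 1 = Monday
    dow <- as.integer(format(doctime, "%u"))
    back <- (dow - target - 1L) %% 7L + 1L  # strictly before, within 7 days
    return(format(doctime - back, "%Y-%m-%d"))
  }
  NA_character_
}

#' @importFrom lubridate %m-%
NULL

iso_day <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  if (is.na(d)) NA_character_ else format(d, "%Y-%m-%d")
}

#' Truncate a normalized date to a coarser granularity
#'
#' Drops trailing components of a normalized date value when it is finer
#' than the target granularity; values already at or coarser than the
#' target are returned unchanged (`"2055"` truncated to `DAY` stays
#' `"2055"`). Idempotent. Used by the evaluator's relaxed granularities.
#'
#' @param date Character vector of normalized values (`"YYYY"`,
#'   `"YYYY-MM"`, or `"YYYY-MM-DD"`). Unknown (`NA`) values are an error.
#' @param granularity One of `"DAY"`, `"MONTH"`, `"YEAR"`.
#' @return Character vector of truncated values.
#' @examples
#' truncate_date("2013-06-20", "MONTH")  # "2013-06"
#' @export
truncate_date <- function(date, granularity = c("DAY", "MONTH", "YEAR")) {
  granularity <- match.arg(granularity)
  if (anyNA(date)) {
    abort("truncate_date() does not accept unknown (NA) dates")
  }
  width <- c(DAY = 10L, MONTH = 7L, YEAR = 4L)[[granularity]]
  ifelse(nchar(date) > width, substr(date, 1L, width), date)
}

date_granularity <- function(date) {
  dplyr::case_when(
    is.na(date) ~ NA_character_,
    nchar(date) == 4L ~ "YEAR",
    nchar(date) == 7L ~ "MONTH",
    nchar(date) == 10L ~ "DAY"
  )
}
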