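EVAL_GRANULARITIES <- c("STRICT", "DAY", "MONTH", "YEAR")

# Map one patient's entries to the comparison key set at a granularity.
# STRICT compares the full normalized value verbatim; DAY/MONTH/YEAR
# truncate first. Truncation can merge entries, so sets are deduplicated
# after mapping.
eval_key_set <- function(entries, granularity) {
  if (nrow(entries) == 0) return(character())
  date <- if (granularity == "STRICT") entries$date
          else truncate_date(entries$date, granularity)
  unique(paste(entries$event, entries$relation, date, sep = "\r"))
}

#' Compare one patient's predicted and gold timelines
#'
#' Maps both timelines to sets of `(event, relation, date)` keys at the
#' requested granularity (dates truncated for the relaxed settings,
#' deduplicated after truncation) and computes precision, recall, and F1
#' on the set intersection. Conventions: both sides empty gives (1, 1, 1)
#' — a correct "no therapy" prediction is not penalized; exactly one side
#' empty gives (0, 0, 0); P = R = 0 gives F1 = 0.
#'
#' @param pred,gold Timeline tibbles for the same single patient.
#' @param granularity One of `"STRICT"`, `"DAY"`, `"MONTH"`, `"YEAR"`.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `n_pred`,
#'   `n_gold`, `n_match`.
#' @export
compare_patient <- function(pred, gold,
                            granularity = c("STRICT", "DAY", "MONTH", "YEAR")) {
  granularity <- match.arg(granularity)
  pid <- unique(c(pred$patient_id, gold$patient_id))
  if (length(pid) > 1) {
    abort("compare_patient() received mismatched patient ids")
  }
  pk <- eval_key_set(pred, granularity)
  gk <- eval_key_set(gold, granularity)
  if (length(pk) == 0 && length(gk) == 0) {
    return(tibble::tibble(precision = 1, recall = 1, f1 = 1,
                          n_pred = 0L, n_gold = 0L, n_match = 0L))
  }
  tp <- length(intersect(pk, gk))
  p <- if (length(pk) == 0) 0 else tp / length(pk)
  r <- if (length(gk) == 0) 0 else tp / length(gk)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble::tibble(precision = p, recall = r, f1 = f1,
                 n_pred = length(pk), n_gold = length(gk), n_match = tp)
}

#' Macro-average per-patient F1 scores
#'
#' The unweighted arithmetic mean across patients; patients with empty
#' gold timelines enter through [compare_patient()]'s conventions.
#'
#' @param per_patient_f1 A nonempty numeric vector of per-patient F1s.
#' @return A single number.
#' @export
macro_f1 <- function(per_patient_f1) {
  if (length(per_patient_f1) == 0) abort("macro_f1() needs at least one patient")
  mean(per_patient_f1)
}

#' Evaluate predicted timelines against gold at all granularities
#'
#' Scores each patient with [compare_patient()] at the four temporal
#' granularities and macro-averages F1 across patients. The gold
#' timelines define the patient universe: gold patients missing from the
#' prediction are scored as empty predictions, while predicted patients
#' absent from gold are an error. The relaxed-to-month score is the
#' headline metric.
#'
#' @param pred,gold Timeline tibbles; the patient universe is
#'   `attr(gold, "patients")` when present, else the patients in `gold`.
#' @return An object of class `timeline_eval` with `per_patient` and
#'   `macro` tibbles; see [tidy.timeline_eval()], [glance.timeline_eval()]
#'   and [autoplot.timeline_eval()].
#' @export
evaluate_timelines <- function(pred, gold) {
  validate_timeline_entries(pred)
  validate_timeline_entries(gold)
  universe <- attr(gold, "patients") %||% unique(gold$patient_id)
  universe <- sort(union(universe, unique(gold$patient_id)))
  unknown <- setdiff(unique(pred$patient_id), universe)
  if (length(unknown) > 0) {
    abort(sprintf("predicted patient(s) absent from gold: %s",
                  paste(unknown, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(patient_id = universe,
                             granularity = EVAL_GRANULARITIES)
  per_patient <- purrr::pmap(grid, function(patient_id, granularity) {
    res <- compare_patient(
      dplyr::filter(pred, .data$patient_id == !!patient_id),
      dplyr::filter(gold, .data$patient_id == !!patient_id),
      granularity
    )
    dplyr::bind_cols(tibble::tibble(patient_id = patient_id,
                                    granularity = granularity), res)
  }) |>
    dplyr::bind_rows()
  macro <- per_patient |>
    dplyr::group_by(.data$granularity) |>
    dplyr::summarise(macro_f1 = macro_f1(.data$f1),
                     mean_precision = mean(.data$precision),
                     mean_recall = mean(.data$recall),
                     n_patients = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(headline = .data$granularity == "MONTH")
  structure(list(per_patient = per_patient, macro = macro),
            class = "timeline_eval")
}

#' @export
print.timeline_eval <- function(x, ...) {
  cat("Patient-level timeline evaluation (macro F1 across",
      x$macro$n_patients[1], "patients)\n")
  m <- x$macro
  lab <- c(STRICT = "strict", DAY = "relaxed-to-day",
           MONTH = "relaxed-to-month", YEAR = "relaxed-to-year")
  for (g in EVAL_GRANULARITIES) {
    row <- m[m$granularity == g, ]
    cat(sprintf("  %-17s F1 = %.3f  (P = %.3f, R = %.3f)%s\n",
                lab[[g]], row$macro_f1, row$mean_precision,
                row$mean_recall,
                if (row$headline) "  [headline]" else ""))
  }
  invisible(x)
}

#' Broom-style accessors for `timeline_eval` objects
#'
#' `tidy()` returns the per-patient, per-granularity scores;
#' `glance()` returns one row per granularity of macro-averaged scores.
#'
#' @param x A `timeline_eval` object from [evaluate_timelines()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy timeline_eval
#' @export
tidy.timeline_eval <- function(x, ...) x$per_patient

#' @rdname tidy.timeline_eval
#' @method glance timeline_eval
#' @export
glance.timeline_eval <- function(x, ...) x$macro

#' Plot macro F1 by temporal granularity
#'
#' @param object A `timeline_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot timeline_eval
#' @export
autoplot.timeline_eval <- function(object, ...) {
  m <- dplyr::mutate(object$macro,
                     granularity = factor(.data$granularity,
                                          levels = EVAL_GRANULARITIES))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$granularity, y = .data$macro_f1,
                                  fill = .data$headline)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "steelblue")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "temporal granularity", y = "macro F1",
                  title = "Timeline evaluation by granularity") +
    ggplot2::theme_minimal()
}

#' Plot a patient timeline
#'
#' Dot plot of a patient's summarized timeline entries over calendar
#' time, one row per event string, colored by relation. Month- and
#' year-granularity dates are placed at the start of their period.
#'
#' @param timelines A timeline tibble.
#' @param patient Optional single patient id to plot (default: all).
#' @return A ggplot.
#' @export
plot_timeline <- function(timelines, patient = NULL) {
  validate_timeline_entries(timelines)
  if (!is.null(patient)) {
    timelines <- dplyr::filter(timelines, .data$patient_id %in% patient)
  }
  df <- dplyr::mutate(
    timelines,
    day = as.Date(dplyr::case_when(
      nchar(.data$date) == 4 ~ paste0(.data$date, "-01-01"),
      nchar(.data$date) == 7 ~ paste0(.data$date, "-01"),
      TRUE ~ .data$date
    ))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$event,
                                   color = .data$relation)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~patient_id, scales = "free") +
    ggplot2::labs(x = "date", y = NULL, color = "relation",
                  title = "Summarized SACT timeline") +
    ggplot2::theme_minimal()
}
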