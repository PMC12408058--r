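# Internal helpers shared across modules.

# Slice a note text by a 0-based half-open [start, end) character span.
slice_span <- function(text, start, end) {
  substr(rep_len(text, length(start)), start + 1L, end)
}

# TLINK pairwise label set; NONE is the artifact-internal negative class.
TLINK_LABELS <- c("CONTAINS", "BEGINS-ON", "ENDS-ON", "OVERLAP", "BEFORE")
TLINK_LABELS_NONE <- c(TLINK_LABELS, "NONE")

# Final summarized timeline relation labels.
TIMELINE_RELATIONS <- c("contains-1", "begins-on", "ends-on")

# Map pairwise labels to the summarized relation vocabulary (CONTAINS is
# inverted to contains-1 so every triple reads <event, relation, time>).
tlink_to_relation <- function(label) {
  dplyr::case_match(
    label,
    "CONTAINS" ~ "contains-1",
    "BEGINS-ON" ~ "begins-on",
    "ENDS-ON" ~ "ends-on",
    .default = NA_character_
  )
}

relation_to_tlink <- function(relation) {
  dplyr::case_match(
    relation,
    c("contains-1", "contains") ~ "CONTAINS",
    "begins-on" ~ "BEGINS-ON",
    "ends-on" ~ "ENDS-ON",
    .default = NA_character_
  )
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Empty prototypes so every path returns tibbles with stable schemas.
empty_mentions <- function() {
  tibble::tibble(
    note_id = character(), mention_id = character(),
    mention_type = character(), start = integer(), end = integer(),
    surface = character()
  )
}

empty_instances <- function() {
  tibble::tibble(
    note_id = character(),
    event_id = character(), event_start = integer(), event_end = integer(),
    event_surface = character(),
    timex_id = character(), timex_start = integer(), timex_end = integer(),
    timex_surface = character(),
    token_distance = integer(), window_text = character()
  )
}

empty_timeline <- function() {
  tibble::tibble(
    patient_id = character(), event = character(),
    relation = character(), date = character()
  )
}

new_id <- function(prefix, n) {
  if (n == 0) return(character())
  sprintf("%s%d", prefix, seq_len(n))
}
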