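#' Whitespace tokenization with character offsets
#'
#' Splits note text into tokens delimited by runs of whitespace, recording
#' 0-based half-open character spans into the original text. This is the
#' token definition used everywhere in the package: BIO labels, the
#' inter-mention distance of the pairing window, and lexicon matching all
#' count these tokens.
#'
#' Each token also carries a "core" span with leading and trailing
#' punctuation stripped (`"FOLFOX."` has core `"FOLFOX"`), which is what
#' dictionary matching and BIO span decoding use, so that mentions do not
#' absorb sentence-final punctuation.
#'
#' @param text A character vector of note texts.
#' @return A tibble with one row per token: `text_idx` (index into `text`),
#'   `index` (token position within its text, 1-based), `start`, `end`
#'   (0-based half-open span), `surface`, `core_start`, `core_end`,
#'   `core` (punctuation-stripped form).
#' @examples
#' tokenize("started carboplatin today.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text))
  if (length(text) == 0) return(tokenize_empty())
  matches <- gregexpr("\\S+", text, perl = TRUE)
  rows <- purrr::map2(seq_along(text), matches, function(i, m) {
    if (length(m) == 1 && m[1] == -1) return(NULL)
    start <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    tibble::tibble(
      text_idx = i,
      index = seq_along(start),
      start = start,
      end = start + as.integer(len)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(tokenize_empty())
  out$surface <- slice_span(text[out$text_idx], out$start, out$end)
  core <- token_core(out$surface)
  out$core_start <- out$start + core$lead
  out$core_end <- out$end - core$trail
  # fully punctuational token: core is the token itself
  degenerate <- out$core_start >= out$core_end
  out$core_start[degenerate] <- out$start[degenerate]
  out$core_end[degenerate] <- out$end[degenerate]
  out$core <- slice_span(text[out$text_idx], out$core_start, out$core_end)
  out
}

tokenize_empty <- function() {
  tibble::tibble(
    text_idx = integer(), index = integer(), start = integer(),
    end = integer(), surface = character(), core_start = integer(),
    core_end = integer(), core = character()
  )
}

# Leading/trailing punctuation widths for each token surface.
token_core <- function(surface) {
  lead <- nchar(stringr::str_extract(surface, "^[[:punct:]]*"))
  trail <- nchar(stringr::str_extract(surface, "[[:punct:]]*$"))
  list(lead = as.integer(lead), trail = as.integer(trail))
}
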