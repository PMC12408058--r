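#' The default systemic anticancer therapy lexicon
#'
#' A small dictionary of lowercased drug and therapy phrases (cytotoxic,
#' endocrine, targeted, and immunotherapy agents plus generic therapy
#' terms) used by the dictionary tagger. Shipped as a plain-text file,
#' one phrase per line; pass your own file to extend it.
#'
#' @param path Path to a lexicon file (one lowercase phrase per line).
#'   Defaults to the lexicon shipped with the package.
#' @return A character vector of lowercase phrases.
#' @export
sact_lexicon <- function(path = system.file("extdata", "sact_lexicon.txt",
                                            package = "oncotimelines")) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- tolower(stringr::str_squish(x))
  x <- x[x != "" & !stringr::str_starts(x, "#")]
  if (length(x) == 0) abort("lexicon is empty")
  unique(x)
}

#' Tag SACT EVENT mentions with a dictionary lookup
#'
#' The baseline tagger: case-insensitive longest-match, leftmost-first,
#' non-overlapping lookup of lexicon phrases over whitespace token
#' boundaries. Tokens are compared after stripping leading/trailing
#' punctuation, so `"FOLFOX."` matches the entry `"folfox"` and the
#' emitted span excludes the period.
#'
#' @param notes A data frame with `note_id` and `text` columns.
#' @param lexicon A character vector of lowercase phrases, e.g.
#'   [sact_lexicon()].
#' @return A tibble of EVENT mentions: `note_id`, `mention_id`,
#'   `mention_type`, `start`, `end`, `surface`.
#' @export
tag_events_lexicon <- function(notes, lexicon = sact_lexicon()) {
  assert_cols(notes, c("note_id", "text"), "`notes`")
  if (length(lexicon) == 0) abort("lexicon is empty")
  entries <- stringr::str_split(tolower(lexicon), "\\s+")
  len <- lengths(entries)
  ord <- order(-len)  # longest phrases first
  entries <- entries[ord]; len <- len[ord]
  out <- purrr::map2(notes$note_id, notes$text, function(nid, text) {
    toks <- tokenize(text)
    if (nrow(toks) == 0) return(NULL)
    core <- tolower(toks$core)
    n <- nrow(toks)
    hits <- list(); i <- 1L
    while (i <= n) {
      matched <- 0L
      for (k in seq_along(entries)) {
        L <- len[k]
        if (i + L - 1L > n) next
        if (identical(core[i:(i + L - 1L)], entries[[k]])) {
          matched <- L
          break
        }
      }
      if (matched > 0L) {
        hits[[length(hits) + 1L]] <-
          c(toks$core_start[i], toks$core_end[i + matched - 1L])
        i <- i + matched
      } else {
        i <- i + 1L
      }
    }
    if (length(hits) == 0) return(NULL)
    m <- do.call(rbind, hits)
    tibble::tibble(note_id = nid, start = as.integer(m[, 1]),
                   end = as.integer(m[, 2]),
                   surface = slice_span(text, m[, 1], m[, 2]))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(empty_mentions())
  tibble::tibble(
    note_id = out$note_id, mention_id = paste0("e", seq_len(nrow(out))),
    mention_type = "EVENT", start = out$start, end = out$end,
    surface = out$surface
  )
}

#' Encode and decode BIO label sequences
#'
#' `bio_encode()` turns mention spans into a per-token Begin/Inside/Outside
#' label sequence; `bio_decode()` turns a label sequence back into mention
#' spans. Mentions not aligned to token boundaries are snapped outward to
#' the punctuation-stripped token cores (a message reports how many were
#' snapped). Decoding repairs a dangling `I` (following `O` or at sequence
#' start) as `B`, and emits spans over token cores, so encode-then-decode
#' is the identity for core-aligned, non-overlapping mentions.
#'
#' @param tokens A token tibble from [tokenize()] for a single text.
#' @param mentions A data frame of mention spans with `start` and `end`.
#' @param labels A character vector of `"B"`, `"I"`, `"O"`, one per token.
#' @param text The original text (used by `bio_decode()` for surfaces).
#' @return `bio_encode()`: a character vector of labels. `bio_decode()`:
#'   a tibble with `start`, `end`, `surface`.
#' @export
bio_encode <- function(tokens, mentions) {
  n <- nrow(tokens)
  labels <- rep("O", n)
  if (is.null(mentions) || nrow(mentions) == 0) return(labels)
  mentions <- dplyr::arrange(tibble::as_tibble(mentions), .data$start)
  if (nrow(mentions) > 1 &&
      any(mentions$start[-1] < mentions$end[-nrow(mentions)])) {
    abort("overlapping mentions cannot be BIO-encoded")
  }
  snapped <- 0L
  for (i in seq_len(nrow(mentions))) {
    s <- mentions$start[i]; e <- mentions$end[i]
    inside <- which(tokens$core_start < e & tokens$core_end > s)
    if (length(inside) == 0) next
    if (tokens$core_start[inside[1]] != s ||
        tokens$core_end[inside[length(inside)]] != e) {
      snapped <- snapped + 1L
    }
    labels[inside[1]] <- "B"
    if (length(inside) > 1) labels[inside[-1]] <- "I"
  }
  if (snapped > 0) {
    message(sprintf("bio_encode: snapped %d mention(s) to token boundaries",
                    snapped))
  }
  labels
}

#' @rdname bio_encode
#' @export
bio_decode <- function(tokens, labels, text) {
  stopifnot(length(labels) == nrow(tokens))
  runs <- list(); current <- NULL
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "O") {
      if (!is.null(current)) { runs[[length(runs) + 1L]] <- current }
      current <- NULL
    } else if (lab == "B" || is.null(current)) {  # dangling I repaired as B
      if (!is.null(current)) runs[[length(runs) + 1L]] <- current
      current <- c(i, i)
    } else {
      current[2] <- i
    }
  }
  if (!is.null(current)) runs[[length(runs) + 1L]] <- current
  if (length(runs) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          surface = character()))
  }
  m <- do.call(rbind, runs)
  start <- tokens$core_start[m[, 1]]
  end <- tokens$core_end[m[, 2]]
  tibble::tibble(start = start, end = end,
                 surface = slice_span(text, start, end))
}

# Token-local feature strings for the sequence labeler: lowercased form,
# 3-character affixes, word shape, and neighbor identities within +-2.
token_features <- function(toks) {
  w <- tolower(toks$core)
  shape <- paste0(
    "sh=",
    ifelse(stringr::str_detect(toks$core, "\\d"), "D", "-"),
    ifelse(stringr::str_detect(toks$core, "^[A-Z]"), "C", "-"),
    ifelse(stringr::str_detect(toks$core, "^[A-Z]+$"), "U", "-"),
    ifelse(stringr::str_detect(toks$surface, "[[:punct:]]"), "P", "-")
  )
  pad <- function(x, k) {
    n <- length(x)
    if (k > 0) c(x[-seq_len(min(k, n))], rep("<pad>", min(k, n)))
    else c(rep("<pad>", min(-k, n)), x[seq_len(max(n + k, 0))])
  }
  purrr::pmap(list(
    paste0("w=", w),
    paste0("p3=", substr(w, 1, 3)),
    paste0("s3=", stringr::str_sub(w, -3)),
    shape,
    paste0("w-1=", pad(w, -1)), paste0("w-2=", pad(w, -2)),
    paste0("w+1=", pad(w, 1)), paste0("w+2=", pad(w, 2))
  ), c)
}

# Ridge fits are computed along an explicit descending lambda path ending
# at the requested penalty: warm starts keep the small-lambda solution
# stable (glmnet's automatic path is poorly scaled for alpha = 0).
ridge_path <- function(lambda) {
  10^seq(1, log10(lambda), length.out = 25)
}

feature_matrix <- function(feat_list, vocab) {
  idx <- purrr::imap(feat_list, function(f, i) {
    j <- match(f, vocab)
    j <- j[!is.na(j)]
    cbind(rep(i, length(j)), j)
  })
  ij <- do.call(rbind, idx)
  Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                       dims = c(length(feat_list), length(vocab)))
}

#' Train a feature-based BIO sequence tagger for SACT events
#'
#' Fits a regularized multinomial logistic model over sparse token-local
#' features (lowercased form, affixes, word shape, neighbors within two
#' tokens) predicting Begin/Inside/Outside labels derived from gold EVENT
#' mentions. A lightweight, CPU-only stand-in with the same
#' predict-spans contract as a neural tagger, which can be plugged in
#' instead (see [tag_events_model()]).
#'
#' @param notes Training notes (`note_id`, `text`).
#' @param mentions Gold EVENT mentions for those notes (`note_id`,
#'   `start`, `end`).
#' @param lambda Ridge penalty passed to [glmnet::glmnet()].
#' @param seed Integer seed (training is deterministic given the data;
#'   the seed is fixed for contract completeness).
#' @return An object of class `sact_tagger` (feature vocabulary + fitted
#'   model + version tag), serializable with `saveRDS()`.
#' @export
train_event_tagger <- function(notes, mentions, lambda = 0.01, seed = 1L) {
  assert_cols(notes, c("note_id", "text"), "`notes`")
  if (nrow(notes) == 0) abort("empty training set")
  set.seed(seed)
  feats <- list(); labels <- character()
  for (i in seq_len(nrow(notes))) {
    toks <- tokenize(notes$text[i])
    if (nrow(toks) == 0) next
    ms <- dplyr::filter(mentions, .data$note_id == notes$note_id[i])
    labels <- c(labels, bio_encode(toks, ms))
    feats <- c(feats, token_features(toks))
  }
  if (!any(labels == "B")) {
    abort("training set contains no EVENT mentions")
  }
  vocab <- sort(unique(unlist(feats)))
  x <- feature_matrix(feats, vocab)
  # drop unobserved classes (e.g. no multi-token mentions means no "I")
  y <- droplevels(factor(labels, levels = c("B", "I", "O")))
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                        lambda = ridge_path(lambda), standardize = FALSE)
  structure(list(vocab = vocab, fit = fit, lambda = lambda,
                 classes = levels(y), version = "sact_tagger/1"),
            class = "sact_tagger")
}

#' Tag SACT EVENT mentions with a trained sequence tagger
#'
#' Predicts per-token BIO labels with a model from [train_event_tagger()]
#' (or any plug-in object implementing the same contract via a
#' `predict_bio(model, tokens)` method) and decodes them into mention
#' spans. Deterministic.
#'
#' @param model A `sact_tagger` object.
#' @inheritParams tag_events_lexicon
#' @return A tibble of EVENT mentions (same schema as
#'   [tag_events_lexicon()]).
#' @export
tag_events_model <- function(notes, model) {
  assert_cols(notes, c("note_id", "text"), "`notes`")
  out <- purrr::map2(notes$note_id, notes$text, function(nid, text) {
    toks <- tokenize(text)
    if (nrow(toks) == 0) return(NULL)
    labels <- predict_bio(model, toks)
    dec <- bio_decode(toks, labels, text)
    if (nrow(dec) == 0) return(NULL)
    dec$note_id <- nid
    dec
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(empty_mentions())
  tibble::tibble(
    note_id = out$note_id, mention_id = paste0("e", seq_len(nrow(out))),
    mention_type = "EVENT", start = out$start, end = out$end,
    surface = out$surface
  )
}

predict_bio <- function(model, tokens) UseMethod("predict_bio")

#' @export
predict_bio.sact_tagger <- function(model, tokens) {
  x <- feature_matrix(token_features(tokens), model$vocab)
  as.character(predict(model$fit, newx = x, s = model$lambda,
                       type = "class"))
}

#' Score predicted mentions against gold mentions
#'
#' Exact-span precision/recall/F1: a predicted mention counts as correct
#' iff a gold mention with the same `(note_id, start, end)` exists.
#'
#' @param pred,gold Mention tibbles with `note_id`, `start`, `end`.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `n_pred`,
#'   `n_gold`, `n_match`.
#' @export
evaluate_mentions <- function(pred, gold) {
  key <- function(m) paste(m$note_id, m$start, m$end, sep = "\r")
  pk <- unique(key(pred)); gk <- unique(key(gold))
  tp <- length(intersect(pk, gk))
  p <- if (length(pk) == 0) 0 else tp / length(pk)
  r <- if (length(gk) == 0) 0 else tp / length(gk)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble::tibble(precision = p, recall = r, f1 = f1,
                 n_pred = length(pk), n_gold = length(gk), n_match = tp)
}
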