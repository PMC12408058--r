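#' Build labeled training instances from gold annotations
#'
#' Joins window instances against gold TLINKs (matched on note id and the
#' two mention spans) to obtain positive labels, and synthesizes the NONE
#' negative class from in-window pairs that carry no gold TLINK,
#' downsampled to `none_ratio` times the number of positives (seeded).
#'
#' @param instances Instances from [make_window_instances()] built over
#'   gold mentions.
#' @param tlinks Gold TLINK tibble (`note_id`, `event_id`, `timex_id`,
#'   `label`).
#' @param none_ratio Maximum NONE negatives per positive.
#' @param seed Integer seed for negative downsampling.
#' @return A labeled instance tibble suitable for
#'   [train_relation_model()].
#' @export
make_training_instances <- function(instances, tlinks, none_ratio = 2,
                                    seed = 1L) {
  if (nrow(instances) == 0) return(dplyr::mutate(instances, label = character()))
  labeled <- dplyr::left_join(
    instances, tlinks,
    by = c("note_id", "event_id", "timex_id")
  )
  pos <- dplyr::filter(labeled, !is.na(.data$label))
  neg <- dplyr::filter(labeled, is.na(.data$label))
  neg$label <- "NONE"
  n_keep <- min(nrow(neg), ceiling(none_ratio * nrow(pos)))
  if (n_keep < nrow(neg)) {
    set.seed(seed)
    neg <- neg[sort(sample.int(nrow(neg), n_keep)), , drop = FALSE]
  }
  dplyr::bind_rows(pos, neg)
}

# Oracle labeling: gold TLINK label where one exists, NONE otherwise.
# Used by the Subtask1 oracle path of run_pipeline().
label_with_gold <- function(instances, tlinks) {
  labeled <- dplyr::left_join(
    instances, tlinks,
    by = c("note_id", "event_id", "timex_id")
  )
  labeled$label[is.na(labeled$label)] <- "NONE"
  labeled
}
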