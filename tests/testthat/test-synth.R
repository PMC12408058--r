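test_that("generation is deterministic given the seed", {
  a <- generate_corpus(4, 3, noise = noise_config(seed = 42))
  b <- generate_corpus(4, 3, noise = noise_config(seed = 42))
  expect_identical(a$notes$text, b$notes$text)
  expect_equal(as.data.frame(a$mentions), as.data.frame(b$mentions))
  expect_equal(as.data.frame(a$timelines), as.data.frame(b$timelines))
  c <- generate_corpus(4, 3, noise = noise_config(seed = 43))
  expect_false(identical(a$notes$text, c$notes$text))
})

test_that("every patient receives a gold timeline", {
  corpus <- generate_corpus(5, 2, noise = noise_config(seed = 8))
  expect_equal(dplyr::n_distinct(corpus$notes$patient_id), 5)
  expect_setequal(attr(corpus$timelines, "patients"),
                  unique(corpus$notes$patient_id))
})

test_that("gold annotations satisfy the span and surface invariants", {
  corpus <- generate_corpus(6, 3,
                            noise = noise_config(0.3, 0.3, 0.3, 0.3,
                                                 seed = 15))
  m <- dplyr::left_join(corpus$mentions,
                        dplyr::select(corpus$notes, note_id, text),
                        by = "note_id")
  expect_true(all(m$start >= 0 & m$start < m$end &
                    m$end <= nchar(m$text)))
  expect_equal(m$surface, substr(m$text, m$start + 1, m$end))
  # TLINKs reference existing mentions of the right types
  key <- paste(corpus$mentions$note_id, corpus$mentions$mention_id)
  expect_true(all(paste(corpus$tlinks$note_id, corpus$tlinks$event_id)
                  %in% key))
  expect_true(all(paste(corpus$tlinks$note_id, corpus$tlinks$timex_id)
                  %in% key))
  expect_true(all(corpus$tlinks$label %in%
                    c("CONTAINS", "BEGINS-ON", "ENDS-ON", "OVERLAP",
                      "BEFORE")))
})

test_that("every gold TLINK's time normalizes to a gold timeline date", {
  corpus <- generate_corpus(5, 3,
                            noise = noise_config(0.2, 0.2, 0, 0.4,
                                                 seed = 77))
  joined <- corpus$tlinks |>
    dplyr::left_join(dplyr::select(corpus$mentions, note_id, mention_id,
                                   surface),
                     by = c("note_id", "timex_id" = "mention_id")) |>
    dplyr::left_join(dplyr::select(corpus$notes, note_id, doctime),
                     by = "note_id")
  norm <- normalize_timex(joined$surface, joined$doctime)
  expect_false(any(is.na(norm)))
  # entries with timeline-bearing labels appear in the gold timeline
  keep <- joined$label %in% c("CONTAINS", "BEGINS-ON", "ENDS-ON")
  expect_true(all(norm[keep] %in% corpus$timelines$date))
})

test_that("the demo platinum-doublet course has the canonical 11 entries", {
  corpus <- demo_corpus(seed = 2)
  tl <- corpus$timelines
  expect_equal(nrow(tl), 11)
  expect_true(all(tl$relation == "contains-1"))
  expect_setequal(unique(tl$event), c("chemotherapy", "carboplatin",
                                      "taxol"))
  expect_true("2013-06-20" %in% tl$date)
  expect_equal(sum(tl$event == "taxol"), 5)
})

test_that("the corruption report counts seeded phenomena", {
  zero <- generate_corpus(4, 3, noise = noise_config(seed = 5))
  r0 <- corruption_report(zero)
  expect_equal(r0$hedged + r0$heading + r0$confounder + r0$relative_date, 0)
  noisy <- generate_corpus(4, 3,
                           noise = noise_config(1, 0, 1, 1, seed = 5))
  rn <- corruption_report(noisy)
  expect_gt(rn$hedged, 0)
  expect_gt(rn$confounder, 0)
  # hedging converts administration facts, so heading noise is counted on
  # its own corpus
  headed <- generate_corpus(4, 3,
                            noise = noise_config(p_heading = 1, seed = 5))
  expect_gt(corruption_report(headed)$heading, 0)
  # reproducible under the same seed
  rn2 <- corruption_report(generate_corpus(4, 3,
                                           noise = noise_config(1, 0, 1, 1,
                                                                seed = 5)))
  expect_equal(as.data.frame(rn), as.data.frame(rn2))
  expect_error(corruption_report(list()), "generate_corpus")
})

test_that("heading probability one puts a heading in every eligible note", {
  corpus <- generate_corpus(5, 3, noise = noise_config(p_heading = 1,
                                                       seed = 21))
  per_note <- corpus$sentences |>
    dplyr::group_by(note_id) |>
    dplyr::summarise(has_heading = any(heading),
                     n = dplyr::n())
  # notes that carry administration facts render them under headings
  hd <- apply_date_heading_rule(corpus$notes, gold_events(corpus))
  expect_gt(nrow(hd), 0)
  expect_gt(sum(per_note$has_heading), 0)
})

test_that("invalid noise configuration is rejected", {
  expect_error(noise_config(p_hedge = 1.5), "probabilities")
  expect_error(generate_corpus(0, 3), "n_patients")
})
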