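mk_mentions <- function(note_id, starts, ends, type, prefix) {
  tibble::tibble(note_id = note_id,
                 mention_id = paste0(prefix, seq_along(starts)),
                 mention_type = type, start = starts, end = ends,
                 surface = NA_character_)
}

test_that("windowing pairs mentions within the token cap with markers", {
  text <- "Started carboplatin on 2013-04-10 after the meeting"
  notes <- tibble::tibble(note_id = "n1", text = text)
  events <- tibble::tibble(note_id = "n1", mention_id = "e1",
                           mention_type = "EVENT", start = 8L, end = 19L,
                           surface = "carboplatin")
  timexes <- tibble::tibble(note_id = "n1", mention_id = "t1",
                            mention_type = "TIMEX3", start = 23L, end = 33L,
                            surface = "2013-04-10")
  inst <- make_window_instances(notes, events, timexes)
  expect_equal(nrow(inst), 1)
  expect_equal(inst$token_distance, 1L)  # "on" lies between
  expect_true(grepl("<e>carboplatin</e>", inst$window_text, fixed = TRUE))
  expect_true(grepl("<t>2013-04-10</t>", inst$window_text, fixed = TRUE))
})

test_that("pairs beyond the configured distance are not generated", {
  far <- paste(rep("w", 61), collapse = " ")
  text <- paste0("carboplatin ", far, " 2013-04-10")
  notes <- tibble::tibble(note_id = "n1", text = text)
  events <- mk_mentions("n1", 0L, 11L, "EVENT", "e")
  timexes <- mk_mentions("n1", nchar(text) - 10L, nchar(text), "TIMEX3", "t")
  expect_equal(nrow(make_window_instances(notes, events, timexes)), 0)
  wide <- window_config(max_token_distance = 61L)
  expect_equal(nrow(make_window_instances(notes, events, timexes, wide)), 1)
})

test_that("two events and two timexes in range give the full Cartesian set", {
  text <- "Received carboplatin and Taxol on 2013-04-10 then 4/17/2013 noted"
  notes <- tibble::tibble(note_id = "n1", text = text)
  events <- mk_mentions("n1", c(9L, 25L), c(20L, 30L), "EVENT", "e")
  timexes <- mk_mentions("n1", c(34L, 50L), c(44L, 59L), "TIMEX3", "t")
  inst <- make_window_instances(notes, events, timexes)
  expect_equal(nrow(inst), 4)
  # each window has exactly one marker pair of each kind
  for (w in inst$window_text) {
    expect_equal(stringr::str_count(w, stringr::fixed("<e>")), 1)
    expect_equal(stringr::str_count(w, stringr::fixed("</e>")), 1)
    expect_equal(stringr::str_count(w, stringr::fixed("<t>")), 1)
    expect_equal(stringr::str_count(w, stringr::fixed("</t>")), 1)
  }
})

test_that("window generation matches the brute-force pairer on random layouts", {
  set.seed(77)
  for (rep in 1:60) {
    lay <- random_layout(n_tokens = sample(40:160, 1),
                         n_events = sample(1:4, 1),
                         n_timexes = sample(1:4, 1))
    notes <- tibble::tibble(note_id = "n1", text = lay$text)
    inst <- make_window_instances(notes, lay$events, lay$timexes)
    oracle <- bf_pair(lay$text, lay$events, lay$timexes, 60L)
    n_oracle <- if (is.null(oracle)) 0L else nrow(oracle)
    expect_equal(nrow(inst), n_oracle)
    if (n_oracle > 0) {
      got <- paste(inst$event_id, inst$timex_id, inst$token_distance)
      want <- paste(oracle$event_id, oracle$timex_id, oracle$dist)
      expect_setequal(got, want)
    }
  }
})

test_that("the rule classifier labels the canonical trigger patterns", {
  expect_equal(
    classify_rule_based(
      "The patient started a regimen of <e>Taxol</e> on <t>August 1, 2012</t>."),
    "BEGINS-ON")
  expect_equal(
    classify_rule_based(
      "<e>Anastrozole</e> 1 mg daily by mouth. Last dose : <t>10/18/2033</t>."),
    "ENDS-ON")
  expect_equal(
    classify_rule_based(
      "Received <e>carboplatin</e> on <t>2013-04-10</t>."),
    "CONTAINS")
  expect_equal(
    classify_rule_based(
      "discussed <e>chemotherapy</e> options near <t>last week</t>"),
    "NONE")
})

test_that("the rule classifier is a pure function of the window text", {
  w <- "Completed <e>FOLFOX</e> on <t>July 2055</t>."
  expect_equal(classify_rule_based(rep(w, 3)), rep("ENDS-ON", 3))
})

test_that("an intervening date or boundary blocks cross-pairings", {
  # nearer date between the pair
  expect_equal(classify_rule_based(
    "Received <e>carboplatin</e> on 2013-04-10. Seen <t>2013-05-12</t>."),
    "NONE")
  # event after a cross-sentence end trigger is not linked
  expect_equal(classify_rule_based(
    "Last dose : <t>10/18/2033</t>. Started <e>Taxol</e> later."),
    "NONE")
})

test_that("date headings pair section events as CONTAINS candidates", {
  text <- paste0("Interval history.\n",
                 "July 2055:\n12 cycles of FOLFOX.\n",
                 "December 2055:\n2 cycles of XELIRI.")
  notes <- tibble::tibble(note_id = "n1", text = text)
  events <- tag_events_lexicon(notes, c("folfox", "xeliri"))
  got <- apply_date_heading_rule(notes, events)
  expect_equal(nrow(got), 2)
  expect_true(all(got$label == "CONTAINS"))
  expect_equal(got$timex_surface[got$event_surface == "FOLFOX"], "July 2055")
  expect_equal(got$timex_surface[got$event_surface == "XELIRI"],
               "December 2055")
  # no headings -> nothing; adjacent headings -> empty first section
  expect_equal(nrow(apply_date_heading_rule(
    tibble::tibble(note_id = "n", text = "Nothing here."), events)), 0)
  text2 <- "July 2055:\nDecember 2055:\n2 cycles of XELIRI."
  got2 <- apply_date_heading_rule(tibble::tibble(note_id = "n1", text = text2),
                                  tag_events_lexicon(
                                    tibble::tibble(note_id = "n1", text = text2),
                                    c("xeliri")))
  expect_equal(got2$timex_surface, "December 2055")
})

test_that("a two-date heading pairs events with both endpoints", {
  text <- "July 2055 through December 2055:\n12 cycles of FOLFOX."
  notes <- tibble::tibble(note_id = "n1", text = text)
  events <- tag_events_lexicon(notes, c("folfox"))
  got <- apply_date_heading_rule(notes, events)
  expect_setequal(got$timex_surface, c("July 2055", "December 2055"))
  expect_true(all(got$label == "CONTAINS"))
})

test_that("the trained relation classifier is deterministic and accurate", {
  train <- generate_corpus(15, 3, model = regimen_model(p_minor = 0.4),
                           noise = noise_config(seed = 301))
  test <- generate_corpus(6, 3, model = regimen_model(p_minor = 0.4),
                          noise = noise_config(seed = 302))
  mk <- function(cp) make_window_instances(cp$notes, gold_events(cp),
                                           gold_timexes(cp))
  tri <- make_training_instances(mk(train), train$tlinks, seed = 7)
  m1 <- suppressWarnings(train_relation_model(tri, seed = 7))
  m2 <- suppressWarnings(train_relation_model(tri, seed = 7))
  held <- make_training_instances(mk(test), test$tlinks, seed = 8)
  p1 <- classify_relations(held[setdiff(names(held), "label")], "model", m1)
  p2 <- classify_relations(held[setdiff(names(held), "label")], "model", m2)
  expect_equal(p1$label, p2$label)
  acc <- mean(p1$label == held$label)
  majority <- max(table(held$label)) / nrow(held)
  expect_gt(acc, 0.9)
  expect_gt(acc, majority)
})

test_that("classification contracts hold for plug-ins and degenerate input", {
  inst <- empty_instances <- make_window_instances(
    tibble::tibble(note_id = "n", text = "nothing"),
    tibble::tibble(note_id = character(), mention_id = character(),
                   mention_type = character(), start = integer(),
                   end = integer(), surface = character()),
    tibble::tibble(note_id = character(), mention_id = character(),
                   mention_type = character(), start = integer(),
                   end = integer(), surface = character()))
  expect_equal(nrow(classify_relations(inst, "rules")), 0)
  notes <- tiny_notes()
  ev <- tag_events_lexicon(notes, sact_lexicon())
  tx <- detect_timex(notes)
  inst <- make_window_instances(notes, ev, tx)
  expect_error(classify_relations(inst, function(x) rep("AFTER", nrow(x))),
               "label")
  expect_error(classify_relations(inst, function(x) "CONTAINS"),
               "one label per instance")
  expect_error(train_relation_model(inst[0, ] |>
                                      dplyr::mutate(label = character())),
               "empty")
  one_label <- dplyr::mutate(inst, label = "CONTAINS")
  expect_error(train_relation_model(one_label), "two distinct labels")
})
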