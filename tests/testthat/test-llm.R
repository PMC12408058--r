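test_that("step-1 prompts embed the system instruction and 12 exemplars", {
  t1 <- prompt_template(1L)
  p <- build_step1_prompt("Received carboplatin on 2013-04-10.", t1)
  expect_true(grepl("You are a helpful assistant for oncologists.", p,
                    fixed = TRUE))
  expect_true(grepl("BEGINS-ON, ENDS-ON, CONTAINS", p, fixed = TRUE))
  # 12 exemplars plus the query sentence
  expect_equal(stringr::str_count(p, "Input: "), 13)
  expect_identical(p, build_step1_prompt("Received carboplatin on 2013-04-10.",
                                         t1))
})

test_that("step-2 prompts pose the doctime-anchored question", {
  t2 <- prompt_template(2L)
  p <- build_step2_prompt("yesterday", as.Date("2013-05-02"), t2)
  expect_true(grepl("If today was 2013-05-02", p, fixed = TRUE))
  expect_true(grepl('"yesterday"', p, fixed = TRUE))
  expect_true(grepl('Answer "Unknown" if you don\'t know.', p, fixed = TRUE))
  expect_equal(stringr::str_count(p, "Input: "), 6)  # 5 exemplars + query
})

test_that("templates with deviating exemplar counts are rejected", {
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Input: a", "Output: ['x', 'CONTAINS-1', '2013']"), bad)
  expect_error(prompt_template(1L, bad), "4 exemplars per label")
  expect_error(prompt_template(2L, bad), "5 exemplars")
})

test_that("sentence selection returns event-bearing sentences intact", {
  notes <- tibble::tibble(
    note_id = "n1",
    text = paste("Oncology visit with Dr. Smith.",
                 "Started carboplatin on 2013-04-10.",
                 "No other complaints today.",
                 "The last 4 cycles were 5-FU/leucovorin.")
  )
  events <- tag_events_lexicon(notes, sact_lexicon())
  s <- select_sentences(notes, events)
  expect_equal(nrow(s), 2)
  expect_true(any(grepl("carboplatin", s$text)))
  expect_true(any(grepl("5-FU/leucovorin", s$text)))
  # abbreviation "Dr." did not split the first sentence
  expect_false(any(grepl("^Smith", s$text)))
  expect_equal(nrow(select_sentences(notes, events[0, ])), 0)
})

test_that("sentence boundaries never cut an event mention", {
  corpus <- generate_corpus(6, 3,
                            noise = noise_config(p_relative_date = 0.4,
                                                 seed = 17))
  events <- gold_events(corpus)
  s <- select_sentences(corpus$notes, events)
  for (i in seq_len(nrow(s))) {
    ev <- events[events$note_id == s$note_id[i], ]
    cut <- ev$start < s$end[i] & ev$end > s$end[i]
    expect_false(any(cut))
  }
})

test_that("the step-1 parser is total and corrects directionality", {
  out <- parse_step1_output(paste(
    "['taxol', 'contains-1', '2013-08-08']",
    "['folfox', 'CONTAINS', 'July 2055']",
    "['folfox', 'AFTER', '2055']",
    "complete garbage line",
    sep = "\n"))
  expect_equal(nrow(out$triples), 2)
  expect_equal(out$triples$relation, c("contains-1", "contains-1"))
  expect_equal(out$n_dropped, 2)
  expect_equal(out$n_corrected, 1)
  expect_equal(out$n_lines, 4)
  # conservation: parsed + dropped = lines
  expect_equal(nrow(out$triples) + out$n_dropped, out$n_lines)
  # totality on junk
  expect_equal(nrow(parse_step1_output("")$triples), 0)
  expect_equal(nrow(parse_step1_output(NULL)$triples), 0)
})

test_that("directionality correction is idempotent", {
  once <- parse_step1_output("['folfox', 'CONTAINS', 'July 2055']")
  line2 <- sprintf("['%s', '%s', '%s']", once$triples$event,
                   once$triples$relation, once$triples$time_surface)
  twice <- parse_step1_output(line2)
  expect_equal(twice$triples, once$triples)
  expect_equal(twice$n_corrected, 0)
})

test_that("the step-2 parser extracts the first well-formed date", {
  expect_equal(parse_step2_output("2013-05-01"), "2013-05-01")
  expect_equal(parse_step2_output("The date is 2013-05-01."), "2013-05-01")
  expect_equal(parse_step2_output("2055-07"), "2055-07")
  expect_true(is.na(parse_step2_output("Unknown")))
  expect_true(is.na(parse_step2_output("no date at all")))
  expect_true(is.na(parse_step2_output("maybe 2013-13-40?")))
})

test_that("the mock-backed pipeline reproduces gold timelines", {
  corpus <- generate_corpus(5, 3, noise = noise_config(seed = 23))
  events <- gold_events(corpus)
  out <- run_llm_pipeline(corpus$notes, events, backend_gold_mock(corpus))
  ev <- evaluate_timelines(out$timelines, corpus$timelines)
  expect_equal(glance(ev)$macro_f1, rep(1, 4))
  # reversed-CONTAINS mock matches after directionality correction
  out_rev <- run_llm_pipeline(corpus$notes, events,
                              backend_gold_mock(corpus,
                                                reversed_contains = TRUE))
  expect_equal(as.data.frame(out$timelines),
               as.data.frame(out_rev$timelines))
  expect_gt(out_rev$report$corrections, 0)
})

test_that("a junk backend yields empty timelines and full parse drops", {
  corpus <- generate_corpus(3, 2, noise = noise_config(seed = 29))
  out <- run_llm_pipeline(corpus$notes, gold_events(corpus),
                          backend_gold_mock(corpus, junk = TRUE))
  expect_equal(nrow(out$timelines), 0)
  expect_equal(out$report$parse_drops, out$report$step1_lines)
  expect_setequal(attr(out$timelines, "patients"),
                  unique(corpus$notes$patient_id))
})

test_that("backend exceptions are recorded and the run continues", {
  corpus <- generate_corpus(2, 2, noise = noise_config(seed = 31))
  flaky <- local({
    n <- 0L
    gold <- backend_gold_mock(corpus)
    function(prompt) {
      n <<- n + 1L
      if (n %% 3 == 0) stop("backend down")
      gold(prompt)
    }
  })
  out <- run_llm_pipeline(corpus$notes, gold_events(corpus), flaky)
  expect_gt(out$report$backend_failures, 0)
  expect_s3_class(out$timelines, "tbl_df")
})
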