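tl <- function(pid, event, relation, date) {
  tibble::tibble(patient_id = pid, event = event, relation = relation,
                 date = date)
}

test_that("identical timelines score perfectly at every granularity", {
  x <- tl("p1", c("taxol", "carboplatin"), "contains-1",
          c("2013-06-20", "2013-07-18"))
  for (g in c("STRICT", "DAY", "MONTH", "YEAR")) {
    s <- compare_patient(x, x, g)
    expect_equal(c(s$precision, s$recall, s$f1), c(1, 1, 1))
  }
})

test_that("day-level mismatch within a month scores 0 strict, 1 at month", {
  pred <- tl("p1", "taxol", "contains-1", "2013-06-21")
  gold <- tl("p1", "taxol", "contains-1", "2013-06-20")
  expect_equal(compare_patient(pred, gold, "STRICT")$f1, 0)
  expect_equal(compare_patient(pred, gold, "DAY")$f1, 0)
  expect_equal(compare_patient(pred, gold, "MONTH")$f1, 1)
  expect_equal(compare_patient(pred, gold, "YEAR")$f1, 1)
})

test_that("partial overlap follows the P/R/F1 formulas exactly", {
  gold <- tl("p1", c("a", "b", "c"), "contains-1",
             c("2013-01-01", "2013-02-02", "2013-03-03"))
  pred <- tl("p1", c("a", "x"), "contains-1", c("2013-01-01", "2014-05-05"))
  s <- compare_patient(pred, gold, "STRICT")
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 1 / 3, tolerance = 1e-12)
  expect_equal(s$f1, 0.4, tolerance = 1e-12)
})

test_that("empty-timeline conventions hold", {
  none <- tl(character(), character(), character(), character())
  some <- tl("p1", "taxol", "contains-1", "2013-06-20")
  both_empty <- compare_patient(dplyr::mutate(none, patient_id = character()),
                                none, "MONTH")
  expect_equal(both_empty$f1, 1)
  expect_equal(compare_patient(none, some, "MONTH")$f1, 0)
  expect_equal(compare_patient(some, none, "MONTH")$f1, 0)
})

test_that("swapping prediction and gold swaps precision and recall", {
  set.seed(12)
  for (i in 1:20) {
    a <- random_timeline("p1", sample(0:6, 1))
    b <- random_timeline("p1", sample(0:6, 1))
    for (g in c("STRICT", "DAY", "MONTH", "YEAR")) {
      ab <- compare_patient(a, b, g)
      ba <- compare_patient(b, a, g)
      expect_equal(ab$precision, ba$recall)
      expect_equal(ab$recall, ba$precision)
      expect_equal(ab$f1, ba$f1)
    }
  }
})

test_that("comparison equals the brute-force oracle on random pairs", {
  set.seed(99)
  for (i in 1:250) {
    a <- random_timeline("p1", sample(0:8, 1))
    b <- random_timeline("p1", sample(0:8, 1))
    for (g in c("STRICT", "DAY", "MONTH", "YEAR")) {
      got <- compare_patient(a, b, g)
      want <- bf_compare_patient(a, b, g)
      expect_equal(c(got$precision, got$recall, got$f1), want,
                   tolerance = 1e-9)
    }
  }
})

test_that("macro F1 is the unweighted mean and rejects empty input", {
  expect_equal(macro_f1(c(1, 0, 0.5)), 0.5)
  expect_equal(macro_f1(rep(1, 7)), 1)
  expect_equal(macro_f1(0.42), 0.42)
  expect_error(macro_f1(numeric()), "at least one")
})

test_that("corpus evaluation treats gold as the patient universe", {
  gold <- tl(c("p1", "p2"), c("taxol", "folfox"), "contains-1",
             c("2013-06-20", "2055-07"))
  attr(gold, "patients") <- c("p1", "p2", "p3")
  pred <- gold[1, ]
  ev <- evaluate_timelines(pred, gold)
  g <- glance(ev)
  expect_equal(nrow(g), 4)
  # p1 perfect, p2 empty-vs-nonempty 0, p3 both-empty 1 -> macro 2/3
  expect_equal(g$macro_f1[g$granularity == "MONTH"], 2 / 3,
               tolerance = 1e-12)
  expect_true(g$headline[g$granularity == "MONTH"])
  expect_error(evaluate_timelines(tl("p9", "x", "contains-1", "2013"), gold),
               "absent from gold")
  td <- tidy(ev)
  expect_equal(nrow(td), 12)
  expect_true(all(td$f1 >= 0 & td$f1 <= 1))
})

test_that("day-jittered predictions separate strict from month scores", {
  gold <- tl("p1", rep("taxol", 3), "contains-1",
             c("2013-06-10", "2013-07-10", "2013-08-10"))
  pred <- tl("p1", rep("taxol", 3), "contains-1",
             c("2013-06-13", "2013-07-08", "2013-08-11"))
  ev <- evaluate_timelines(pred, gold)
  g <- glance(ev)
  expect_lt(g$macro_f1[g$granularity == "STRICT"], 1)
  expect_equal(g$macro_f1[g$granularity == "MONTH"], 1)
})

test_that("strict-matched entries stay matched at coarser granularities", {
  set.seed(4)
  for (i in 1:20) {
    a <- random_timeline("p1", 5)
    s_strict <- compare_patient(a, a, "STRICT")
    for (g in c("DAY", "MONTH", "YEAR")) {
      expect_equal(compare_patient(a, a, g)$f1, 1)
    }
    expect_equal(s_strict$f1, 1)
  }
})

test_that("the evaluation object plots and prints", {
  gold <- tl("p1", "taxol", "contains-1", "2013-06-20")
  ev <- evaluate_timelines(gold, gold)
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
  expect_output(print(ev), "relaxed-to-month")
  p2 <- plot_timeline(gold)
  expect_s3_class(p2, "ggplot")
})
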