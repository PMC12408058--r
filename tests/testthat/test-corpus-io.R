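write_tiny_corpus <- function(dir, doctimes = c("2013-05-02", "2013-06-01",
                                                "2014-01-01", "2014-02-02")) {
  notes <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p2"),
    note_id = c("n1", "n2", "n3", "n4"),
    doctime = as.Date(doctimes),
    text = c("Started carboplatin on 2013-04-10.",
             "Completed carboplatin on May 20, 2013.",
             "Received Taxol yesterday.", "")
  )
  write_corpus(notes, dir)
  notes
}

test_that("a corpus round-trips through the manifest layout", {
  dir <- withr::local_tempdir()
  notes <- write_tiny_corpus(dir)
  got <- read_corpus(dir)
  expect_equal(nrow(got), 4)
  expect_equal(dplyr::n_distinct(got$patient_id), 2)
  expect_equal(as.data.frame(got), as.data.frame(notes))
})

test_that("non-ISO doctime, duplicates, and missing files are hard errors", {
  dir <- withr::local_tempdir()
  write_tiny_corpus(dir)
  manifest <- readr::read_tsv(file.path(dir, "notes.tsv"),
                              col_types = "cccc", progress = FALSE)
  bad <- manifest
  bad$doctime[1] <- "2013/05/02"
  readr::write_tsv(bad, file.path(dir, "notes.tsv"))
  expect_error(read_corpus(dir), "doctime")
  bad <- manifest
  bad$note_id[2] <- bad$note_id[1]
  bad$patient_id[2] <- bad$patient_id[1]
  readr::write_tsv(bad, file.path(dir, "notes.tsv"))
  expect_error(read_corpus(dir), "duplicate")
  readr::write_tsv(manifest, file.path(dir, "notes.tsv"))
  file.remove(file.path(dir, manifest$path[3]))
  expect_error(read_corpus(dir), "missing note file")
})

test_that("an empty manifest loads as an empty corpus", {
  dir <- withr::local_tempdir()
  readr::write_tsv(tibble::tibble(patient_id = character(),
                                  note_id = character(),
                                  doctime = character(),
                                  path = character()),
                   file.path(dir, "notes.tsv"))
  got <- read_corpus(dir)
  expect_equal(nrow(got), 0)
})

test_that("annotations round-trip and enforce their contracts", {
  dir <- withr::local_tempdir()
  notes <- write_tiny_corpus(dir)
  mentions <- tibble::tibble(
    note_id = c("n1", "n1"), mention_id = c("e1", "t1"),
    mention_type = c("EVENT", "TIMEX3"),
    start = c(8L, 23L), end = c(19L, 33L),
    surface = c("carboplatin", "2013-04-10")
  )
  tlinks <- tibble::tibble(note_id = "n1", event_id = "e1",
                           timex_id = "t1", label = "BEGINS-ON")
  path <- file.path(dir, "ann.json")
  write_annotations(list(mentions = mentions, tlinks = tlinks), path)
  got <- read_annotations(path, notes)
  expect_equal(as.data.frame(got$mentions), as.data.frame(mentions))
  expect_equal(as.data.frame(got$tlinks), as.data.frame(tlinks))
  # surface always equals the text slice
  expect_equal(got$mentions$surface,
               substring(notes$text[1], got$mentions$start + 1,
                         got$mentions$end))

  bad <- tlinks; bad$label <- "AFTER"
  write_annotations(list(mentions = mentions, tlinks = bad), path)
  expect_error(read_annotations(path, notes), "label")

  bad <- tlinks; bad$timex_id <- "t999"
  write_annotations(list(mentions = mentions, tlinks = bad), path)
  expect_error(read_annotations(path, notes), "unknown mention id")

  bad_m <- mentions; bad_m$end[1] <- 2000L
  write_annotations(list(mentions = bad_m, tlinks = tlinks[0, ]), path)
  expect_error(read_annotations(path, notes), "out-of-bounds")
})

test_that("the canonical 11-entry timeline round-trips unchanged", {
  dates <- c("2013-07-18", "2013-08-08", "2013-08-29", "2013-09-19",
             "2013-10-24")
  tl <- dplyr::bind_rows(
    tibble::tibble(patient_id = "p1", event = "chemotherapy",
                   relation = "contains-1", date = "2013-06-20"),
    tidyr::expand_grid(event = c("carboplatin", "taxol"), date = dates) |>
      dplyr::mutate(patient_id = "p1", relation = "contains-1")
  ) |> dplyr::select(patient_id, event, relation, date)
  expect_equal(nrow(tl), 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_timelines(tl, path)
  got <- read_timelines(path)
  expect_equal(as.data.frame(got), as.data.frame(tl), ignore_attr = TRUE)
})

test_that("patients with empty timelines survive the round trip", {
  tl <- tibble::tibble(patient_id = "p1", event = "taxol",
                       relation = "ends-on", date = "2013-10-24")
  path <- withr::local_tempfile(fileext = ".json")
  write_timelines(tl, path, patients = c("p1", "p2"))
  got <- read_timelines(path)
  expect_setequal(attr(got, "patients"), c("p1", "p2"))
  expect_equal(nrow(got), 1)
})

test_that("timeline files reject unsummarized labels and bad dates", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"p1": [["taxol", "contains", "2013-10-24"]]}', path)
  expect_error(read_timelines(path), "contains")
  writeLines('{"p1": [["taxol", "contains-1", "2013-13-24"]]}', path)
  expect_error(read_timelines(path), "valid normalized date")
  writeLines('{"p1": [["Taxol", "contains-1", "2013-10-24"]]}', path)
  expect_error(read_timelines(path), "lowercase")
})
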