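test_that("bundled corpus reproduces the published incidence counts", {
  dav <- davinci_corpus()
  expect_equal(unname(colSums(dav[theme_ids(dav, "utility")])),
               c(16, 7, 12, 2, 5, 5, 3))
  expect_equal(unname(colSums(dav[theme_ids(dav, "issue")])),
               c(16, 9, 4, 1, 12, 6, 2, 6, 6))
  cells <- dav[theme_ids(dav)]
  expect_equal(nrow(dav) * length(theme_ids(dav)), 304)
  expect_equal(sum(cells), 50 + 62)  # sums of the two printed count rows
  win <- corpus_window(dav)
  expect_equal(win$anchor_date, as.Date("2000-07-12"))
  expect_equal(win$end_date, as.Date("2004-10-24"))
  expect_true(all(dav$resolved_date >= win$anchor_date &
                    dav$resolved_date <= win$end_date))
})

test_that("wide and long CSV round-trips preserve every cell", {
  dav <- davinci_corpus()
  for (dialect in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_presence_matrix(dav, path, dialect)
    back <- read_presence_matrix(path, dialect, codebook = codebook(dav))
    expect_identical(
      as.matrix(back[theme_ids(back)]),
      as.matrix(dav[theme_ids(dav)]),
      info = dialect)
  }
})

test_that("wide and long readers handle degenerate inputs", {
  # all-absent wide file
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(article_id = 1:2,
                                  study_label = c("a1", "a2"),
                                  pub_year_month = c("2001/01", "2001/02"),
                                  T1 = 0L, T2 = 0L, T3 = 0L), path)
  m <- read_presence_matrix(path, "wide")
  expect_equal(unname(colSums(m[theme_ids(m)])), c(0, 0, 0))

  # long file listing only present pairs, completed against a 2x2 codebook
  cb <- tibble::tibble(theme_id = c("T1-1", "T1-2"),
                       label = c("t1", "t2"),
                       category = c("utility", "utility"))
  readr::write_csv(tibble::tibble(article_id = 1:2,
                                  theme_id = c("T1-1", "T1-1"),
                                  present = c(1L, 0L)), path)
  m <- read_presence_matrix(path, "long", codebook = cb)
  expect_equal(sum(as.matrix(m[theme_ids(m)])), 1)
  expect_equal(dim(m[theme_ids(m)]), c(2L, 2L))
})

test_that("malformed inputs are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(article_id = 1, study_label = "a",
                                  pub_year_month = "2001/01", T1 = 2), path)
  expect_error(read_presence_matrix(path, "wide"), "0 or 1")

  readr::write_csv(tibble::tibble(article_id = c(1, 1),
                                  theme_id = c("T1", "T1"),
                                  present = c(1, 0)), path)
  expect_error(read_presence_matrix(path, "long"), "Duplicate")

  readr::write_csv(tibble::tibble(article_id = 1, study_label = "a",
                                  pub_year_month = "May 2001", T1 = 1), path)
  expect_error(read_presence_matrix(path, "wide"), "Unparseable")

  # wide theme column not covered by the supplied codebook
  cb <- tibble::tibble(theme_id = "T1", label = "t", category = "utility")
  readr::write_csv(tibble::tibble(article_id = 1, study_label = "a",
                                  pub_year_month = "2001/05",
                                  T1 = 1, T9 = 0), path)
  expect_error(read_presence_matrix(path, "wide", codebook = cb),
               "not in codebook")
})

test_that("day-of-month conventions resolve as defined", {
  m <- make_pm(matrix(c(1L, 1L), ncol = 1),
               months = c("2001/05", "2004/09"), day = NULL)
  expect_equal(resolve_dates(m, "mid")$resolved_date,
               as.Date(c("2001-05-15", "2004-09-15")))
  expect_equal(resolve_dates(m, "first")$resolved_date,
               as.Date(c("2001-05-01", "2004-09-01")))
  expect_equal(resolve_dates(m, "last")$resolved_date,
               as.Date(c("2001-05-31", "2004-09-30")))
  for (day in c("first", "mid", "last")) {
    dav <- davinci_corpus(day)
    win <- corpus_window(dav)
    expect_true(all(dav$resolved_date >= win$anchor_date &
                      dav$resolved_date <= win$end_date), info = day)
  }
})

test_that("elapsed months use fixed 30.4375-day months from the anchor", {
  win <- study_window("2000-07-12", "2004-10-24")
  expect_equal(elapsed_months(win$anchor_date, win), 0)
  expect_equal(elapsed_months(as.Date("2001-05-15"), win), 307 / 30.4375)
  expect_equal(elapsed_months(as.Date("2004-09-15"), win), 1526 / 30.4375)
  dates <- sort(win$anchor_date + sample.int(1500, 30))
  expect_true(all(diff(elapsed_months(dates, win)) > 0))
  expect_error(elapsed_months(as.Date("2000-01-01"), win), "before")
})
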