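#' Observation window of a literature corpus
#'
#' The window bounds the early-adoption corpus: it runs from an anchor date
#' (for the bundled corpus, the day after the device's regulatory clearance)
#' to an end date (the day before the first randomized trial was published).
#' All article publication dates must fall inside it, and elapsed time is
#' measured from the anchor.
#'
#' @param anchor_date,end_date `Date` scalars (or strings coercible with
#'   [as.Date()]); `anchor_date` must precede `end_date`.
#' @return An object of class `study_window`: a list with elements
#'   `anchor_date` and `end_date`.
#' @examples
#' study_window("2000-07-12", "2004-10-24")
#' @export
study_window <- function(anchor_date, end_date) {
  anchor_date <- as.Date(anchor_date)
  end_date <- as.Date(end_date)
  if (length(anchor_date) != 1L || length(end_date) != 1L ||
      is.na(anchor_date) || is.na(end_date)) {
    abort("`anchor_date` and `end_date` must be single non-missing dates.")
  }
  if (!(anchor_date < end_date)) {
    abort("`anchor_date` must be strictly before `end_date`.")
  }
  structure(list(anchor_date = anchor_date, end_date = end_date),
            class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat("<study_window> ", format(x$anchor_date), " -- ", format(x$end_date),
      " (", round(elapsed_months(x$end_date, x), 1), " months)\n", sep = "")
  invisible(x)
}

# metadata columns preceding the theme columns in the wide layout
pm_meta_cols <- c("article_id", "study_label", "pub_year_month", "resolved_date")

#' Theme columns of a presence matrix
#'
#' @param x A `presence_matrix`.
#' @param category `"all"`, `"utility"` or `"issue"`; categories other than
#'   `"all"` require a codebook with category information.
#' @return Character vector of theme ids (column names).
#' @export
theme_ids <- function(x, category = c("all", "utility", "issue")) {
  category <- match.arg(category)
  cb <- codebook(x)
  if (category == "all") {
    return(cb$theme_id)
  }
  if (all(is.na(cb$category))) {
    abort("This presence matrix has no theme categories; supply a codebook.")
  }
  cb$theme_id[!is.na(cb$category) & cb$category == category]
}

#' Codebook of a presence matrix
#'
#' @param x A `presence_matrix`.
#' @return A tibble with columns `theme_id`, `label`, `category`.
#' @export
codebook <- function(x) {
  attr(x, "codebook")
}

#' Observation window attached to a presence matrix
#'
#' @param x A `presence_matrix`.
#' @return A [study_window()] or `NULL` if none is attached.
#' @export
corpus_window <- function(x) {
  attr(x, "window")
}

new_presence_matrix <- function(df, codebook, window = NULL) {
  structure(df,
            codebook = codebook,
            window = window,
            class = c("presence_matrix", class(tibble::tibble())))
}

validate_presence_matrix <- function(x) {
  cb <- codebook(x)
  missing_meta <- setdiff(pm_meta_cols, names(x))
  if (length(missing_meta) > 0) {
    abort(paste0("Missing metadata column(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  if (anyDuplicated(cb$theme_id)) {
    abort("Duplicated theme_id in codebook.")
  }
  if (!all(cb$theme_id %in% names(x))) {
    abort("Codebook lists themes absent from the matrix columns.")
  }
  if (anyDuplicated(x$article_id)) {
    abort("Duplicated article_id.")
  }
  cells <- as.matrix(x[cb$theme_id])
  if (!is.numeric(cells) || anyNA(cells) || !all(cells %in% c(0, 1))) {
    abort("Presence cells must all be 0 or 1.")
  }
  win <- corpus_window(x)
  if (!is.null(win) && any(!is.na(x$resolved_date))) {
    d <- x$resolved_date[!is.na(x$resolved_date)]
    if (any(d < win$anchor_date | d > win$end_date)) {
      abort("Resolved article dates fall outside the observation window.")
    }
  }
  invisible(x)
}

#' Build a presence matrix from a wide data frame
#'
#' A presence matrix is the fundamental data object of the analysis: a binary
#' article-by-theme incidence table. The wide layout has one row per article,
#' metadata columns `article_id`, `study_label`, `pub_year_month` (format
#' `YYYY/MM`), and one 0/1 column per theme.
#'
#' @param df Data frame in the wide layout. A `resolved_date` column is
#'   optional; if absent it is initialised to `NA` (see [resolve_dates()]).
#' @param codebook Optional tibble (or list) with columns `theme_id`, `label`,
#'   `category` (`"utility"` or `"issue"`). If `NULL`, every non-metadata
#'   column is taken to be a theme with unknown category. If supplied, theme
#'   columns not listed in the codebook are an error, and codebook themes
#'   missing from `df` are added as all-absent columns.
#' @param window Optional [study_window()].
#' @return A `presence_matrix` (a tibble subclass carrying the codebook and
#'   window as attributes).
#' @export
as_presence_matrix <- function(df, codebook = NULL, window = NULL) {
  df <- tibble::as_tibble(df)
  if (!"resolved_date" %in% names(df)) {
    df$resolved_date <- as.Date(NA)
  }
  if (!"study_label" %in% names(df)) df$study_label <- NA_character_
  if (!"pub_year_month" %in% names(df)) df$pub_year_month <- NA_character_
  theme_cols <- setdiff(names(df), pm_meta_cols)
  if (is.null(codebook)) {
    codebook <- tibble::tibble(theme_id = theme_cols,
                               label = theme_cols,
                               category = NA_character_)
  } else {
    codebook <- tibble::as_tibble(codebook)
    unknown <- setdiff(theme_cols, codebook$theme_id)
    if (length(unknown) > 0) {
      abort(paste0("Theme column(s) not in codebook: ",
                   paste(unknown, collapse = ", ")))
    }
    for (th in setdiff(codebook$theme_id, theme_cols)) {
      df[[th]] <- 0L
    }
  }
  df <- df[c(pm_meta_cols, codebook$theme_id)]
  df$article_id <- as.integer(df$article_id)
  for (th in codebook$theme_id) df[[th]] <- as.integer(df[[th]])
  x <- new_presence_matrix(df, codebook, window)
  validate_presence_matrix(x)
  x
}

#' @export
print.presence_matrix <- function(x, ...) {
  cb <- codebook(x)
  n_cat <- table(factor(cb$category, levels = c("utility", "issue")))
  cat("<presence_matrix> ", nrow(x), " articles x ", nrow(cb), " themes (",
      n_cat[["utility"]], " utilities, ", n_cat[["issue"]], " issues); ",
      sum(as.matrix(x[cb$theme_id])), " present cells\n", sep = "")
  win <- corpus_window(x)
  if (!is.null(win)) {
    cat("window: ", format(win$anchor_date), " -- ",
        format(win$end_date), "\n", sep = "")
  }
  NextMethod()
}

# extract the article x theme 0/1 integer matrix
presence_cells <- function(x, category = "all") {
  ids <- theme_ids(x, category)
  m <- as.matrix(x[ids])
  rownames(m) <- x$article_id
  storage.mode(m) <- "integer"
  m
}

#' The da Vinci early-adoption corpus
#'
#' The bundled dataset: 19 peer-reviewed clinical studies of the da Vinci
#' surgical system published between May 2001 and September 2004 (between the
#' system's FDA clearance and the first randomized trial), coded for 16
#' descriptive themes — 7 device utilities (T1-1 .. T3-3) and 9 operational
#' issues (T4-1 .. T6-1). A cell is 1 when the study addresses the theme.
#' The observation window runs 2000-07-12 to 2004-10-24.
#'
#' Publication dates are printed at month resolution in the source tables;
#' the day of month is resolved by convention (default: mid-month).
#'
#' @param day Day-of-month convention passed to [resolve_dates()];
#'   `"none"` leaves dates unresolved.
#' @return A `presence_matrix` with codebook and [study_window()] attached.
#' @examples
#' dav <- davinci_corpus()
#' colSums(dav[theme_ids(dav, "utility")])
#' @export
davinci_corpus <- function(day = c("mid", "first", "last", "none")) {
  day <- match.arg(day)
  labels <- c("Mohr2001", "Rassweiler2001", "Pasticier2001", "Ruurda2002",
              "Horgan2002", "Melfi2002", "Gutt2002", "Gettman2002",
              "Ruurda2003", "Giulianotti2003", "Bentas2003", "Talamini2003",
              "Muhlmann2003", "Munz2004", "Desgranges2004", "Bodner2004-1",
              "Bodner2004-2", "Newlin2004", "Ayav2004")
  months <- c("2001/05", "2001/07", "2001/07", "2002/02", "2002/02",
              "2002/05", "2002/07", "2002/09", "2003/02", "2003/07",
              "2003/08", "2003/08", "2003/12", "2004/01", "2004/05",
              "2004/05", "2004/07", "2004/07", "2004/09")
  # article indices (table row order) addressing each theme
  present <- list(
    `T1-1` = c(1, 3:13, 16:19),
    `T1-2` = c(1, 4, 5, 6, 8, 18, 19),
    `T2-1` = c(1, 4, 5, 7, 8, 11, 12, 13, 16, 17, 18, 19),
    `T2-2` = c(7, 18),
    `T3-1` = c(1, 4, 7, 11, 15),
    `T3-2` = c(3, 12, 13, 15, 19),
    `T3-3` = c(1, 6, 7),
    `T4-1` = c(1, 2, 3, 4, 6, 7, 8, 10, 11, 12, 13, 15, 16, 17, 18, 19),
    `T4-2` = c(3, 4, 6, 8, 9, 10, 11, 13, 16),
    `T4-3` = c(4, 11, 12, 19),
    `T4-4` = 1,
    `T5-1` = c(6, 7, 9, 10, 12, 13, 14, 15, 16, 17, 18, 19),
    `T5-2` = c(1, 4, 8, 10, 15, 19),
    `T5-3` = c(15, 17),
    `T5-4` = c(8, 12, 14, 16, 17, 19),
    `T6-1` = c(2, 7, 8, 13, 15, 19))
  df <- tibble::tibble(article_id = 1:19,
                       study_label = labels,
                       pub_year_month = months)
  for (th in names(present)) {
    df[[th]] <- as.integer(seq_len(19) %in% present[[th]])
  }
  x <- as_presence_matrix(df, codebook = davinci_codebook(),
                          window = study_window("2000-07-12", "2004-10-24"))
  if (day != "none") x <- resolve_dates(x, day)
  x
}

#' Codebook of the da Vinci corpus
#'
#' @return A tibble with columns `theme_id`, `label`, `category` for the 16
#'   themes of [davinci_corpus()].
#' @export
davinci_codebook <- function() {
  tibble::tribble(
    ~theme_id, ~label, ~category,
    "T1-1", "Dexterity: tasks enabled by instrument dexterity", "utility",
    "T1-2", "Precision: motion scaling and tremor filtering", "utility",
    "T2-1", "Depth perception with stereoscopic vision", "utility",
    "T2-2", "Surgeon-controlled viewpoint", "utility",
    "T3-1", "Improved hand-eye coordination", "utility",
    "T3-2", "Reduced physical strain; neutral posture", "utility",
    "T3-3", "Indexing function", "utility",
    "T4-1", "Loss of haptic feedback", "issue",
    "T4-2", "Instrument limitations", "issue",
    "T4-3", "Device failures", "issue",
    "T4-4", "Control stability", "issue",
    "T5-1", "Cumbersome setup pre- and intraoperatively", "issue",
    "T5-2", "Collisions with bulky arms", "issue",
    "T5-3", "Disrupted coordination with assistants", "issue",
    "T5-4", "Other workflow constraints", "issue",
    "T6-1", "High costs", "issue")
}

#' Read a presence matrix from CSV
#'
#' Two dialects are supported. *Wide*: one row per article with columns
#' `article_id,study_label,pub_year_month,<theme>,...` and 0/1 cells.
#' *Long*: `(article_id, theme_id, present)` triples; pairs absent from the
#' file default to absent, so a file may list only the present pairs.
#'
#' @param path Path to a CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @param codebook Optional codebook (see [as_presence_matrix()]); required to
#'   recover all-absent themes from a long file, and used to reject unknown
#'   theme columns in a wide file.
#' @param window Optional [study_window()] to attach.
#' @return A `presence_matrix`.
#' @export
read_presence_matrix <- function(path, dialect = c("wide", "long"),
                                 codebook = NULL, window = NULL) {
  dialect <- match.arg(dialect)
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (dialect == "wide") {
    if ("pub_year_month" %in% names(df)) {
      df$pub_year_month <- as.character(df$pub_year_month)
      bad <- !is.na(df$pub_year_month) &
        !grepl("^[0-9]{4}/[0-9]{2}$", df$pub_year_month)
      if (any(bad)) {
        abort(paste0("Unparseable pub_year_month (expected YYYY/MM): ",
                     paste(unique(df$pub_year_month[bad]), collapse = ", ")))
      }
    }
    return(as_presence_matrix(df, codebook = codebook, window = window))
  }
  need <- c("article_id", "theme_id", "present")
  if (!all(need %in% names(df))) {
    abort("Long dialect requires columns article_id, theme_id, present.")
  }
  if (anyDuplicated(df[c("article_id", "theme_id")])) {
    abort("Duplicate (article_id, theme_id) pair in long input.")
  }
  if (!all(df$present %in% c(0, 1))) {
    abort("Presence cells must all be 0 or 1.")
  }
  wide <- tidyr::pivot_wider(df, names_from = "theme_id",
                             values_from = "present", values_fill = 0L)
  wide <- wide[order(wide$article_id), ]
  as_presence_matrix(wide, codebook = codebook, window = window)
}

#' Write a presence matrix to CSV
#'
#' @param x A `presence_matrix`.
#' @param path Output path.
#' @param dialect `"wide"` writes the canonical wide layout
#'   (`article_id,study_label,pub_year_month,<theme>,...`); `"long"` writes
#'   every `(article_id, theme_id, present)` triple.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  cb <- codebook(x)
  if (dialect == "wide") {
    out <- tibble::as_tibble(x)[c("article_id", "study_label",
                                  "pub_year_month", cb$theme_id)]
  } else {
    out <- tidyr::pivot_longer(
      tibble::as_tibble(x)[c("article_id", cb$theme_id)],
      cols = dplyr::all_of(cb$theme_id),
      names_to = "theme_id", values_to = "present")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a codebook from JSON
#'
#' Expects a JSON array of objects with fields `theme_id`, `label`,
#' `category`.
#'
#' @param path Path to a JSON file.
#' @return A codebook tibble.
#' @export
read_codebook <- function(path) {
  cb <- tibble::as_tibble(jsonlite::fromJSON(path))
  need <- c("theme_id", "label", "category")
  if (!all(need %in% names(cb))) {
    abort("Codebook JSON must provide theme_id, label and category.")
  }
  cb[need]
}

#' Resolve month-resolution publication dates to calendar dates
#'
#' Source tables print publication dates at month resolution; a day-of-month
#' convention turns them into calendar dates for the elapsed-time axis.
#' `"mid"` (day 15) is the default: it places each article at the unbiased
#' centre of its month. Article order is never changed, so same-date articles
#' keep their table row order.
#'
#' @param x A `presence_matrix` with `pub_year_month` populated.
#' @param day `"first"` (day 1), `"mid"` (day 15) or `"last"` (last day of
#'   the month).
#' @return `x` with `resolved_date` set. Errors if a resolved date falls
#'   outside an attached observation window.
#' @export
resolve_dates <- function(x, day = c("mid", "first", "last")) {
  day <- match.arg(day)
  ym <- x$pub_year_month
  if (anyNA(ym) || !all(grepl("^[0-9]{4}/[0-9]{2}$", ym))) {
    abort("pub_year_month must be populated as YYYY/MM before resolving.")
  }
  first <- as.Date(paste0(sub("/", "-", ym), "-01"))
  x$resolved_date <- switch(day,
    first = first,
    mid = first + 14,
    # day 1 of next month, minus one day
    last = as.Date(vapply(first, function(d) {
      as.character(seq(d, by = "1 month", length.out = 2)[2] - 1)
    }, character(1))))
  validate_presence_matrix(x)
  x
}

#' Months elapsed since the window anchor
#'
#' Elapsed time is measured in fixed-length months of 365.25/12 = 30.4375
#' days, so the axis is calendar-independent and exactly reproducible.
#'
#' @param date `Date` vector (each on or after the anchor).
#' @param window A [study_window()].
#' @return Numeric vector of elapsed months (0 at the anchor).
#' @examples
#' elapsed_months(as.Date("2001-05-15"), study_window("2000-07-12", "2004-10-24"))
#' @export
elapsed_months <- function(date, window) {
  stopifnot(inherits(window, "study_window"))
  days <- as.numeric(date) - as.numeric(window$anchor_date)
  if (any(days < 0)) {
    abort("Dates before the window anchor have no elapsed time.")
  }
  days / 30.4375
}
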