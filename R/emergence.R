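#' First occurrence of each theme
#'
#' Under the first-occurrence rule a theme contributes to the cumulative
#' count only at the earliest article mentioning it (date order, ties broken
#' by table row order). Themes never present anywhere are omitted.
#'
#' @param x A `presence_matrix` with resolved dates.
#' @param category `"all"`, `"utility"` or `"issue"`.
#' @return A tibble with columns `theme_id`, `article_id`, `study_label`,
#'   `date`, ordered by first-occurrence date.
#' @examples
#' first_occurrences(davinci_corpus(), "utility")
#' @export
first_occurrences <- function(x, category = c("all", "utility", "issue")) {
  category <- match.arg(category)
  if (anyNA(x$resolved_date)) {
    abort("Dates must be resolved first; see resolve_dates().")
  }
  ord <- order(x$resolved_date)  # stable: ties keep row order
  ids <- theme_ids(x, category)
  cells <- presence_cells(x, category)[ord, , drop = FALSE]
  rows <- lapply(ids, function(th) {
    hit <- which(cells[, th] == 1L)
    if (length(hit) == 0) return(NULL)
    i <- ord[hit[1]]
    tibble::tibble(theme_id = th, article_id = x$article_id[i],
                   study_label = x$study_label[i], date = x$resolved_date[i])
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$date), ]
}

#' Cumulative theme-emergence series
#'
#' Walks the articles in publication order and records, at each article, the
#' number of newly appearing themes, the cumulative number of themes observed
#' so far, and the cumulative occurrence proportion — 100 x (themes observed
#' up to article n) / (themes observed by the final article). Articles that
#' contribute no new theme are retained as flat segments: each publication is
#' an observation on both explanatory axes.
#'
#' By default the series is anchored at the origin — a row with elapsed time
#' 0, publication count 0 and proportion 0 at the window anchor — reflecting
#' that no theme had been published when the observation window opened. Set
#' `include_origin = FALSE` to keep only the article points.
#'
#' @param x A `presence_matrix` with resolved dates.
#' @param category `"all"`, `"utility"` or `"issue"`.
#' @param window A [study_window()]; defaults to the one attached to `x`.
#' @param include_origin Add the (0, 0) anchor row (default `TRUE`).
#' @return An `emergence_series`: a tibble with columns `article_id`,
#'   `study_label`, `date`, `t_months`, `pub_count`, `t_new`, `t_sum`,
#'   `proportion` (percent), carrying `category` and `t_sum_end` as
#'   attributes. The origin row has `article_id` `NA` and `t_new` 0.
#' @examples
#' emergence_series(davinci_corpus(), "utility")
#' @export
emergence_series <- function(x, category = c("all", "utility", "issue"),
                             window = corpus_window(x),
                             include_origin = TRUE) {
  category <- match.arg(category)
  if (anyNA(x$resolved_date)) {
    abort("Dates must be resolved first; see resolve_dates().")
  }
  if (is.null(window)) {
    abort("An observation window is required (attach one or pass `window`).")
  }
  ids <- theme_ids(x, category)
  cells <- presence_cells(x, category)
  if (length(ids) == 0 || sum(cells) == 0) {
    abort(paste0("No observed theme in category '", category, "'."))
  }
  ord <- order(x$resolved_date)
  cells <- cells[ord, , drop = FALSE]
  seen <- rep(FALSE, length(ids))
  t_new <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    new <- cells[i, ] == 1L & !seen
    t_new[i] <- sum(new)
    seen <- seen | new
  }
  t_sum <- cumsum(t_new)
  t_sum_end <- t_sum[length(t_sum)]
  out <- tibble::tibble(
    article_id = x$article_id[ord],
    study_label = x$study_label[ord],
    date = x$resolved_date[ord],
    t_months = elapsed_months(x$resolved_date[ord], window),
    pub_count = seq_along(ord),
    t_new = t_new,
    t_sum = t_sum,
    proportion = 100 * t_sum / t_sum_end)
  if (include_origin) {
    origin <- tibble::tibble(article_id = NA_integer_,
                             study_label = NA_character_,
                             date = window$anchor_date, t_months = 0,
                             pub_count = 0L, t_new = 0L, t_sum = 0L,
                             proportion = 0)
    out <- dplyr::bind_rows(origin, out)
  }
  structure(out, category = category, t_sum_end = t_sum_end,
            class = c("emergence_series", class(out)))
}

#' Extract (x, y) points from an emergence series
#'
#' @param series An [emergence_series()].
#' @param axis Explanatory axis: `"months"` (elapsed months since the window
#'   anchor) or `"publications"` (cumulative article count).
#' @return A tibble with columns `x` and `y` (cumulative occurrence
#'   proportion, percent).
#' @export
series_points <- function(series, axis = c("months", "publications")) {
  axis <- match.arg(axis)
  tibble::tibble(
    x = if (axis == "months") series$t_months else as.numeric(series$pub_count),
    y = series$proportion)
}

#' @export
print.emergence_series <- function(x, ...) {
  cat("<emergence_series> category = ", attr(x, "category"),
      ", ", attr(x, "t_sum_end"), " themes, ",
      sum(!is.na(x$article_id)), " articles",
      if (any(is.na(x$article_id))) " (+ origin anchor)", "\n", sep = "")
  NextMethod()
}

#' Per-theme cumulative mention counts
#'
#' For each theme, the running count of articles mentioning it at each
#' publication date — the per-theme accumulation picture that complements
#' the category-level emergence series.
#'
#' @inheritParams emergence_series
#' @return A tibble with columns `theme_id`, `label`, `category`, `date`,
#'   `t_months`, `pub_count`, `n_mentions`.
#' @export
theme_accumulation <- function(x, category = c("all", "utility", "issue"),
                               window = corpus_window(x)) {
  category <- match.arg(category)
  if (anyNA(x$resolved_date)) {
    abort("Dates must be resolved first; see resolve_dates().")
  }
  ids <- theme_ids(x, category)
  ord <- order(x$resolved_date)
  cells <- presence_cells(x, category)[ord, , drop = FALSE]
  cb <- codebook(x)
  purrr::map_dfr(ids, function(th) {
    tibble::tibble(
      theme_id = th,
      label = cb$label[cb$theme_id == th],
      category = cb$category[cb$theme_id == th],
      date = x$resolved_date[ord],
      t_months = elapsed_months(x$resolved_date[ord], window),
      pub_count = seq_along(ord),
      n_mentions = cumsum(cells[, th]))
  })
}
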