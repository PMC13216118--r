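#' Plot an emergence series
#'
#' @param object An [emergence_series()].
#' @param axis `"months"` or `"publications"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emergence_series <- function(object,
                                      axis = c("months", "publications"),
                                      ...) {
  axis <- match.arg(axis)
  pts <- series_points(object, axis)
  xlab <- if (axis == "months") "Months since window anchor" else
    "Cumulative publications"
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "Cumulative occurrence proportion (%)",
                  title = paste0("Theme emergence (",
                                 attr(object, "category"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot per-theme cumulative mention counts
#'
#' One line per theme: the running number of articles mentioning it, over
#' elapsed months.
#'
#' @inheritParams theme_accumulation
#' @return A ggplot object.
#' @export
plot_theme_accumulation <- function(x,
                                    category = c("all", "utility", "issue"),
                                    window = corpus_window(x)) {
  category <- match.arg(category)
  acc <- theme_accumulation(x, category, window)
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$t_months,
                                    y = .data$n_mentions,
                                    colour = .data$theme_id)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Months since window anchor",
                  y = "Cumulative mentions (articles)",
                  colour = "Theme",
                  title = paste0("Per-theme accumulation (", category, ")")) +
    ggplot2::theme_minimal()
}

# one panel: observed points and selected fitted curves for both categories
fit_panel <- function(fits, axis) {
  curves <- purrr::imap_dfr(fits, function(f, nm) {
    g <- seq(0, max(f$data$x), length.out = 200)
    tibble::tibble(category = sub("_[^_]*$", "", nm), x = g,
                   y = model_eval(f, g))
  })
  pts <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(f$data, category = sub("_[^_]*$", "", nm))
  })
  xlab <- if (axis == "months") "Months since window anchor" else
    "Cumulative publications"
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts, ggplot2::aes(shape = .data$category)) +
    ggplot2::labs(x = xlab, y = "Cumulative occurrence proportion (%)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Run the full saturation analysis on a corpus
#'
#' The end-to-end pipeline: per category (utilities and issues) and per
#' explanatory axis, build the cumulative emergence series, fit and compare
#' the candidate saturation models, and tabulate the times (or publication
#' counts) to reach the target proportions from the selected model. Optional
#' `outdir` writes the series, the fit summaries, the threshold table and
#' the report plots to disk.
#'
#' @param corpus A `presence_matrix` with resolved dates and window; default
#'   the bundled da Vinci corpus.
#' @param categories Theme categories to analyse.
#' @param axes Explanatory axes.
#' @param kinds Candidate model kinds for [compare_models()].
#' @param targets Target proportions for [threshold_table()].
#' @param ci_method CI method for thresholds.
#' @param include_origin Anchor series at (0, 0); see [emergence_series()].
#' @param outdir Optional output directory (created if needed). Writes
#'   `series_<category>.csv`, `fits.json`, `comparison.json`,
#'   `thresholds.csv`, and PDF plots.
#' @return A list with `series` (per category), `comparisons` (per
#'   category x axis), `fits` (selected fit per cell), `thresholds`
#'   (tibble with `category` and `axis` columns) and `plots`.
#' @examples
#' rep <- fit_report(davinci_corpus(), targets = c(50, 80, 99.9))
#' rep$thresholds
#' @export
fit_report <- function(corpus = davinci_corpus(),
                       categories = c("utility", "issue"),
                       axes = c("months", "publications"),
                       kinds = c("exponential", "logistic"),
                       targets = c(50, 80, 99.9),
                       ci_method = "transform",
                       include_origin = TRUE,
                       outdir = NULL) {
  if (nrow(corpus) == 0 || sum(presence_cells(corpus)) == 0) {
    abort("Empty corpus: no present cells to analyse.")
  }
  series <- setNames(lapply(categories, function(ct) {
    emergence_series(corpus, ct, include_origin = include_origin)
  }), categories)
  comparisons <- list()
  fits <- list()
  for (ct in categories) {
    for (ax in axes) {
      cell <- paste(ct, ax, sep = "_")
      cmp <- compare_models(series_points(series[[ct]], ax), kinds)
      for (k in names(cmp$fits)) cmp$fits[[k]]$axis <- ax
      comparisons[[cell]] <- cmp
      fits[[cell]] <- cmp$fits[[cmp$selected]]
    }
  }
  thresholds <- threshold_table(fits, targets, method = ci_method)
  if (nrow(thresholds) > 0) {
    parts <- strsplit(thresholds$fit, "_")
    thresholds$category <- vapply(parts, `[`, "", 1)
    thresholds$axis <- vapply(parts, `[`, "", 2)
    thresholds <- thresholds[c("category", "axis", "target_pct", "estimate",
                               "ci_low", "ci_high", "method")]
  }
  plots <- list()
  for (ax in axes) {
    plots[[paste0("fit_", ax)]] <-
      fit_panel(fits[paste(categories, ax, sep = "_")], ax) +
      ggplot2::labs(title = paste0("Saturation fits (", ax, " axis)"))
  }
  for (ct in intersect(categories, c("utility", "issue"))) {
    plots[[paste0("themes_", ct)]] <- plot_theme_accumulation(corpus, ct)
  }
  out <- list(series = series, comparisons = comparisons, fits = fits,
              thresholds = thresholds, plots = plots)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (ct in categories) {
      readr::write_csv(tibble::as_tibble(series[[ct]]),
                       file.path(outdir, paste0("series_", ct, ".csv")),
                       progress = FALSE)
    }
    jsonlite::write_json(
      lapply(fits, function(f) c(as.list(glance(f)),
                                 list(params = tidy(f)))),
      file.path(outdir, "fits.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    jsonlite::write_json(
      lapply(comparisons, function(cm) list(selected = cm$selected,
                                            table = cm$table)),
      file.path(outdir, "comparison.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    readr::write_csv(thresholds, file.path(outdir, "thresholds.csv"),
                     progress = FALSE)
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(outdir, paste0(nm, ".pdf")), plots[[nm]],
                      width = 7, height = 5, device = "pdf")
    }
  }
  out
}

#' Inter-rater agreement report
#'
#' Computes the matrix-level agreement statistics for two coders and
#' optionally writes them as JSON.
#'
#' @inheritParams agreement_rate
#' @param path Optional JSON output path.
#' @return The [cohens_kappa()] `agreement_result`, invisibly when `path`
#'   is given.
#' @export
agreement_report <- function(coder_a, coder_b, path = NULL) {
  res <- cohens_kappa(coder_a, coder_b)
  if (!is.null(path)) {
    jsonlite::write_json(unclass(res), path, auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
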