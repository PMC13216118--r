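# small presence matrices built in code for unit tests

# wide presence matrix from a 0/1 cell matrix (articles x themes)
make_pm <- function(cells, months = NULL, categories = NULL,
                    window = NULL, day = "mid") {
  n <- nrow(cells)
  if (is.null(months)) {
    months <- format(seq(as.Date("2001-01-01"), by = "1 month",
                         length.out = n), "%Y/%m")
  }
  if (is.null(colnames(cells))) {
    colnames(cells) <- paste0("X", seq_len(ncol(cells)))
  }
  cb <- tibble::tibble(
    theme_id = colnames(cells),
    label = colnames(cells),
    category = categories %||% rep(NA_character_, ncol(cells)))
  df <- tibble::tibble(article_id = seq_len(n),
                       study_label = paste0("study", seq_len(n)),
                       pub_year_month = months)
  for (j in colnames(cells)) df[[j]] <- as.integer(cells[, j])
  x <- evidsat::as_presence_matrix(df, codebook = cb, window = window)
  if (!is.null(day)) x <- evidsat::resolve_dates(x, day)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the documented 6-cell coder pair (2 articles x 3 themes)
coder_pair <- function() {
  a <- matrix(c(1, 1, 0, 1, 0, 1), nrow = 2)
  b <- matrix(c(1, 1, 0, 0, 0, 1), nrow = 2)
  list(a = a, b = b)
}
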