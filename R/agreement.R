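#' Inter-rater agreement rate on pooled presence cells
#'
#' Two coders independently fill the same article-by-theme presence matrix;
#' the agreement rate is the fraction of the pooled cells on which they give
#' the same value.
#'
#' @param coder_a,coder_b Two `presence_matrix` objects (or plain 0/1
#'   matrices) with identical article and theme orderings.
#' @return Proportion of agreeing cells, in \[0, 1\].
#' @export
agreement_rate <- function(coder_a, coder_b) {
  m <- paired_cells(coder_a, coder_b)
  mean(m$a == m$b)
}

paired_cells <- function(coder_a, coder_b) {
  a <- if (inherits(coder_a, "presence_matrix")) presence_cells(coder_a) else
    as.matrix(coder_a)
  b <- if (inherits(coder_b, "presence_matrix")) presence_cells(coder_b) else
    as.matrix(coder_b)
  if (!identical(dim(a), dim(b))) {
    abort("Coder matrices must have identical dimensions.")
  }
  if (!is.null(colnames(a)) && !is.null(colnames(b)) &&
      !identical(colnames(a), colnames(b))) {
    abort("Coder matrices must have identical theme orderings.")
  }
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    abort("Presence cells must all be 0 or 1.")
  }
  list(a = as.vector(a), b = as.vector(b))
}

#' Cohen's kappa for two coders' presence matrices
#'
#' Chance-corrected agreement over the pooled cells of the whole matrix
#' (two raters, two categories): kappa = (p_o - p_e) / (1 - p_e), where p_o
#' is the observed agreement rate and p_e the agreement expected by chance
#' from each coder's marginal present/absent frequencies,
#' p_e = pA(1) pB(1) + pA(0) pB(0).
#'
#' When both marginals are degenerate (p_e = 1) the formula is 0/0 and kappa
#' is reported as undefined (`NA`) rather than silently substituted.
#'
#' The result also carries the two prespecified reliability verdicts used in
#' coding workflows: agreement rate strictly above 90%, and kappa at or
#' above 0.80.
#'
#' @inheritParams agreement_rate
#' @return An `agreement_result`: list with `n_total`, `n_agree`, `p_o`,
#'   `p_e`, `kappa`, `band` (Landis-Koch interpretation), and logical
#'   `pass_rate_threshold`, `pass_kappa_threshold`.
#' @examples
#' a <- matrix(c(1, 1, 0, 1, 0, 1), nrow = 2)
#' b <- matrix(c(1, 1, 0, 0, 0, 1), nrow = 2)
#' cohens_kappa(a, b)
#' @export
cohens_kappa <- function(coder_a, coder_b) {
  m <- paired_cells(coder_a, coder_b)
  n <- length(m$a)
  n_agree <- sum(m$a == m$b)
  p_o <- n_agree / n
  pa1 <- mean(m$a)
  pb1 <- mean(m$b)
  p_e <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  band <- if (is.na(kappa)) "undefined" else interpret_kappa(kappa)
  structure(list(n_total = n, n_agree = n_agree, p_o = p_o, p_e = p_e,
                 kappa = kappa, band = band,
                 pass_rate_threshold = p_o > 0.90,
                 pass_kappa_threshold = !is.na(kappa) && kappa >= 0.80),
            class = "agreement_result")
}

#' Landis-Koch interpretation band for a kappa value
#'
#' Bands follow the conventional scale: below 0 poor; 0 up to 0.21 slight;
#' 0.21 up to 0.41 fair; 0.41 up to 0.61 moderate; 0.61 up to 0.81
#' substantial; 0.81 to 1 almost perfect. Intervals are half-open on the
#' upper end so that every value in \[-1, 1\] belongs to exactly one band
#' while each printed boundary (0.20, 0.21, ...) keeps its conventional
#' membership.
#'
#' @param kappa Numeric vector of kappa values in \[-1, 1\].
#' @return Character vector of band names.
#' @examples
#' interpret_kappa(c(0.85, -0.1, 0.20, 0.21))
#' @export
interpret_kappa <- function(kappa) {
  if (any(is.na(kappa)) || any(kappa < -1 | kappa > 1)) {
    abort("kappa must lie in [-1, 1].")
  }
  bands <- c("poor", "slight", "fair", "moderate", "substantial",
             "almost_perfect")
  idx <- findInterval(kappa, c(0, 0.21, 0.41, 0.61, 0.81)) + 1L
  bands[idx]
}

#' Per-theme Cohen's kappa
#'
#' The matrix-level kappa pools all cells; this helper computes kappa
#' separately within each theme column, which can localise coding
#' disagreement. Themes where a coder's marginal is degenerate yield `NA`.
#'
#' @inheritParams agreement_rate
#' @return A tibble with columns `theme_id`, `n`, `p_o`, `p_e`, `kappa`,
#'   `band`.
#' @export
kappa_by_theme <- function(coder_a, coder_b) {
  stopifnot(inherits(coder_a, "presence_matrix"),
            inherits(coder_b, "presence_matrix"))
  ids <- theme_ids(coder_a)
  if (!identical(ids, theme_ids(coder_b))) {
    abort("Coder matrices must have identical theme orderings.")
  }
  purrr::map_dfr(ids, function(th) {
    r <- cohens_kappa(matrix(coder_a[[th]]), matrix(coder_b[[th]]))
    tibble::tibble(theme_id = th, n = r$n_total, p_o = r$p_o, p_e = r$p_e,
                   kappa = r$kappa, band = r$band)
  })
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result> ", x$n_agree, "/", x$n_total, " cells agree\n",
      sep = "")
  cat(sprintf("  agreement rate p_o = %.4f (threshold > 0.90: %s)\n",
              x$p_o, ifelse(x$pass_rate_threshold, "pass", "FAIL")))
  if (is.na(x$kappa)) {
    cat("  Cohen's kappa undefined (chance agreement p_e = 1)\n")
  } else {
    cat(sprintf("  Cohen's kappa = %.4f [%s] (threshold >= 0.80: %s)\n",
                x$kappa, x$band,
                ifelse(x$pass_kappa_threshold, "pass", "FAIL")))
  }
  invisible(x)
}

#' @rdname cohens_kappa
#' @param x An `agreement_result`.
#' @param ... Unused.
#' @export
tidy.agreement_result <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_agree = x$n_agree, p_o = x$p_o,
                 p_e = x$p_e, kappa = x$kappa, band = x$band,
                 pass_rate_threshold = x$pass_rate_threshold,
                 pass_kappa_threshold = x$pass_kappa_threshold)
}

#' @rdname cohens_kappa
#' @export
glance.agreement_result <- function(x, ...) {
  tidy.agreement_result(x)
}
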