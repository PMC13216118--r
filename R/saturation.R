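#' Saturation models for cumulative theme occurrence
#'
#' Two candidate laws describe how the cumulative occurrence proportion
#' (percent) rises toward its plateau at 100:
#' * exponential plateau: `f(t) = 100 (1 - exp(-t / Tc))`, with time
#'   constant `Tc` (the point where ~63.2% of themes have emerged). It
#'   passes through the origin analytically.
#' * logistic: `f(t) = 100 / (1 + a exp(-b t))`, with shape `a > 0` and
#'   rate `b > 0`; `f(0) = 100 / (1 + a)`.
#'
#' Parameters are in months or publications according to the axis the model
#' was fitted on.
#'
#' @param kind `"exponential"` or `"logistic"`.
#' @param tc Time constant (exponential), > 0.
#' @param a,b Logistic parameters, both > 0.
#' @return A `saturation_model`: list with `kind` and named `params`.
#' @examples
#' m <- saturation_model("exponential", tc = 8.2)
#' model_eval(m, c(0, 8.2))
#' @export
saturation_model <- function(kind = c("exponential", "logistic"),
                             tc = NULL, a = NULL, b = NULL) {
  kind <- match.arg(kind)
  if (kind == "exponential") {
    if (is.null(tc) || !is.finite(tc) || tc <= 0) {
      abort("Exponential model needs a positive time constant `tc`.")
    }
    params <- c(tc = tc)
  } else {
    if (is.null(a) || is.null(b) || !all(is.finite(c(a, b))) ||
        a <= 0 || b <= 0) {
      abort("Logistic model needs positive parameters `a` and `b`.")
    }
    params <- c(a = a, b = b)
  }
  structure(list(kind = kind, params = params), class = "saturation_model")
}

#' @export
print.saturation_model <- function(x, ...) {
  cat("<saturation_model> ", x$kind, ": ",
      paste(names(x$params), signif(x$params, 6), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

sat_fun <- function(kind) {
  switch(kind,
         exponential = function(t, p) 100 * (1 - exp(-t / p[["tc"]])),
         logistic = function(t, p) 100 / (1 + p[["a"]] * exp(-p[["b"]] * t)))
}

#' Evaluate a saturation model
#'
#' @param model A [saturation_model()] (or a `saturation_fit`, whose model is
#'   used).
#' @param t Non-negative axis values (months or publications).
#' @return Cumulative occurrence proportion (percent) at each `t`.
#' @export
model_eval <- function(model, t) {
  if (inherits(model, "saturation_fit")) model <- model$model
  stopifnot(inherits(model, "saturation_model"))
  if (any(t < 0)) abort("`t` must be non-negative.")
  sat_fun(model$kind)(t, model$params)
}

sat_start <- function(kind, x, y) {
  tc0 <- max(x) / 3
  if (kind == "exponential") return(list(tc = tc0))
  y1 <- y[y > 0][1]
  if (is.na(y1)) abort("Cannot initialise a logistic fit on all-zero data.")
  list(a = max(100 / y1 - 1, 0.1), b = 1 / tc0)
}

# goodness-of-fit and selection statistics for an NLS fit.
# aicc uses the Gaussian concentrated likelihood without the 2*pi constant:
# n log(rss/n) + 2k + 2k(k+1)/(n-k-1), with k = p + 1 (error variance
# counted as a parameter). Undefined (NA) when rss = 0 or n <= k + 1.
sat_stats <- function(y, fitted, p) {
  n <- length(y)
  rss <- sum((y - fitted)^2)
  rmse <- sqrt(rss / n)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  r2_adj <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - p - 1)
  k <- p + 1
  # rmse below 1e-8 on a 0-100 scale is numerically a perfect fit; the
  # concentrated log-likelihood degenerates and AICc is reported undefined
  perfect <- rmse < 1e-8
  aicc <- if (perfect || n <= k + 1) NA_real_ else
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  list(n = n, rss = rss, rmse = rmse, r2 = r2, r2_adj = r2_adj,
       aicc = aicc, perfect_fit = perfect)
}

#' Fit a saturation model by nonlinear least squares
#'
#' Minimises the residual sum of squares of the cumulative occurrence
#' proportion against the chosen model with a Levenberg-Marquardt solver
#' ([minpack.lm::nlsLM()]), with positivity bounds on all parameters.
#' Starting values are deterministic: `tc0 = max(x)/3` for the exponential;
#' `b0 = 1/tc0` and `a0 = max(100/y1 - 1, 0.1)` (first positive observation
#' `y1`) for the logistic.
#'
#' Standard errors come from the Jacobian-based covariance scaled by
#' `rss/(n - p)`; 95% confidence intervals use the Student-t quantile with
#' `n - p` degrees of freedom (Wald intervals).
#'
#' @param data A data frame with columns `x` and `y` (e.g. from
#'   [series_points()]), or an [emergence_series()] together with `axis`.
#' @param kind `"exponential"` or `"logistic"`.
#' @param axis When `data` is an emergence series: `"months"` or
#'   `"publications"`.
#' @param level Confidence level for parameter intervals (default 0.95).
#' @return A `saturation_fit`: list with the fitted `model`, a `params`
#'   tibble (`term`, `estimate`, `std.error`, `conf.low`, `conf.high`),
#'   sizes `n` and `p`, statistics `rss`, `rmse`, `r2`, `r2_adj`, `aicc`,
#'   flags `converged`, `perfect_fit`, iteration count `n_iter`, the fitted
#'   `data`, the `axis` label and the covariance matrix `cov`.
#' @examples
#' pts <- series_points(emergence_series(davinci_corpus(), "utility"))
#' fit_saturation(pts, "exponential")
#' @export
fit_saturation <- function(data, kind = c("exponential", "logistic"),
                           axis = c("months", "publications"),
                           level = 0.95) {
  kind <- match.arg(kind)
  if (inherits(data, "emergence_series")) {
    axis <- match.arg(axis)
    data <- series_points(data, axis)
  } else {
    axis <- if (missing(axis)) NA_character_ else match.arg(axis)
    data <- tibble::as_tibble(data)[c("x", "y")]
  }
  p <- if (kind == "exponential") 1L else 2L
  if (nrow(data) < p + 1) {
    abort("Need at least p + 1 points to fit a saturation model.")
  }
  if (any(data$x < 0) || any(data$y < 0 | data$y > 100)) {
    abort("Points must satisfy x >= 0 and 0 <= y <= 100.")
  }
  formula <- if (kind == "exponential") {
    y ~ 100 * (1 - exp(-x / tc))
  } else {
    y ~ 100 / (1 + a * exp(-b * x))
  }
  start <- sat_start(kind, data$x, data$y)
  fit <- minpack.lm::nlsLM(
    formula, data = data, start = start,
    lower = rep(1e-10, p),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 500))
  if (!fit$convInfo$isConv) abort("Saturation fit failed to converge.")
  est <- coef(fit)
  stats <- sat_stats(data$y, predict(fit), p)
  covm <- tryCatch(vcov(fit), error = function(e) {
    matrix(NA_real_, p, p, dimnames = list(names(est), names(est)))
  })
  se <- sqrt(pmax(diag(covm), 0))
  tcrit <- qt(1 - (1 - level) / 2, df = stats$n - p)
  params <- tibble::tibble(term = names(est),
                           estimate = unname(est),
                           std.error = unname(se),
                           conf.low = unname(est - tcrit * se),
                           conf.high = unname(est + tcrit * se))
  model <- if (kind == "exponential") {
    saturation_model("exponential", tc = est[["tc"]])
  } else {
    saturation_model("logistic", a = est[["a"]], b = est[["b"]])
  }
  structure(c(list(model = model, kind = kind, params = params, p = p,
                   converged = fit$convInfo$isConv,
                   n_iter = fit$convInfo$finIter,
                   level = level, data = data, axis = axis, cov = covm),
              stats),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit> ", x$kind, " on ", x$n, " points",
      if (!is.na(x$axis)) paste0(" (", x$axis, " axis)"), "\n", sep = "")
  for (i in seq_len(nrow(x$params))) {
    cat(sprintf("  %-3s = %8.4f  (SE %.4f, %g%% CI %.4f to %.4f)\n",
                x$params$term[i], x$params$estimate[i], x$params$std.error[i],
                100 * x$level, x$params$conf.low[i], x$params$conf.high[i]))
  }
  cat(sprintf("  rss %.3f, rmse %.3f, adj. R2 %.4f, AICc %s\n",
              x$rss, x$rmse, x$r2_adj,
              ifelse(is.na(x$aicc), "undefined",
                     sprintf("%.2f", x$aicc))))
  if (x$perfect_fit) cat("  (perfect fit: rss = 0, AICc undefined)\n")
  invisible(x)
}

#' @rdname fit_saturation
#' @param x A `saturation_fit`.
#' @param ... Unused.
#' @export
tidy.saturation_fit <- function(x, ...) {
  x$params
}

#' @rdname fit_saturation
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = x$n, p = x$p, rss = x$rss, rmse = x$rmse,
                 r.squared = x$r2, adj.r.squared = x$r2_adj, AICc = x$aicc,
                 converged = x$converged, perfect_fit = x$perfect_fit,
                 n_iter = x$n_iter)
}

#' Fit and compare candidate saturation models
#'
#' Fits every candidate on identical points and ranks them by AICc (lowest
#' wins; a perfect fit, whose AICc is degenerate at minus infinity, ranks
#' first). The comparison table also reports the margins (differences to the
#' selected model) in AICc, adjusted R-squared and RMSE.
#'
#' @inheritParams fit_saturation
#' @param kinds Candidate model kinds (at least one).
#' @return A `model_comparison`: list with `fits` (named list of
#'   `saturation_fit`), `table` (one row per candidate with a `delta_aicc`
#'   column) and `selected` (kind with the lowest AICc).
#' @examples
#' pts <- series_points(emergence_series(davinci_corpus(), "utility"))
#' compare_models(pts)
#' @export
compare_models <- function(data, kinds = c("exponential", "logistic"),
                           axis = c("months", "publications"),
                           level = 0.95) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (inherits(data, "emergence_series")) {
    axis <- match.arg(axis)
    data <- series_points(data, axis)
  }
  fits <- setNames(
    lapply(kinds, function(k) fit_saturation(data, k, level = level)),
    kinds)
  tab <- purrr::map_dfr(fits, glance)
  key <- ifelse(tab$perfect_fit, -Inf, tab$AICc)
  if (anyNA(key)) abort("AICc undefined for a candidate; cannot rank.")
  sel <- which.min(key)
  tab$delta_aicc <- key - key[sel]
  tab$delta_adj_r2 <- tab$adj.r.squared - tab$adj.r.squared[sel]
  tab$delta_rmse <- tab$rmse - tab$rmse[sel]
  structure(list(fits = fits, table = tab, selected = kinds[sel]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> selected:", x$selected, "\n")
  print(x$table[c("kind", "n", "rmse", "adj.r.squared", "AICc",
                  "delta_aicc")])
  invisible(x)
}

#' @rdname compare_models
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @export
tidy.model_comparison <- function(x, ...) {
  x$table
}

# pointwise delta-method standard error of f(t) under the fit's covariance
fit_curve_se <- function(fit, t) {
  f <- sat_fun(fit$kind)
  p0 <- fit$model$params
  eps <- pmax(abs(p0), 1) * 1e-6
  grads <- vapply(seq_along(p0), function(j) {
    ph <- p0; ph[j] <- ph[j] + eps[j]
    pl <- p0; pl[j] <- pl[j] - eps[j]
    (f(t, ph) - f(t, pl)) / (2 * eps[j])
  }, numeric(length(t)))
  grads <- matrix(grads, nrow = length(t))
  sqrt(pmax(rowSums((grads %*% fit$cov) * grads), 0))
}

#' Plot a saturation fit
#'
#' Observed cumulative occurrence proportions with the fitted curve and a
#' pointwise Wald confidence band (delta method on the fitted parameters).
#'
#' @param object A `saturation_fit`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saturation_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble::tibble(x = seq(0, max(object$data$x), length.out = n_grid))
  grid$y <- model_eval(object, grid$x)
  se <- fit_curve_se(object, grid$x)
  tcrit <- qt(1 - (1 - object$level) / 2, df = object$n - object$p)
  grid$ymin <- pmax(grid$y - tcrit * se, 0)
  grid$ymax <- pmin(grid$y + tcrit * se, 100)
  xlab <- switch(as.character(object$axis),
                 months = "Months since window anchor",
                 publications = "Cumulative publications",
                 "t")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y), colour = "steelblue") +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = xlab, y = "Cumulative occurrence proportion (%)",
                  title = paste0(object$kind, " saturation fit")) +
    ggplot2::theme_minimal()
}
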