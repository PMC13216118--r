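#' Invert a saturation model at a target proportion
#'
#' Solves `f(t) = target` for the elapsed time (or publication count) at
#' which the cumulative occurrence proportion reaches the target. Closed
#' forms: exponential `t = -Tc log(1 - target/100)`; logistic
#' `t = -(1/b) log((100/target - 1)/a)`. A logistic target at or below
#' `f(0)` is reached before the origin and is reported as 0 with a warning.
#'
#' @param model A [saturation_model()] or `saturation_fit`.
#' @param target_pct Target proportion(s) in percent, strictly inside
#'   (0, 100).
#' @return Axis value(s) at which the target is reached.
#' @examples
#' invert_model(saturation_model("exponential", tc = 8.2), c(50, 80, 99.9))
#' @export
invert_model <- function(model, target_pct) {
  if (inherits(model, "saturation_fit")) model <- model$model
  stopifnot(inherits(model, "saturation_model"))
  if (any(target_pct <= 0 | target_pct >= 100)) {
    abort("`target_pct` must lie strictly inside (0, 100).")
  }
  p <- model$params
  if (model$kind == "exponential") {
    return(-p[["tc"]] * log(1 - target_pct / 100))
  }
  t <- -(1 / p[["b"]]) * log((100 / target_pct - 1) / p[["a"]])
  if (any(t <= 0)) {
    warn("Logistic target at or below f(0); reached before the origin, reporting 0.")
    t <- pmax(t, 0)
  }
  t
}

# run code with a temporarily seeded RNG, restoring the caller's state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Threshold estimate with confidence interval
#'
#' Estimates the axis value needed to reach a target cumulative occurrence
#' proportion from a fitted saturation model, with a confidence interval by
#' one of three methods:
#' * `"transform"` (exponential only): maps the Wald CI of `Tc` through the
#'   inversion, which is a monotone scalar reparameterization — exact given
#'   the parameter interval. The default for exponential fits.
#' * `"delta"`: first-order propagation, `SE(t) = sqrt(g' V g)` with `g` the
#'   gradient of the inversion in the parameters and `V` the fit covariance;
#'   works for both kinds and is the default for logistic fits.
#' * `"bootstrap"`: residual resampling — refit on `fitted + resampled
#'   residuals`, invert each replicate, take percentile limits.
#'
#' @param fit A `saturation_fit`.
#' @param target_pct Target proportion(s) in percent, inside (0, 100).
#' @param method `"transform"`, `"delta"` or `"bootstrap"`.
#' @param level Confidence level (default: the fit's own, 0.95).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Optional seed for the bootstrap (RNG state is restored).
#' @return A tibble with one row per target: `target_pct`, `estimate`,
#'   `ci_low`, `ci_high`, `axis`, `method`.
#' @examples
#' pts <- series_points(emergence_series(davinci_corpus(), "utility"))
#' fit <- fit_saturation(pts, "exponential")
#' threshold_ci(fit, c(50, 80, 99.9))
#' @export
threshold_ci <- function(fit, target_pct,
                         method = c("transform", "delta", "bootstrap"),
                         level = fit$level, n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "saturation_fit"))
  est <- invert_model(fit, target_pct)
  if (method == "transform") {
    if (fit$kind != "exponential") {
      abort(paste("The transform method needs a monotone scalar parameter;",
                  "use method = 'delta' or 'bootstrap' for logistic fits."))
    }
    tcrit <- qt(1 - (1 - level) / 2, df = fit$n - fit$p)
    se_tc <- fit$params$std.error[fit$params$term == "tc"]
    tc <- fit$model$params[["tc"]]
    fac <- -log(1 - target_pct / 100)  # > 0, monotone in tc
    lo <- (tc - tcrit * se_tc) * fac
    hi <- (tc + tcrit * se_tc) * fac
  } else if (method == "delta") {
    p0 <- fit$model$params
    se <- vapply(seq_along(target_pct), function(i) {
      g <- if (fit$kind == "exponential") {
        matrix(-log(1 - target_pct[i] / 100))
      } else {
        t_i <- est[i]
        matrix(c(1 / (p0[["a"]] * p0[["b"]]), -t_i / p0[["b"]]), ncol = 1)
      }
      sqrt(max(t(g) %*% fit$cov %*% g, 0))
    }, numeric(1))
    tcrit <- qt(1 - (1 - level) / 2, df = fit$n - fit$p)
    lo <- pmax(est - tcrit * se, 0)
    hi <- est + tcrit * se
  } else {
    fitted_y <- model_eval(fit, fit$data$x)
    res <- fit$data$y - fitted_y
    reps <- with_local_seed(seed, {
      replicate(n_boot, {
        y_star <- pmin(pmax(fitted_y + sample(res, replace = TRUE), 0), 100)
        f <- tryCatch(
          fit_saturation(tibble::tibble(x = fit$data$x, y = y_star),
                         fit$kind),
          error = function(e) NULL)
        if (is.null(f)) rep(NA_real_, length(target_pct))
        else suppressWarnings(invert_model(f, target_pct))
      })
    })
    reps <- matrix(reps, nrow = length(target_pct))
    alpha <- (1 - level) / 2
    qs <- apply(reps, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    lo <- qs[1, ]
    hi <- qs[2, ]
  }
  tibble::tibble(target_pct = target_pct, estimate = unname(est),
                 ci_low = unname(lo), ci_high = unname(hi),
                 axis = fit$axis, method = method)
}

#' Threshold table over several fits
#'
#' Tabulates the estimated time (or publication count) to reach each target
#' proportion for a collection of fitted models — typically one fit per
#' (category, axis) pair.
#'
#' @param fits A named list of `saturation_fit` objects (a single fit is
#'   accepted and labelled `"fit"`).
#' @param targets Target proportions in percent (default `c(50, 80, 99.9)`,
#'   with 99.9% the saturation proxy). An empty vector yields an empty
#'   table.
#' @param method CI method passed to [threshold_ci()]; `"transform"` falls
#'   back to `"delta"` for logistic fits.
#' @param ... Passed on to [threshold_ci()].
#' @return A tibble with columns `fit`, `target_pct`, `estimate`, `ci_low`,
#'   `ci_high`, `axis`, `method`.
#' @export
threshold_table <- function(fits, targets = c(50, 80, 99.9),
                            method = "transform", ...) {
  if (inherits(fits, "saturation_fit")) fits <- list(fit = fits)
  if (length(targets) == 0) {
    return(tibble::tibble(fit = character(), target_pct = numeric(),
                          estimate = numeric(), ci_low = numeric(),
                          ci_high = numeric(), axis = character(),
                          method = character()))
  }
  purrr::imap_dfr(fits, function(f, nm) {
    m <- if (method == "transform" && f$kind != "exponential") "delta" else
      method
    dplyr::bind_cols(tibble::tibble(fit = nm),
                     threshold_ci(f, targets, method = m, ...))
  })
}
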