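# independent 1-d oracle: golden-section minimisation of the exponential RSS
oracle_exp_tc <- function(pts) {
  rss <- function(tc) sum((pts$y - 100 * (1 - exp(-pts$x / tc)))^2)
  stats::optimize(rss, c(0.05, 10 * max(pts$x)), tol = 1e-10)$minimum
}

test_that("saturation models evaluate their closed forms", {
  ex <- saturation_model("exponential", tc = 8.2)
  expect_equal(model_eval(ex, 0), 0)
  expect_equal(model_eval(ex, 8.2), 100 * (1 - exp(-1)))
  lo <- saturation_model("logistic", a = 9, b = 0.2)
  expect_equal(model_eval(lo, log(9) / 0.2), 50)
  expect_equal(model_eval(lo, 0), 10)
  expect_error(saturation_model("exponential", tc = -1), "positive")
  expect_error(saturation_model("logistic", a = 1, b = 0), "positive")
  expect_error(model_eval(ex, -1), "non-negative")
})

test_that("noiseless model-generated data is recovered exactly", {
  x <- 1:10
  pts_e <- tibble::tibble(x = x, y = 100 * (1 - exp(-x / 10)))
  fe <- fit_saturation(pts_e, "exponential")
  expect_equal(fe$model$params[["tc"]], 10, tolerance = 1e-6)
  expect_lt(fe$rmse, 1e-8)
  expect_true(fe$perfect_fit)
  expect_true(is.na(fe$aicc))
  expect_equal(fe$r2_adj, 1, tolerance = 1e-10)

  pts_l <- tibble::tibble(x = x, y = 100 / (1 + 20 * exp(-0.4 * x)))
  fl <- fit_saturation(pts_l, "logistic")
  expect_equal(unname(fl$model$params), c(20, 0.4), tolerance = 1e-5)
  expect_lt(fl$rmse, 1e-7)
})

test_that("the least-squares solution agrees with an independent optimiser", {
  dav <- davinci_corpus()
  for (ct in c("utility", "issue")) {
    pts <- series_points(emergence_series(dav, ct), "months")
    fit <- fit_saturation(pts, "exponential")
    expect_equal(fit$model$params[["tc"]], oracle_exp_tc(pts),
                 tolerance = 1e-6, info = ct)
  }
})

test_that("exponential fits are scale-equivariant in x", {
  pts <- series_points(emergence_series(davinci_corpus(), "utility"),
                       "months")
  tc1 <- fit_saturation(pts, "exponential")$model$params[["tc"]]
  scaled <- tibble::tibble(x = pts$x * 2.5, y = pts$y)
  tc2 <- fit_saturation(scaled, "exponential")$model$params[["tc"]]
  expect_equal(tc2, 2.5 * tc1, tolerance = 1e-8)
})

test_that("fit statistics and Wald intervals are internally consistent", {
  pts <- series_points(emergence_series(davinci_corpus(), "issue"),
                       "months")
  fit <- fit_saturation(pts, "exponential")
  expect_equal(fit$rmse, sqrt(fit$rss / fit$n))
  expect_lte(fit$r2_adj, 1)
  expect_true(fit$params$conf.low < fit$params$estimate &
                fit$params$estimate < fit$params$conf.high)
  g <- glance(fit)
  expect_equal(g$AICc,
               fit$n * log(fit$rss / fit$n) + 2 * 2 + 2 * 2 * 3 / (fit$n - 3))

  # zero-variance outcome: R2 undefined, no error
  flat <- fit_saturation(tibble::tibble(x = 1:5, y = rep(50, 5)),
                         "exponential")
  expect_true(is.na(flat$r2_adj))
})

test_that("Wald CI width shrinks roughly as 1/sqrt(n)", {
  set.seed(31)
  sim_fit <- function(n) {
    x <- seq(0.5, 50, length.out = n)
    y <- pmin(pmax(100 * (1 - exp(-x / 8)) + rnorm(n, 0, 3), 0), 100)
    f <- fit_saturation(tibble::tibble(x = x, y = y), "exponential")
    diff(c(f$params$conf.low, f$params$conf.high))
  }
  w_small <- sim_fit(25)
  w_large <- sim_fit(400)
  expect_lt(w_large, w_small / 2.5)
})

test_that("model comparison selects the generating family", {
  dav <- davinci_corpus()
  cmp <- compare_models(series_points(emergence_series(dav, "utility"),
                                      "months"))
  expect_equal(cmp$selected, "exponential")
  expect_equal(cmp$table$delta_aicc[cmp$table$kind == cmp$selected], 0)

  set.seed(5)
  x <- seq(1, 25)
  y <- pmin(pmax(100 / (1 + 20 * exp(-0.3 * x)) + rnorm(25, 0, 1), 0), 100)
  cmp_l <- compare_models(tibble::tibble(x = x, y = y))
  expect_equal(cmp_l$selected, "logistic")

  single <- compare_models(tibble::tibble(x = x, y = y),
                           kinds = "exponential")
  expect_equal(single$selected, "exponential")
})

test_that("underdetermined fits are refused", {
  expect_error(fit_saturation(tibble::tibble(x = 1, y = 50), "exponential"),
               "at least")
  expect_error(fit_saturation(tibble::tibble(x = 1:2, y = c(10, 50)),
                              "logistic"),
               "at least")
  expect_error(fit_saturation(tibble::tibble(x = 1:3, y = c(-5, 50, 60)),
                              "exponential"),
               "0 <= y")
})
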