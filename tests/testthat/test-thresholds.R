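test_that("model inversion has the closed forms", {
  expect_equal(invert_model(saturation_model("exponential", tc = 8.2), 50),
               8.2 * log(2), tolerance = 1e-12)
  expect_equal(invert_model(saturation_model("exponential", tc = 16.2), 80),
               16.2 * log(5), tolerance = 1e-12)  # about 26.07 months
  expect_error(invert_model(saturation_model("exponential", tc = 5), 100),
               "inside")
  expect_warning(
    t0 <- invert_model(saturation_model("logistic", a = 9, b = 0.2), 5),
    "before the origin")
  expect_equal(t0, 0)
})

test_that("inversion and evaluation are mutual inverses", {
  targets <- c(seq(1, 99, by = 7), 99.9)
  for (m in list(saturation_model("exponential", tc = 8.2),
                 saturation_model("logistic", a = 9, b = 0.12))) {
    tt <- suppressWarnings(invert_model(m, targets))
    ok <- tt > 0  # logistic targets below f(0) are clamped to the origin
    expect_equal(model_eval(m, tt[ok]), targets[ok], tolerance = 1e-9)
    expect_true(all(diff(tt[ok]) > 0))
  }
})

test_that("the 99.9/50 threshold ratio is the exponential invariant", {
  for (tc in c(1.3, 8.2, 16.2)) {
    m <- saturation_model("exponential", tc = tc)
    expect_equal(invert_model(m, 99.9) / invert_model(m, 50),
                 log(1000) / log(2), tolerance = 1e-9)
  }
})

test_that("transform CIs equal the image of the Tc interval", {
  fit <- fit_saturation(
    series_points(emergence_series(davinci_corpus(), "utility"), "months"),
    "exponential")
  out <- threshold_ci(fit, c(50, 80, 99.9), method = "transform")
  # oracle: dense grid image of the parameter interval under inversion
  grid <- seq(fit$params$conf.low, fit$params$conf.high, length.out = 2001)
  for (i in seq_len(nrow(out))) {
    img <- range(-grid * log(1 - out$target_pct[i] / 100))
    expect_equal(out$ci_low[i], img[1], tolerance = 1e-6)
    expect_equal(out$ci_high[i], img[2], tolerance = 1e-6)
  }
  expect_true(all(out$ci_low < out$estimate & out$estimate < out$ci_high))
  expect_true(all(diff(out$estimate) > 0))
  # published interval for the 50% utilities threshold: 5.2 to 6.2 months
  expect_equal(out$ci_low[1], 5.13, tolerance = 0.02)
  expect_equal(out$ci_high[1], 6.32, tolerance = 0.02)
})

test_that("delta and transform CIs coincide for the exponential model", {
  fit <- fit_saturation(
    series_points(emergence_series(davinci_corpus(), "issue"), "months"),
    "exponential")
  tr <- threshold_ci(fit, c(50, 99.9), method = "transform")
  de <- threshold_ci(fit, c(50, 99.9), method = "delta")
  # the inversion is linear in Tc, so first-order propagation is exact
  expect_equal(de$ci_low, tr$ci_low, tolerance = 1e-10)
  expect_equal(de$ci_high, tr$ci_high, tolerance = 1e-10)
})

test_that("transform is refused for the two-parameter logistic", {
  set.seed(8)
  x <- 1:25
  y <- pmin(pmax(100 / (1 + 15 * exp(-0.25 * x)) + rnorm(25, 0, 1), 0), 100)
  fit_l <- fit_saturation(tibble::tibble(x = x, y = y), "logistic")
  expect_error(threshold_ci(fit_l, 50, method = "transform"), "delta")
  de <- threshold_ci(fit_l, 50, method = "delta")
  expect_true(de$ci_low < de$estimate & de$estimate < de$ci_high)
})

test_that("a perfect fit yields a zero-width interval", {
  x <- 1:10
  fit <- fit_saturation(tibble::tibble(x = x, y = 100 * (1 - exp(-x / 6))),
                        "exponential")
  out <- threshold_ci(fit, 50, method = "transform")
  expect_equal(out$ci_low, out$estimate, tolerance = 1e-6)
  expect_equal(out$ci_high, out$estimate, tolerance = 1e-6)
})

test_that("bootstrap and transform CIs agree on well-specified data", {
  set.seed(19)
  x <- seq(1, 50, length.out = 40)
  y <- pmin(pmax(100 * (1 - exp(-x / 9)) + rnorm(40, 0, 2.5), 0), 100)
  fit <- fit_saturation(tibble::tibble(x = x, y = y), "exponential")
  tr <- threshold_ci(fit, 50, method = "transform")
  bs <- threshold_ci(fit, 50, method = "bootstrap", n_boot = 600, seed = 20)
  width <- tr$ci_high - tr$ci_low
  expect_lt(abs(bs$ci_low - tr$ci_low), 0.5 * width)
  expect_lt(abs(bs$ci_high - tr$ci_high), 0.5 * width)
  # seeded bootstrap is reproducible
  bs2 <- threshold_ci(fit, 50, method = "bootstrap", n_boot = 600, seed = 20)
  expect_identical(bs, bs2)
})

test_that("threshold tables cover the requested grid", {
  dav <- davinci_corpus()
  fits <- list(
    utility_months = fit_saturation(
      series_points(emergence_series(dav, "utility"), "months"),
      "exponential"),
    issue_months = fit_saturation(
      series_points(emergence_series(dav, "issue"), "months"),
      "exponential"))
  tab <- threshold_table(fits, targets = c(50, 80, 99.9))
  expect_equal(nrow(tab), 6)
  expect_equal(unique(tab$fit), c("utility_months", "issue_months"))
  empty <- threshold_table(fits, targets = numeric(0))
  expect_equal(nrow(empty), 0)
})
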