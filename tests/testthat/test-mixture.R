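test_that("histograms conserve counts and place edge values correctly", {
  h <- build_histogram(c(0.5, 0.5, 0.5))
  expect_equal(sum(h$counts), 3)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$mids[h$counts == 3], 0.525) # 0.5 falls in [0.5, 0.55)

  empty <- build_histogram(numeric(0))
  expect_true(all(empty$counts == 0))
  expect_equal(length(empty$counts), 20)

  # right edge 1.0 goes to the last bin; counts always conserved
  h2 <- build_histogram(c(0, 1, 0.999, 0.049, 0.05))
  expect_equal(sum(h2$counts), 5)
  expect_equal(h2$counts[20], 2)
  expect_equal(h2$counts[1], 2)
  expect_equal(h2$counts[2], 1)

  expect_error(build_histogram(c(0.5, 1.2)), class = "oligofret_out_of_range")
})

test_that("the modal bin of a truncated normal sample contains its center", {
  set.seed(21)
  e <- pmin(pmax(rnorm(1000, 0.24, 0.08), 0), 1)
  h <- build_histogram(e)
  modal <- h$mids[which.max(h$counts)]
  expect_lt(abs(modal - 0.24), 0.05)
})

test_that("a single-population histogram yields one dominant component at its center", {
  set.seed(22)
  e <- pmin(pmax(rnorm(3000, 0.24, 0.08), 0), 1)
  fit <- global_fit(build_histogram(e))
  areas <- fit$amplitudes[1, ] * fit$widths
  dominant <- which.max(areas)
  expect_equal(unname(fit$centers[dominant]), 0.24, tolerance = 0.02)
  expect_lt(min(areas) / sum(areas), 0.1)
})

test_that("global fit shares one center pair across datasets with distinct amplitudes", {
  set.seed(23)
  draw <- function(n, f) {
    comp <- rbinom(n, 1, f)
    pmin(pmax(rnorm(n, ifelse(comp == 1, 0.48, 0.24), 0.08), 0), 1)
  }
  h1 <- build_histogram(draw(4000, 0.3), label = "t1")
  h2 <- build_histogram(draw(4000, 0.7), label = "t2")
  fit <- global_fit(list(h1, h2))
  expect_equal(unname(fit$centers["low"]), 0.24, tolerance = 0.02)
  expect_equal(unname(fit$centers["high"]), 0.48, tolerance = 0.02)
  f1 <- fraction_converted(fit, "t1")
  f2 <- fraction_converted(fit, "t2")
  expect_equal(f1$fraction, 0.3, tolerance = 0.05)
  expect_equal(f2$fraction, 0.7, tolerance = 0.05)
  expect_gt(f2$fraction, f1$fraction)
  expect_true(f1$se > 0 && f2$se > 0)
})

test_that("fraction converted follows the analytic area ratio", {
  # noise-free histograms constructed from exact two-Gaussian curves
  mids <- build_histogram(numeric(0))$mids
  curve <- function(a1, a2, w = 0.06) {
    a1 * exp(-(mids - 0.24)^2 / (2 * w^2)) +
      a2 * exp(-(mids - 0.48)^2 / (2 * w^2))
  }
  mk <- function(a1, a2) {
    h <- build_histogram(numeric(0))
    h$counts <- round(curve(a1, a2))
    h
  }
  fit_eq <- global_fit(mk(400, 400))
  expect_equal(fraction_converted(fit_eq)$fraction, 0.5, tolerance = 1e-3)
  fit_31 <- global_fit(mk(600, 200))
  expect_equal(fraction_converted(fit_31)$fraction, 0.25, tolerance = 1e-3)
})

test_that("empty histograms and missing datasets are rejected", {
  expect_error(global_fit(build_histogram(numeric(0))),
               class = "oligofret_nonconvergence")
  set.seed(24)
  h <- build_histogram(pmin(pmax(rnorm(500, 0.3, 0.1), 0), 1))
  fit <- suppressWarnings(global_fit(h))
  expect_error(fraction_converted(fit, 5), class = "oligofret_invalid_params")
})

test_that("fraction converted is invariant to uniform count rescaling", {
  set.seed(25)
  e <- c(pmin(pmax(rnorm(2100, 0.24, 0.08), 0), 1),
         pmin(pmax(rnorm(900, 0.48, 0.08), 0), 1))
  h <- build_histogram(e)
  h4 <- h
  h4$counts <- h$counts * 4L
  f <- fraction_converted(global_fit(h))$fraction
  f4 <- fraction_converted(global_fit(h4))$fraction
  # invariance is exact up to the unit weight floor on empty bins
  expect_equal(f, f4, tolerance = 1e-3)
  f_unw <- fraction_converted(global_fit(h, weighting = "none"))$fraction
  f4_unw <- fraction_converted(global_fit(h4, weighting = "none"))$fraction
  expect_equal(f_unw, f4_unw, tolerance = 1e-6)
  expect_true(f >= 0 && f <= 1)
})

test_that("pooling datasets does not inflate the shared-center uncertainty", {
  set.seed(26)
  draw <- function(n, f) {
    comp <- rbinom(n, 1, f)
    pmin(pmax(rnorm(n, ifelse(comp == 1, 0.48, 0.24), 0.08), 0), 1)
  }
  h1 <- build_histogram(draw(3000, 0.4), label = "a")
  h2 <- build_histogram(draw(3000, 0.4), label = "b")
  se_global <- global_fit(list(h1, h2))$center_se
  se_1 <- global_fit(h1)$center_se
  se_2 <- global_fit(h2)$center_se
  expect_lte(se_global["low"], max(se_1["low"], se_2["low"]) * 1.01)
  expect_lte(se_global["high"], max(se_1["high"], se_2["high"]) * 1.01)
})

test_that("bootstrap mean CI behaves on degenerate and normal samples", {
  cst <- bootstrap_mean_ci(c(0.3, 0.3, 0.3), n_resamples = 999, seed = 1)
  expect_equal(cst$ci, c(0.3, 0.3))

  two <- bootstrap_mean_ci(c(0, 1), n_resamples = 9999, seed = 2)
  expect_equal(two$mean, 0.5)
  expect_equal(two$ci, c(0, 1))

  set.seed(3)
  x <- rnorm(100, 0.5, 0.1)
  b <- bootstrap_mean_ci(x, n_resamples = 9999, seed = 4)
  width <- b$ci[2] - b$ci[1]
  expect_equal(width, 2 * 1.96 * 0.1 / sqrt(100), tolerance = 0.2)
  # reproducible for a fixed seed
  b2 <- bootstrap_mean_ci(x, n_resamples = 9999, seed = 4)
  expect_identical(b$ci, b2$ci)

  expect_error(bootstrap_mean_ci(0.5), class = "oligofret_insufficient_data")
})
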