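test_that("uniform stack reproduces the closed-form voxel efficiency exactly", {
  st <- voxel_stack(array(100, c(4, 4, 2)), array(60, c(4, 4, 2)),
                    array(50, c(4, 4, 2)))
  p <- instrument_params(autofluor_donor = 20, autofluor_acceptor = 10,
                         crosstalk = 0.1)
  mask <- array(TRUE, c(4, 4, 2))
  fm <- voxel_fret_map(st, mask, p)
  expect_true(all(fm$E == 40 / 120))
  expect_equal(fm$n_excluded, 0)
})

test_that("acceptor signal equal to its autofluorescence gives zero efficiency", {
  st <- voxel_stack(array(100, c(3, 3, 1)), array(10, c(3, 3, 1)),
                    array(50, c(3, 3, 1)))
  p <- instrument_params(autofluor_acceptor = 10, crosstalk = 0)
  fm <- voxel_fret_map(st, array(TRUE, c(3, 3, 1)), p)
  expect_true(all(fm$E == 0))
})

test_that("masking thresholds the direct channel at mean + k*sd of the blank", {
  set.seed(31)
  blank <- blank_stats(rpois(5000, 2))
  empty <- simulate_incell_stack(data.frame(), dim = c(24, 24, 2), seed = 32)
  expect_warning(m <- make_mask(empty$stack, blank, k = 6), "empty")
  expect_false(any(m))

  # k = 0: every voxel above the blank mean
  st <- voxel_stack(array(1, c(2, 2, 1)), array(1, c(2, 2, 1)),
                    array(c(1, 3, 5, 2), c(2, 2, 1)))
  m0 <- make_mask(st, list(mean = 2, sd = 1), k = 0)
  expect_identical(as.vector(m0), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("mask covers a bright synthetic aggregate (Jaccard >= 0.8)", {
  layout <- data.frame(x = 32, y = 32, z = 4, r_core = 4, r_rim = 8,
                       e_core = 0.48, e_rim = 0.24, brightness = 300,
                       direct_brightness = 20, cell = 1) # 10x background of 2
  sim <- simulate_incell_stack(layout, dim = c(64, 64, 8), seed = 33)
  set.seed(34)
  blank <- blank_stats(rpois(5000, 2))
  mask <- make_mask(sim$stack, blank, k = 3)
  agg <- sim$truth$core | sim$truth$rim
  jac <- sum(mask & agg) / sum(mask | agg)
  expect_gte(jac, 0.8)
  expect_gte(mean(agg[mask]), 0.9) # mask voxels lie almost entirely inside
})

test_that("core/rim aggregates yield higher median efficiency in the core", {
  layout <- data.frame(x = 32, y = 32, z = 4, r_core = 4, r_rim = 8,
                       e_core = 0.48, e_rim = 0.24, brightness = 300,
                       direct_brightness = 150, cell = 1)
  inst <- instrument_params(2, 2, 0.05, 1)
  sim <- simulate_incell_stack(layout, dim = c(64, 64, 8),
                               instrument = inst, seed = 35)
  fm <- voxel_fret_map(sim$stack, sim$truth$core | sim$truth$rim, inst)
  med_core <- median(fm$E[sim$truth$core], na.rm = TRUE)
  med_rim <- median(fm$E[sim$truth$rim], na.rm = TRUE)
  expect_gt(med_core, med_rim)
  expect_equal(med_core, 0.48, tolerance = 0.05)
  expect_equal(med_rim, 0.24, tolerance = 0.05)
  expect_true(all(fm$E >= 0 & fm$E <= 1, na.rm = TRUE))
})

test_that("correction consistency: offsetting channels and constants together leaves E unchanged", {
  set.seed(36)
  d <- array(rpois(64, 100), c(4, 4, 4))
  a <- array(rpois(64, 60), c(4, 4, 4))
  dir <- array(50, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  p <- instrument_params(autofluor_donor = 0, autofluor_acceptor = 0,
                         crosstalk = 0)
  e0 <- voxel_fret_map(voxel_stack(d, a, dir), mask, p)$E
  p_off <- instrument_params(autofluor_donor = 7, autofluor_acceptor = 11,
                             crosstalk = 0)
  e1 <- voxel_fret_map(voxel_stack(d + 7, a + 11, dir), mask, p_off)$E
  expect_equal(e1, e0)
})

test_that("per-cell summaries recover known per-cell efficiencies", {
  st <- voxel_stack(array(c(60, 100), c(2, 1, 1)),
                    array(c(40, 1), c(2, 1, 1)),
                    array(c(50, 50), c(2, 1, 1)))
  fm <- voxel_fret_map(st, array(TRUE, c(2, 1, 1)), instrument_params())
  one <- summarize_cell(fm, st, array(c(1L, 0L), c(2, 1, 1)))
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_E, 0.4)
  expect_equal(one$total_alpha_syn, 50)

  # ten cells with known efficiencies, order-stable by label
  es <- seq(0.1, 0.55, by = 0.05)
  layout <- data.frame(x = rep(c(12, 28, 44, 60, 76), 2),
                       y = rep(c(12, 36), each = 5), z = 3,
                       r_core = 4, r_rim = 4, e_core = es, e_rim = es,
                       brightness = 800, direct_brightness = 150,
                       cell = 1:10)
  inst <- instrument_params(2, 2, 0.05, 1)
  sim <- simulate_incell_stack(layout, dim = c(88, 48, 5),
                               instrument = inst, seed = 37)
  fm <- voxel_fret_map(sim$stack, sim$truth$labels > 0, inst)
  cs <- summarize_cell(fm, sim$stack, sim$truth$labels)
  expect_identical(cs$cell, 1:10)
  expect_true(all(abs(cs$mean_E - es) < 0.02))
  expect_true(all(diff(cs$mean_E) > 0)) # ordering follows the true gradient
})

test_that("voxel efficiency histograms feed the mixture fit unchanged", {
  layout <- data.frame(x = 24, y = 24, z = 3, r_core = 5, r_rim = 10,
                       e_core = 0.48, e_rim = 0.24, brightness = 400,
                       direct_brightness = 150, cell = 1)
  inst <- instrument_params(2, 2, 0.05, 1)
  sim <- simulate_incell_stack(layout, dim = c(48, 48, 6),
                               instrument = inst, seed = 38)
  fm <- voxel_fret_map(sim$stack, sim$truth$core | sim$truth$rim, inst)
  e <- fm$E[!is.na(fm$E)]
  fit <- global_fit(build_histogram(e))
  expect_equal(unname(fit$centers["low"]), 0.24, tolerance = 0.03)
  expect_equal(unname(fit$centers["high"]), 0.48, tolerance = 0.03)
})
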