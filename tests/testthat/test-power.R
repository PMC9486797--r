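test_that("single-replicate power is degenerate and reruns are identical", {
  cell <- run_power_cell(0.5, 20, 18, effect = -0.15, reps = 1, seed = 51)
  expect_true(cell$power %in% c(0, 1))

  a <- run_power_cell(0.5, 20, 18, effect = -0.10, reps = 20, seed = 52)
  b <- run_power_cell(0.5, 20, 18, effect = -0.10, reps = 20, seed = 52)
  expect_identical(a, b)
})

test_that("a strong effect at high fraction and N saturates power", {
  cell <- run_power_cell(0.8, 80, 127, effect = -0.15, reps = 40,
                         seed = 53)
  expect_gt(cell$power, 0.95)
})

test_that("the grid sweep is a full factorial with derived seeds", {
  cfg <- power_grid_config(neutrophil_fractions = c(0.3, 0.6),
                           sample_sizes = c(20, 40),
                           alpha0_values = c(18, 127),
                           reps = 3, seed = 54)
  g <- run_power_grid(cfg)
  expect_equal(nrow(g), 8)
  expect_equal(g$power, g$rejections / g$reps)

  # default grid dimensions: 13 fractions x 4 sizes x 3 concentrations
  dflt <- power_grid_config()
  expect_equal(length(dflt$neutrophil_fractions) *
                 length(dflt$sample_sizes) * length(dflt$alpha0_values),
               156)

  g2 <- run_power_grid(cfg)
  expect_identical(g, g2)
})

test_that("welch t-test agrees between raw and summary forms", {
  set.seed(55)
  x <- rnorm(19, 10, 2); y <- rnorm(19, 8, 3)
  raw <- welch_t_test(x, y)
  summ <- welch_t_test(mean_x = mean(x), sd_x = sd(x), n_x = 19,
                       mean_y = mean(y), sd_y = sd(y), n_y = 19)
  expect_equal(raw$p.value, summ$p.value, tolerance = 1e-12)
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)

  ref <- t.test(x, y) # established implementation as cross-check
  expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(raw$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(raw$p.value, ref$p.value, tolerance = 1e-10)

  same <- welch_t_test(mean_x = 5, sd_x = 0, n_x = 10,
                       mean_y = 5, sd_y = 0, n_y = 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(welch_t_test(1, 1:5), "n >= 2")
})

test_that("published cohort-table group comparisons reproduce", {
  # absolute neutrophils: printed p 0.0007
  neu <- welch_t_test(mean_x = 8651.2, sd_x = 4527, n_x = 19,
                      mean_y = 4180, sd_y = 2369.1, n_y = 19)
  expect_equal(round(neu$p.value, 4), 0.0007)
  # absolute CD4: printed p 0.008
  cd4 <- welch_t_test(mean_x = 517.6, sd_x = 443.8, n_x = 19,
                      mean_y = 930.5, sd_y = 466.9, n_y = 19)
  expect_equal(round(cd4$p.value, 3), 0.008)
})

test_that("chi-squared test matches the direct formula and printed tables", {
  tab <- matrix(c(17, 1, 1, 7, 4, 8), nrow = 2, byrow = TRUE)
  ct <- chi_squared_test(tab)
  expect_equal(round(ct$p.value, 3), 0.003)
  expect_equal(ct$df, 2)
  # expected counts reproduce the outer-product formula
  expect_equal(ct$expected,
               outer(rowSums(tab), colSums(tab)) / sum(tab),
               ignore_attr = TRUE)

  sym <- chi_squared_test(matrix(c(14, 5, 14, 5), nrow = 2, byrow = TRUE))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 1)

  expect_error(chi_squared_test(matrix(c(0, 0, 1, 2), 2)), "marginal")
  expect_error(chi_squared_test(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})
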