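test_that("cell methylome sampling honours panel moments and determinism", {
  cells <- c("CD4T", "CD8T", "Bcell", "NK", "Mono", "Neu")
  panel <- reference_panel(data.frame(
    cpg_id = "cgs00001", cell_type = cells,
    mean = c(0.3, 0.5, 0.5, 0.5, 0.5, 0.5),
    sd = c(0.05, 1e-12, 0.05, 0.05, 0.05, 0.05)))

  xs <- sample_cell_methylomes(panel, 1000, seed = 7)
  v <- vapply(xs, function(x) x[1, "CD4T"], numeric(1))
  # empirical mean within 3 Monte-Carlo SEs of the panel mean
  expect_lt(abs(mean(v) - 0.3), 3 * 0.05 / sqrt(1000))
  # degenerate SD: draws equal the mean
  d <- vapply(xs, function(x) x[1, "CD8T"], numeric(1))
  expect_true(all(abs(d - 0.5) < 1e-6))

  again <- sample_cell_methylomes(panel, 1000, seed = 7)
  expect_identical(xs, again)
})

test_that("exposure injection shifts only the designated entries", {
  panel <- tiny_panel()
  x <- sample_cell_methylomes(panel, 1, seed = 3)[[1]]

  expect_identical(inject_exposure_effect(x, "Neu", 0), x)

  delta <- setNames(-0.1, rownames(x)[1])
  y <- inject_exposure_effect(x, "Neu", delta)
  expect_equal(y[1, "Neu"], max(x[1, "Neu"] - 0.1, 0.001))
  y[1, "Neu"] <- x[1, "Neu"]
  expect_identical(y, x)

  # boundary rule: shift below zero clips at the floor epsilon
  low <- x; low[1, "Neu"] <- 0.05
  z <- inject_exposure_effect(low, "Neu", setNames(-0.1, rownames(x)[1]))
  expect_equal(z[1, "Neu"], 0.001)

  expect_error(inject_exposure_effect(x, "Eosinophil", 0), "unknown cell")
})

test_that("Dirichlet fractions have the stated moments and simplex rows", {
  mf <- mean_fractions(0.5)
  expect_equal(sum(mf), 1)
  expect_equal(unname(mf["Neu"]), 0.5)

  w18 <- sample_cell_fractions(18, mf, 10000, seed = 5)
  expect_true(all(abs(rowSums(w18) - 1) < 1e-9))
  expect_true(all(w18 >= 0))
  # Dirichlet mean property, within 3 MC standard errors
  sd18 <- sqrt(0.5 * 0.5 / 19)
  expect_lt(abs(mean(w18[, "Neu"]) - 0.5), 3 * sd18 / sqrt(10000))
  # closed-form component variance at alpha0 = 18
  expect_equal(sd(w18[, "Neu"]), sd18, tolerance = 0.05)

  # higher concentration => less variability, every component
  w127 <- sample_cell_fractions(127, mf, 10000, seed = 6)
  expect_true(all(apply(w127, 2, sd) < apply(w18, 2, sd)))

  expect_error(sample_cell_fractions(18, c(0.5, 0.5, 0), 5), "positive")
})

test_that("whole-blood mixing is an exact convex combination", {
  X <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  expect_equal(unname(mix_whole_blood(X, c(1, 0))), unname(X[, 1]))
  expect_equal(unname(mix_whole_blood(X, c(0.5, 0.5))[1]), 0.5)

  set.seed(8)
  Xr <- matrix(runif(60), 10, 6)
  w <- rgamma(6, 1); w <- w / sum(w)
  y <- mix_whole_blood(Xr, w)
  expect_true(all(y >= apply(Xr, 1, min) - 1e-12))
  expect_true(all(y <= apply(Xr, 1, max) + 1e-12))

  expect_error(mix_whole_blood(Xr, c(0.5, 0.5)), "dimension mismatch")
})

test_that("generate_cohort meets its shape and determinism contracts", {
  panel <- default_panel(n_cpgs = 300)
  cfg <- simulation_config(10, 10, seed = 11)
  co <- generate_cohort(cfg, panel)
  expect_equal(dim(co$betas), c(300, 20))
  expect_identical(unname(co$labels), rep(0:1, each = 10))
  expect_true(all(co$betas >= 0 & co$betas <= 1))
  expect_equal(dim(co$true_fractions), c(20, 6))

  co2 <- generate_cohort(cfg, panel)
  expect_identical(co, co2)
})

test_that("injected group difference matches the mixture algebra", {
  # strong neutrophil delta, near-degenerate fractions: the whole-blood
  # group mean difference at affected CpGs approaches fraction * delta
  panel <- default_panel(n_cpgs = 300)
  idx <- panel_index_cpgs(panel)
  delta <- setNames(rep(-0.2, length(idx)), idx)
  cfg <- simulation_config(150, 150, alpha0 = 5000,
                           neutrophil_mean_fraction = 0.6,
                           effect = delta, seed = 13)
  co <- generate_cohort(cfg, panel)
  db <- rowMeans(co$betas[idx, co$labels == 1]) -
    rowMeans(co$betas[idx, co$labels == 0])
  expect_equal(mean(db), 0.6 * -0.2, tolerance = 0.02)

  # null construction: no effect => no systematic difference anywhere
  cfg0 <- simulation_config(150, 150, effect = setNames(0, idx[1]),
                            seed = 14)
  co0 <- generate_cohort(cfg0, panel)
  db0 <- rowMeans(co0$betas[, co0$labels == 1]) -
    rowMeans(co0$betas[, co0$labels == 0])
  expect_lt(abs(mean(db0)), 0.01)
})

test_that("cohort round-trips through its delimited-text form", {
  panel <- default_panel(n_cpgs = 300)
  co <- generate_cohort(simulation_config(5, 5, wbc = TRUE, seed = 2),
                        panel)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  b <- read_cohort_betas(dir)
  expect_equal(b, co$betas, tolerance = 1e-8)
  ss <- read.delim(file.path(dir, "samples.tsv"))
  expect_identical(ss$exposed, unname(co$labels))
  expect_true("true_frac_Neu" %in% names(ss))
})
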