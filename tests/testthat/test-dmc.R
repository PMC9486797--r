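test_that("ewas screen applies both thresholds and flags constants", {
  set.seed(31)
  n <- 40
  labels <- rep(0:1, each = n / 2)
  betas <- matrix(runif(5 * n, 0.3, 0.5), 5, n,
                  dimnames = list(paste0("cg", 1:5), NULL))
  # big clean shift passes; sub-threshold shift with tiny p fails
  betas[1, labels == 1] <- betas[1, labels == 1] + 0.12
  betas[2, ] <- rep(c(0.40, 0.45), c(n / 2, n / 2)) +
    rnorm(n, 0, 0.001) # delta 0.05, p tiny
  betas[3, ] <- 0.5 # constant
  res <- ewas_screen(betas, labels)
  expect_true(res$passes_filter[1])
  expect_lt(res$p_value[2], 1e-6)
  expect_false(res$passes_filter[2]) # fails the >= 0.10 delta filter
  expect_true(is.na(res$p_value[3]) && !res$passes_filter[3])
  expect_equal(res$delta_beta[2], 0.05, tolerance = 0.01)
})

test_that("ewas p-values are uniform under the null", {
  set.seed(32)
  n <- 60
  labels <- rep(0:1, each = n / 2)
  betas <- matrix(rbeta(1000 * n, 5, 5), 1000, n,
                  dimnames = list(sprintf("cg%04d", 1:1000), NULL))
  res <- ewas_screen(betas, labels, db_threshold = 0)
  frac <- mean(res$p_value < 0.05)
  # binomial 99% bounds around 0.05 at 1000 CpGs
  expect_lt(abs(frac - 0.05), 2.58 * sqrt(0.05 * 0.95 / 1000))
})

test_that("interaction model recovers a neutrophil-specific effect", {
  panel <- default_panel(n_cpgs = 60, n_discriminating = 5)
  idx <- panel_index_cpgs(panel)
  delta <- setNames(rep(-0.25, length(idx)), idx)
  ests <- replicate(15, {
    seed <- sample.int(1e6, 1)
    co <- suppressWarnings(
      generate_cohort(simulation_config(70, 60, effect = delta,
                                        seed = seed), panel))
    f <- fit_interaction_model(co$betas[idx[1], ], co$true_fractions,
                               co$labels)
    f$coefficients$b
  })
  b <- rowMeans(ests)
  names(b) <- c("CD4T", "CD8T", "Bcell", "NK", "Mono", "Neu")
  expect_equal(unname(b["Neu"]), -0.25, tolerance = 0.04)
  expect_true(all(abs(b[setdiff(names(b), "Neu")]) < 0.04))
})

test_that("interaction fit matches a normal-equations brute force", {
  set.seed(34)
  N <- 50
  W <- sample_cell_fractions(18, mean_fractions(0.6), N)
  labels <- rep(0:1, length.out = N)
  y <- runif(N, 0.2, 0.8)
  f <- fit_interaction_model(y, W, labels)
  X <- cbind(W, W * labels)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$coefficients$b, unname(beta[7:12, 1]), tolerance = 1e-8)
  expect_equal(f$coefficients$a, unname(beta[1:6, 1]), tolerance = 1e-8)
  # degenerate cases
  expect_error(fit_interaction_model(y, W, rep(0, N)), "both exposure")
  fc <- fit_interaction_model(rep(0.4, N), W, labels)
  expect_true(all(fc$coefficients$b == 0))
  expect_true(all(is.na(fc$coefficients$p)))
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(35)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_brute_force(p))
  }
  p <- c(0.01, NA, 0.5)
  expect_true(is.na(bh_fdr(p)[2]))
  expect_true(all(bh_fdr(p) >= p, na.rm = TRUE))
})

test_that("partition handles the trivial boundary cases", {
  ewas <- data.frame(cpg_id = c("a", "b", "c"),
                     delta_beta = c(0.2, 0.15, 0.01),
                     p_value = c(0.001, 0.002, 0.9),
                     passes_filter = c(TRUE, TRUE, FALSE))
  ints <- data.frame(cpg_id = character(), cell = character(),
                     b = numeric(), se = numeric(), p = numeric(),
                     fdr = numeric(), het_p = numeric())
  part <- partition_dmcs(ewas, ints)
  expect_length(unlist(part$cell_specific), 0)
  expect_setequal(part$non_cell_specific, c("a", "b"))
})

test_that("partition separates neutrophil-specific from global loci", {
  # one cohort with both locus classes; 20-replicate version lives in the
  # acceptance suite
  panel <- default_panel(n_cpgs = 160, n_index = 28,
                         n_discriminating = 20)
  cpgs <- attr(panel, "cpg_ids")
  neu_cpgs <- cpgs[149:156]
  glob_cpgs <- cpgs[157:160]
  set.seed(36)
  eff <- rbind(
    data.frame(cpg_id = neu_cpgs, cell_type = "Neu",
               delta = runif(8, -0.30, -0.20)),
    data.frame(cpg_id = glob_cpgs, cell_type = "all",
               delta = runif(4, -0.15, -0.11)))
  co <- generate_cohort(simulation_config(76, 59, effect = eff, seed = 37),
                        panel)
  ew <- ewas_screen(co)
  ints <- interaction_screen(co, co$true_fractions,
                             cpgs = ew$cpg_id[ew$passes_filter])
  part <- partition_dmcs(ew, ints)
  expect_gte(length(intersect(part$cell_specific$Neu, neu_cpgs)), 6)
  expect_gte(length(intersect(part$non_cell_specific, glob_cpgs)), 3)
})

test_that("hypomethylating neutrophil effects give negative interactions", {
  panel <- default_panel(n_cpgs = 60, n_discriminating = 5)
  idx <- panel_index_cpgs(panel)
  delta <- setNames(rep(-0.25, length(idx)), idx)
  co <- suppressWarnings(
    generate_cohort(simulation_config(70, 60, effect = delta,
                                      seed = 38), panel))
  ints <- interaction_screen(co, co$true_fractions, cpgs = idx)
  neu <- ints[ints$cell == "Neu" & ints$fdr <= 0.05, ]
  expect_gt(nrow(neu), 0)
  expect_true(all(neu$b < 0))
})
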