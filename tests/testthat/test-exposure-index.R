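test_that("composition features are the 6 fractions plus 3 ratios", {
  set.seed(41)
  fr <- sample_cell_fractions(30, mean_fractions(0.5), 12)
  d <- list(fractions = fr, ratios = derived_indices(fr))
  x <- build_composition_features(d)
  expect_equal(ncol(x), 9)
  expect_equal(nrow(x), 12)

  # zero-denominator sample is dropped with a warning
  d$ratios$cd4_cd8[3] <- NA
  expect_warning(x2 <- build_composition_features(d), "dropped")
  expect_equal(nrow(x2), 11)
})

test_that("elastic net separates a clean feature and is deterministic", {
  set.seed(42)
  n <- 60
  labels <- rep(0:1, each = n / 2)
  x <- cbind(signal = labels * 2 + rnorm(n, 0, 0.05),
             noise1 = rnorm(n), noise2 = rnorm(n))
  m <- fit_elastic_net(x, labels, seed = 7)
  expect_s3_class(m, "exposure_index_model")
  expect_true("signal" %in% names(m$coefficients))
  sc <- ndmi_score(m, x)
  expect_equal(roc_auc(sc, labels)$auc, 1)

  m2 <- fit_elastic_net(x, labels, seed = 7)
  expect_identical(m$lambda, m2$lambda)
  expect_identical(m$coefficients, m2$coefficients)

  expect_error(fit_elastic_net(x, rep(1, n)), "both classes")
  expect_error(fit_elastic_net(matrix(1, n, 3), labels), "constant")
})

test_that("null-label fits select an empty or near-empty support", {
  set.seed(43)
  n <- 60
  support <- replicate(60, {
    x <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    labels <- sample(rep(0:1, each = n / 2))
    length(fit_elastic_net(x, labels, seed = 1)$coefficients)
  })
  expect_lte(median(support), 2)
})

test_that("index scoring is the stated linear form", {
  m <- structure(list(intercept = 1,
                      coefficients = c(cgs1 = 2),
                      family = "neutrophil_cpg", alpha = 0.5,
                      lambda = 0.1, folds = 10, seed = 1L),
                 class = "exposure_index_model")
  expect_equal(unname(ndmi_score(m, c(cgs1 = 0.5))), 2.0)

  m0 <- m; m0$intercept <- 0; m0$coefficients <- c(cgs1 = 0)
  expect_equal(unname(ndmi_score(m0, c(cgs1 = 0.7))), 0)

  # linearity: score of a mixture equals the mixture of scores
  m2 <- m; m2$coefficients <- c(cgs1 = 2, cgs2 = -3)
  a <- c(cgs1 = 0.1, cgs2 = 0.9)
  b <- c(cgs1 = 0.8, cgs2 = 0.2)
  lam <- 0.3
  expect_equal(unname(ndmi_score(m2, lam * a + (1 - lam) * b)),
               lam * ndmi_score(m2, a) + (1 - lam) * ndmi_score(m2, b))

  expect_error(ndmi_score(m2, c(cgs1 = 0.5)), "cgs2")
})

test_that("exposure probability is the logistic transform", {
  expect_equal(exposure_probability(0), 0.5)
  expect_equal(exposure_probability(50), 1, tolerance = 1e-10)
  expect_equal(exposure_probability(-50), 0, tolerance = 1e-10)
  s <- seq(-5, 5, by = 0.25)
  expect_equal(exposure_probability(s) + exposure_probability(-s),
               rep(1, length(s)))
  expect_true(all(diff(exposure_probability(s)) > 0))
})

test_that("AUC matches the brute-force pairwise oracle", {
  expect_equal(roc_auc(1:4, c(0, 0, 1, 1))$auc, 1)
  # positives {1, 4}, negatives {2, 3}: 2 of 4 pairs concordant
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 0, 0, 1))$auc, 0.5)

  set.seed(44)
  for (i in 1:15) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1) # induce ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_brute_force(scores, labels))
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("label permutation drives AUC to one half on average", {
  set.seed(45)
  scores <- rnorm(40)
  labels <- rep(0:1, each = 20)
  aucs <- replicate(1000, auc_brute_force(scores, sample(labels)))
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
})

test_that("slope-modification test is calibrated and powered", {
  set.seed(46)
  # null: identical slopes => approximately uniform p
  ps <- replicate(500, {
    n <- 60
    labels <- rep(0:1, each = n / 2)
    frac <- runif(n, 0.3, 0.8)
    score <- 2 * frac + rnorm(n, 0, 0.3)
    slope_modification_test(score, frac, labels)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)

  # alternative: exposed slope doubled, low noise
  n <- 80
  labels <- rep(0:1, each = n / 2)
  frac <- runif(n, 0.3, 0.8)
  score <- (2 + 2 * labels) * frac + rnorm(n, 0, 0.1)
  st <- slope_modification_test(score, frac, labels)
  expect_lt(st$p, 0.001)
  expect_gt(st$slope_exposed, st$slope_unexposed)

  expect_error(
    slope_modification_test(1:5, runif(5), c(0, 0, 0, 1, 1)),
    ">= 3 samples")
})

test_that("index models round-trip through JSON", {
  skip_if_not_installed("jsonlite")
  m <- structure(list(intercept = -0.5,
                      coefficients = c(cgs00001 = -2.5, cgs00007 = 1.25),
                      family = "neutrophil_cpg", alpha = 0.5,
                      lambda = 0.037, folds = 10, seed = 3L),
                 class = "exposure_index_model")
  path <- withr::local_tempfile(fileext = ".json")
  write_index_model(m, path)
  m2 <- read_index_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(ndmi_score(m2, c(cgs00001 = 0.4, cgs00007 = 0.6)),
               ndmi_score(m, c(cgs00001 = 0.4, cgs00007 = 0.6)))
})
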