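# Shared statistical kernels: Welch t-test accepting raw data or printed
# summary statistics, uncorrected chi-squared, the stratified
# group-comparison report, and a checked ordinary least squares fit.

#' Welch two-sample t-test from raw data or summary statistics
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and two-sided p. Accepts either two raw-data vectors or the
#' summary-statistic triples (mean, SD, n) of each group, so published
#' summary tables can be checked directly.
#'
#' @param x,y Raw data vectors (each n >= 2), or `NULL` when using the
#'   summary form.
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Summary statistics (used when
#'   `x`/`y` are `NULL`).
#' @return List: `statistic` (t), `df`, `p.value`, `estimate` (mean
#'   difference x minus y).
#' @export
welch_t_test <- function(x = NULL, y = NULL,
                         mean_x = NULL, sd_x = NULL, n_x = NULL,
                         mean_y = NULL, sd_y = NULL, n_y = NULL) {
  if (!is.null(x) || !is.null(y)) {
    if (length(x) < 2 || length(y) < 2) {
      stop("each group needs n >= 2", call. = FALSE)
    }
    mean_x <- mean(x); sd_x <- stats::sd(x); n_x <- length(x)
    mean_y <- mean(y); sd_y <- stats::sd(y); n_y <- length(y)
  }
  if (n_x < 2 || n_y < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd_x < 0 || sd_y < 0) stop("SDs must be >= 0", call. = FALSE)
  se2 <- sd_x^2 / n_x + sd_y^2 / n_y
  if (se2 == 0) { # both variances zero
    t <- if (mean_x == mean_y) 0 else sign(mean_x - mean_y) * Inf
    return(list(statistic = t, df = n_x + n_y - 2,
                p.value = if (t == 0) 1 else 0,
                estimate = mean_x - mean_y))
  }
  t <- (mean_x - mean_y) / sqrt(se2)
  df <- se2^2 / ((sd_x^2 / n_x)^2 / (n_x - 1) +
                   (sd_y^2 / n_y)^2 / (n_y - 1))
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df),
       estimate = mean_x - mean_y)
}

#' Pearson chi-squared test of independence on a contingency table
#'
#' Uncorrected (no Yates continuity correction), matching the convention
#' used for the published cohort tables.
#'
#' @param table r x c matrix of non-negative counts with positive row and
#'   column sums.
#' @return List: `statistic`, `df`, `p.value`, `expected`.
#' @export
chi_squared_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, expected = ct$expected)
}

#' Group-comparison report for a two-group cohort
#'
#' For each continuous variable: per-group mean, median, SD, min, max, n
#' and the Welch t p-value. For each categorical variable: per-group
#' counts and percentages and the uncorrected chi-squared p-value.
#' Variables constant in both groups get `NA` p.
#'
#' @param data Data frame of per-sample variables.
#' @param group Length-N binary grouping vector (two levels present).
#' @param continuous_vars,categorical_vars Column names of `data`.
#' @return List with data frames `continuous` and `categorical`.
#' @export
group_comparison_report <- function(data, group,
                                    continuous_vars = character(),
                                    categorical_vars = character()) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  lv <- levels(g)
  cont <- lapply(continuous_vars, function(v) {
    x <- data[[v]]
    per <- lapply(lv, function(l) {
      xi <- x[g == l]
      data.frame(mean = mean(xi), median = stats::median(xi),
                 sd = stats::sd(xi), min = min(xi), max = max(xi),
                 n = length(xi))
    })
    p <- if (stats::sd(x) == 0) NA_real_ else {
      welch_t_test(x[g == lv[2]], x[g == lv[1]])$p.value
    }
    cbind(variable = v, group1 = per[[1]], group2 = per[[2]],
          p_value = p)
  })
  cat_ <- lapply(categorical_vars, function(v) {
    tab <- table(g, data[[v]])
    p <- if (ncol(tab) < 2) NA_real_ else chi_squared_test(tab)$p.value
    counts <- as.data.frame.matrix(tab)
    data.frame(variable = v,
               level = rep(colnames(tab), each = 1),
               count_group1 = as.integer(tab[1, ]),
               pct_group1 = as.numeric(prop.table(tab, 1)[1, ]) * 100,
               count_group2 = as.integer(tab[2, ]),
               pct_group2 = as.numeric(prop.table(tab, 1)[2, ]) * 100,
               p_value = p, row.names = NULL)
  })
  list(continuous = if (length(cont)) do.call(rbind, cont) else NULL,
       categorical = if (length(cat_)) do.call(rbind, cat_) else NULL)
}

#' Ordinary least squares with analytic covariance
#'
#' OLS fit of `y` on the supplied design columns (no implicit intercept;
#' include a column of ones if wanted). Errors on rank deficiency, naming
#' the collinear columns.
#'
#' @param y Response vector.
#' @param X Design matrix with column names; `nrow(X) > ncol(X)`.
#' @return List: `coefficients` (data frame: term, estimate, se, t, p),
#'   `r2`, `sigma`, `df_residual`, `fitted`, `residuals`.
#' @export
linear_model_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X)) stop("need more rows than columns", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  dfres <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / dfres
  se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * sigma2)
  t <- fit$coefficients / se
  has_int <- any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  list(coefficients = data.frame(term = colnames(X),
                                 estimate = unname(fit$coefficients),
                                 se = unname(se), t = unname(t),
                                 p = unname(2 * stats::pt(-abs(t), dfres)),
                                 row.names = NULL),
       r2 = 1 - sum(res^2) / tss, sigma = sqrt(sigma2),
       df_residual = dfres, fitted = fit$fitted.values, residuals = res)
}

#' Published immune-parameter summary of the glioma flow-cytometry
#' subcohort
#'
#' Bundled summary statistics (mean, median, SD, range, n = 19 per group)
#' of immune parameters for 38 glioma patients stratified by current
#' dexamethasone use, as printed in the source cohort table, together
#' with the categorical gender and tumor-grade tables. These are inputs
#' for reconstructing the printed Welch t and chi-squared p-values.
#'
#' @return List with data frame `continuous` (variable, printed p, and
#'   per-group mean/sd/n) and matrices `gender`, `tumor_grade` (rows =
#'   exposed, unexposed).
#' @export
ips_summary_table <- function() {
  path <- system.file("extdata", "ips_immune_summary.tsv",
                      package = "ndmi", mustWork = TRUE)
  cont <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  list(continuous = cont,
       gender = matrix(c(14, 5, 14, 5), nrow = 2, byrow = TRUE,
                       dimnames = list(c("exposed", "unexposed"),
                                       c("male", "female"))),
       tumor_grade = matrix(c(17, 1, 1, 7, 4, 8), nrow = 2, byrow = TRUE,
                            dimnames = list(c("exposed", "unexposed"),
                                            c("grade4", "grade3", "grade2"))))
}
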