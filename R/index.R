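# Sparse elastic-net exposure indices over CpG betas or leukocyte
# composition features, scored through a logistic link, with ROC
# evaluation and the exposed-vs-unexposed slope-modification test of the
# index on neutrophil fraction.

#' Composition feature table from a deconvolution result
#'
#' Nine candidate features per sample: the six cell-type proportions plus
#' the neutrophil/lymphocyte, CD4/CD8 and lymphocyte/monocyte ratios.
#' Samples with any missing ratio (zero denominator) are dropped with a
#' warning.
#'
#' @param deconv Output of [deconvolve()] (needs `fractions` and
#'   `ratios`).
#' @return N x 9 numeric matrix.
#' @export
build_composition_features <- function(deconv) {
  x <- cbind(deconv$fractions, as.matrix(deconv$ratios))
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) dropped: undefined composition ratio",
            call. = FALSE)
    x <- x[keep, , drop = FALSE]
  }
  x
}

#' Fit a sparse logistic elastic-net exposure index
#'
#' Cross-validated logistic elastic net (glmnet); lambda is chosen at the
#' minimum cross-validated binomial deviance. Features are standardised
#' internally by glmnet; coefficients are returned on the original feature
#' scale, with exact zeros dropped.
#'
#' @param features N x p numeric matrix with column names (CpG ids or
#'   composition feature names).
#' @param labels Length-N 0/1 exposure labels, both classes present.
#' @param alpha Elastic-net mixing parameter in (0, 1] (default 0.5).
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed fixing the fold assignment.
#' @param family Feature family tag stored in the model (free text, e.g.
#'   `"neutrophil_cpg"`, `"non_cell_specific_cpg"`, `"composition"`).
#' @return An `exposure_index_model`: list with `intercept`,
#'   `coefficients` (named, non-zero only), `family`, `alpha`, `lambda`,
#'   `folds`, `seed`.
#' @export
fit_elastic_net <- function(features, labels, alpha = 0.5, folds = 10,
                            seed = 1L, family = "unspecified") {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  if (min(table(labels)) < 2) stop("need >= 2 samples per class",
                                   call. = FALSE)
  sds <- apply(features, 2, stats::sd)
  if (all(sds == 0)) stop("all features are constant", call. = FALSE)
  stopifnot(alpha > 0, alpha <= 1)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(features, labels, family = "binomial",
                          alpha = alpha, nfolds = folds,
                          type.measure = "deviance", standardize = TRUE)
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  coefs <- cf[-1, 1]
  coefs <- coefs[coefs != 0]
  structure(list(intercept = unname(cf[1, 1]), coefficients = coefs,
                 family = family, alpha = alpha,
                 lambda = cv$lambda.min, folds = folds,
                 seed = as.integer(seed)),
            class = "exposure_index_model")
}

#' @export
print.exposure_index_model <- function(x, ...) {
  cat("exposure_index_model [", x$family, "]: ",
      length(x$coefficients), " non-zero coefficients, lambda = ",
      signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

#' Score samples with an exposure index
#'
#' The index score is the linear predictor
#' `beta0 + sum_i beta_i x_i` over the model's retained features. Every
#' model feature must be present in the input; missing features are an
#' error naming the offending probes (no imputation).
#'
#' @param model An `exposure_index_model`.
#' @param features Feature matrix: samples x features with column names,
#'   or a CpG x sample beta matrix (CpG rownames; detected and
#'   transposed), or a single named vector.
#' @return Named numeric vector of scores.
#' @export
ndmi_score <- function(model, features) {
  stopifnot(inherits(model, "exposure_index_model"))
  need <- names(model$coefficients)
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  }
  # accept CpG x sample orientation
  if (!all(need %in% colnames(features)) &&
      all(need %in% rownames(features))) {
    features <- t(features)
  }
  missing <- setdiff(need, colnames(features))
  if (length(missing)) {
    stop("missing model feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  drop(model$intercept +
         features[, need, drop = FALSE] %*% model$coefficients)
}

#' Logistic probability of exposure from an index score
#'
#' `p = 1 / (1 + exp(-score))`: strictly increasing, `p(0) = 0.5`,
#' `p(s) + p(-s) = 1`.
#'
#' @param score Numeric index score(s).
#' @return Probabilities in (0, 1).
#' @export
exposure_probability <- function(score) {
  stopifnot(all(is.finite(score)))
  stats::plogis(score)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC via the rank (Mann-Whitney) formulation with half credit for ties;
#' 95% CI by DeLong's method.
#'
#' @param scores Numeric scores (higher = more exposed-like).
#' @param labels 0/1 labels, both classes present.
#' @return List: `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))
  list(auc = as.numeric(pROC::auc(r)), ci_low = ci[1], ci_high = ci[3],
       n_pos = sum(labels == 1), n_neg = sum(labels == 0))
}

#' Test for exposure modification of the index-on-neutrophil slope
#'
#' Fits `score ~ fraction + label + fraction:label` and reports the
#' interaction coefficient with its two-sided p — the test of equality of
#' slopes between the exposed and unexposed regression lines of index
#' score on neutrophil fraction.
#'
#' @param index_scores Numeric index scores.
#' @param neutrophil_fractions Numeric neutrophil fractions.
#' @param labels 0/1 exposure labels, >= 3 samples per group.
#' @return List: `interaction` (slope difference, exposed minus
#'   unexposed), `se`, `p`, `slope_unexposed`, `slope_exposed`.
#' @export
slope_modification_test <- function(index_scores, neutrophil_fractions,
                                    labels) {
  labels <- as.integer(labels)
  if (min(table(factor(labels, levels = 0:1))) < 3) {
    stop("need >= 3 samples per exposure group", call. = FALSE)
  }
  for (g in 0:1) {
    if (stats::sd(neutrophil_fractions[labels == g]) == 0) {
      stop("neutrophil fraction is constant within group ", g, call. = FALSE)
    }
  }
  fit <- stats::lm(index_scores ~ neutrophil_fractions * labels)
  cf <- summary(fit)$coefficients
  b_frac <- cf["neutrophil_fractions", "Estimate"]
  b_int <- cf["neutrophil_fractions:labels", ]
  list(interaction = unname(b_int["Estimate"]),
       se = unname(b_int["Std. Error"]),
       p = unname(b_int["Pr(>|t|)"]),
       slope_unexposed = unname(b_frac),
       slope_exposed = unname(b_frac + b_int["Estimate"]))
}

#' Write / read an exposure index model as JSON
#'
#' The serialised model includes the probe list so that scoring fails
#' loudly on missing probes.
#'
#' @param model An `exposure_index_model`.
#' @param path File path.
#' @export
write_index_model <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite required to serialise models", call. = FALSE)
  }
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         family = model$family, alpha = model$alpha,
         lambda = model$lambda, folds = model$folds, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index_model
#' @export
read_index_model <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite required to read models", call. = FALSE)
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = x$intercept,
                 coefficients = unlist(x$coefficients),
                 family = x$family, alpha = x$alpha, lambda = x$lambda,
                 folds = x$folds, seed = x$seed),
            class = "exposure_index_model")
}
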