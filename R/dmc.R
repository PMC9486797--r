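# Two-stage cell-specific differential methylation screen: a per-CpG
# exposure EWAS filter (Welch t on beta values with a delta-beta
# threshold), then per-CpG interaction models of methylation on cell
# fractions and exposure-by-fraction terms that localise the exposure
# effect to specific leukocyte types.

#' Epigenome-wide exposure screen on beta values
#'
#' Per-CpG two-group comparison of whole-blood beta values between exposed
#' and unexposed samples (Welch t by default; limma empirical-Bayes
#' moderated t optionally), filtered on nominal significance and absolute
#' delta-beta.
#'
#' @param betas J x N beta matrix (CpG rownames) or a `cohort_dataset`.
#' @param labels Length-N 0/1 exposure labels (ignored when `betas` is a
#'   cohort).
#' @param p_threshold Nominal p-value filter (default 0.05).
#' @param db_threshold Absolute delta-beta filter (default 0.10); set to 0
#'   for the p-only filter.
#' @param moderated Use limma's moderated t statistics (requires limma).
#' @return Data frame per CpG: `cpg_id`, `delta_beta` (exposed minus
#'   unexposed), `p_value`, `passes_filter`. CpGs constant across all
#'   samples get `NA` p and fail the filter.
#' @export
ewas_screen <- function(betas, labels = NULL, p_threshold = 0.05,
                        db_threshold = 0.10, moderated = FALSE) {
  if (inherits(betas, "cohort_dataset")) {
    labels <- betas$labels
    betas <- betas$betas
  }
  labels <- as.integer(labels)
  stopifnot(ncol(betas) == length(labels), all(labels %in% 0:1))
  if (sum(labels == 0) < 2 || sum(labels == 1) < 2) {
    stop("need >= 2 samples per exposure group", call. = FALSE)
  }
  x1 <- betas[, labels == 1, drop = FALSE]
  x0 <- betas[, labels == 0, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  db <- m1 - m0
  if (moderated) {
    if (!requireNamespace("limma", quietly = TRUE)) {
      stop("moderated = TRUE requires the limma package", call. = FALSE)
    }
    fit <- limma::eBayes(limma::lmFit(betas, cbind(1, labels)))
    p <- fit$p.value[, 2]
  } else {
    v1 <- apply(x1, 1, stats::var)
    v0 <- apply(x0, 1, stats::var)
    se2 <- v1 / n1 + v0 / n0
    t <- db / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  const <- apply(betas, 1, function(r) max(r) == min(r))
  p[const] <- NA_real_
  passes <- !is.na(p) & p < p_threshold & abs(db) >= db_threshold
  data.frame(cpg_id = rownames(betas), delta_beta = db, p_value = p,
             passes_filter = passes, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit the cell-fraction interaction model for one CpG
#'
#' Fits the no-intercept linear model
#' `y = sum_k w_k a_k + sum_k (label * w_k) b_k + e`
#' (the fractions sum to one, so an intercept is redundant) and returns,
#' per cell type, the interaction coefficient `b_k`, its standard error,
#' and a two-sided p-value. Also reports a homogeneity F-test comparing
#' the full model against the common-shift reduction
#' `y = sum_k w_k a_k + label d + e`; a small homogeneity p indicates the
#' exposure effect genuinely differs across cell types.
#'
#' @param y Length-N beta vector for one CpG.
#' @param W N x K cell-fraction matrix (rows on the simplex).
#' @param labels Length-N 0/1 exposure labels.
#' @return List with `coefficients` (data frame: cell, a, b, se, p) and
#'   `het_p` (homogeneity F-test p). Constant `y` yields zero coefficients
#'   with `NA` p. Inestimable cells (zero design column) get `NA` rows.
#' @export
fit_interaction_model <- function(y, W, labels) {
  labels <- as.integer(labels)
  N <- length(y); K <- ncol(W)
  stopifnot(nrow(W) == N, length(labels) == N)
  if (all(labels == labels[1])) {
    stop("both exposure groups required: interaction design is empty",
         call. = FALSE)
  }
  if (N <= 2 * K) stop("need N > 2K samples to fit the interaction model",
                       call. = FALSE)
  cells <- colnames(W)
  out <- data.frame(cell = cells, a = NA_real_, b = NA_real_,
                    se = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  if (max(y) == min(y)) {
    out$a <- y[1]; out$b <- 0
    return(list(coefficients = out, het_p = NA_real_))
  }
  X <- cbind(W, W * labels)
  qrx <- qr(X)
  if (qrx$rank < 2 * K) {
    est <- qrx$pivot[seq_len(qrx$rank)] # estimable columns only
    fit <- stats::lm.fit(X[, est, drop = FALSE], y)
    beta <- stats::setNames(rep(NA_real_, 2 * K), colnames(X))
    beta[est] <- fit$coefficients
    rss <- sum(fit$residuals^2)
    dfres <- N - qrx$rank
    XtXi <- chol2inv(chol(crossprod(X[, est, drop = FALSE])))
    se <- stats::setNames(rep(NA_real_, 2 * K), colnames(X))
    se[est] <- sqrt(diag(XtXi) * rss / dfres)
  } else {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    rss <- sum(fit$residuals^2)
    dfres <- N - 2 * K
    se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * rss / dfres)
  }
  out$a <- unname(beta[seq_len(K)])
  out$b <- unname(beta[K + seq_len(K)])
  out$se <- unname(se[K + seq_len(K)])
  out$p <- 2 * stats::pt(-abs(out$b / out$se), dfres)

  # homogeneity: common-shift reduced model
  het_p <- NA_real_
  if (dfres > 0) {
    fitr <- stats::lm.fit(cbind(W, labels), y)
    rssr <- sum(fitr$residuals^2)
    Fst <- ((rssr - rss) / (K - 1)) / (rss / dfres)
    het_p <- stats::pf(Fst, K - 1, dfres, lower.tail = FALSE)
  }
  list(coefficients = out, het_p = het_p)
}

#' Interaction screen over a CpG set
#'
#' Runs [fit_interaction_model()] for each CpG and applies
#' Benjamini-Hochberg adjustment, by default separately within each cell
#' type across the tested CpGs (pooled across cells optionally).
#'
#' @param betas J x N beta matrix or a `cohort_dataset`.
#' @param W N x K fraction matrix (typically deconvolution estimates).
#' @param labels Length-N 0/1 exposure labels.
#' @param cpgs CpG ids to test (default: all rows of `betas`).
#' @param fdr_scope `"per_cell"` (default) or `"pooled"`.
#' @return Data frame, one row per (CpG, cell): `cpg_id`, `cell`, `b`,
#'   `se`, `p`, `fdr`, `het_p`.
#' @export
interaction_screen <- function(betas, W, labels = NULL, cpgs = NULL,
                               fdr_scope = c("per_cell", "pooled")) {
  fdr_scope <- match.arg(fdr_scope)
  if (inherits(betas, "cohort_dataset")) {
    labels <- betas$labels
    betas <- betas$betas
  }
  if (is.null(cpgs)) cpgs <- rownames(betas)
  res <- lapply(cpgs, function(cg) {
    f <- fit_interaction_model(betas[cg, ], W, labels)
    cbind(cpg_id = cg, f$coefficients, het_p = f$het_p)
  })
  res <- do.call(rbind, res)
  if (fdr_scope == "per_cell") {
    res$fdr <- stats::ave(res$p, res$cell, FUN = bh_fdr)
  } else {
    res$fdr <- bh_fdr(res$p)
  }
  res[c("cpg_id", "cell", "b", "se", "p", "fdr", "het_p")]
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`; `NA` propagated.
#' @return Adjusted values, capped at 1.
#' @export
bh_fdr <- function(p_values) {
  if (any(stats::na.omit(p_values) < 0) || any(stats::na.omit(p_values) > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Partition exposure-associated CpGs into cell-specific and
#' non-cell-specific sets
#'
#' CpGs passing the EWAS filter are assigned to cell type `c` when the
#' `c` interaction is FDR-significant *and* (by default) the homogeneity
#' test rejects a common cross-cell shift; a CpG may be assigned to
#' several cells. EWAS-passing CpGs with no such assignment form the
#' non-cell-specific set. The homogeneity filter exists because, with
#' fractions summing to one, a uniform exposure shift in every cell type
#' induces identical interaction coefficients in all cells — such loci are
#' exposure-associated but not cell-specific. Set
#' `homogeneity_filter = FALSE` for the plain FDR-only rule.
#'
#' @param ewas Output of [ewas_screen()].
#' @param interactions Output of [interaction_screen()] computed on the
#'   EWAS-passing CpGs.
#' @param fdr_threshold Interaction FDR threshold (default 0.05).
#' @param homogeneity_filter Require heterogeneity of interaction
#'   coefficients for a cell-specific call (default TRUE).
#' @param het_threshold Homogeneity-test p threshold (default 0.05).
#' @return List with `cell_specific` (named list: cell type -> character
#'   vector of CpG ids) and `non_cell_specific` (character vector).
#' @export
partition_dmcs <- function(ewas, interactions, fdr_threshold = 0.05,
                           homogeneity_filter = TRUE,
                           het_threshold = 0.05) {
  passing <- ewas$cpg_id[ewas$passes_filter]
  ints <- interactions[interactions$cpg_id %in% passing, , drop = FALSE]
  sig <- !is.na(ints$fdr) & ints$fdr <= fdr_threshold
  if (homogeneity_filter) {
    sig <- sig & !is.na(ints$het_p) & ints$het_p <= het_threshold
  }
  cells <- unique(interactions$cell)
  cell_specific <- lapply(stats::setNames(cells, cells), function(ct) {
    unique(ints$cpg_id[sig & ints$cell == ct])
  })
  assigned <- unique(unlist(cell_specific))
  list(cell_specific = cell_specific,
       non_cell_specific = setdiff(passing, assigned))
}
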