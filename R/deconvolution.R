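# Reference-based leukocyte deconvolution: per-sample non-negative least
# squares projection of whole-blood beta values onto cell-type reference
# means, followed by sum-to-one renormalisation, plus the derived immune
# ratios and absolute counts.

#' Estimate leukocyte fractions from whole-blood beta values
#'
#' For each sample solves `min ||y - M w||` subject to `w >= 0` over the
#' CpGs shared between the beta matrix and the reference means, then
#' renormalises `w` to sum to one. An equality-constrained quadratic
#' program (sum-to-one imposed inside the solve) is available as an
#' optional mode.
#'
#' @param betas J x N whole-blood beta matrix with CpG rownames.
#' @param panel_means J x K reference mean matrix (CpG rownames,
#'   cell-type colnames), e.g. `panel_matrix(panel)`.
#' @param method `"nnls"` (non-negative LS then renormalise; default) or
#'   `"qp"` (non-negative LS with sum-to-one enforced via an augmented,
#'   heavily weighted constraint row).
#' @return List with `fractions` (N x K, rows sum to 1), `residual_norm`
#'   (per sample), and `cpgs_used`.
#' @export
estimate_fractions <- function(betas, panel_means,
                               method = c("nnls", "qp")) {
  method <- match.arg(method)
  if (is.null(dim(betas))) betas <- as.matrix(betas)
  shared <- intersect(rownames(betas), rownames(panel_means))
  K <- ncol(panel_means)
  if (length(shared) < K) {
    stop("need at least ", K, " shared CpGs between betas and panel; got ",
         length(shared), call. = FALSE)
  }
  M <- panel_means[shared, , drop = FALSE]
  if (qr(M)$rank < K) {
    stop("reference panel is rank deficient: cell-type profiles are ",
         "collinear over the shared CpGs", call. = FALSE)
  }
  if (kappa(M) > 1e6) {
    warning("ill-conditioned reference panel (kappa > 1e6); fraction ",
            "estimates may be unstable", call. = FALSE)
  }
  Y <- betas[shared, , drop = FALSE]
  n <- ncol(Y)
  W <- matrix(NA_real_, n, K,
              dimnames = list(colnames(Y), colnames(panel_means)))
  rn <- numeric(n)
  if (method == "qp") { # soft equality constraint via augmented row
    lambda <- 1e4
    Ma <- rbind(M, rep(lambda, K))
  }
  for (i in seq_len(n)) {
    if (method == "nnls") {
      fit <- pracma::lsqnonneg(M, Y[, i])
    } else {
      fit <- pracma::lsqnonneg(Ma, c(Y[, i], lambda))
    }
    w <- fit$x
    s <- sum(w)
    if (s <= 0) stop("deconvolution degenerate: all-zero solution for sample ",
                     colnames(Y)[i], call. = FALSE)
    W[i, ] <- w / s
    rn[i] <- sqrt(sum((Y[, i] - M %*% W[i, ])^2))
  }
  list(fractions = W, residual_norm = rn, cpgs_used = shared)
}

#' Derived immune-composition indices
#'
#' Computes the neutrophil/lymphocyte, CD4/CD8, and lymphocyte/monocyte
#' ratios, with lymphocytes = CD4T + CD8T + Bcell + NK. Zero denominators
#' yield `NA` (flagged missing) rather than infinities.
#'
#' @param fractions N x K fraction matrix (or a single named length-K
#'   vector) with the canonical cell-type names.
#' @return Data frame with columns `nlr`, `cd4_cd8`, `lymph_mono`.
#' @export
derived_indices <- function(fractions) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1,
    dimnames = list(NULL, names(fractions)))
  need <- c("CD4T", "CD8T", "Bcell", "NK", "Mono", "Neu")
  if (!all(need %in% colnames(fractions))) {
    stop("fractions must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lymph <- rowSums(fractions[, c("CD4T", "CD8T", "Bcell", "NK"), drop = FALSE])
  safe_ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  data.frame(
    nlr = safe_ratio(fractions[, "Neu"], lymph),
    cd4_cd8 = safe_ratio(fractions[, "CD4T"], fractions[, "CD8T"]),
    lymph_mono = safe_ratio(lymph, fractions[, "Mono"]),
    row.names = rownames(fractions)
  )
}

#' Absolute cell counts from fractions and total white-cell count
#'
#' @param fractions N x K fraction matrix (or named vector).
#' @param wbc Total white-cell count(s) in cells/ul, > 0, length 1 or N.
#' @return Matrix of counts (cells/ul); rows sum to `wbc`.
#' @export
absolute_counts <- function(fractions, wbc) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1,
    dimnames = list(NULL, names(fractions)))
  if (any(!is.finite(wbc)) || any(wbc <= 0)) {
    stop("wbc must be positive", call. = FALSE)
  }
  fractions * wbc
}

#' Full deconvolution report for a cohort
#'
#' Runs [estimate_fractions()], appends the derived ratios, and, when
#' white-cell counts are supplied, the absolute counts.
#'
#' @param betas J x N whole-blood beta matrix.
#' @param panel A [reference_panel()].
#' @param wbc Optional length-N total white-cell counts (cells/ul).
#' @param method Passed to [estimate_fractions()].
#' @return List with `fractions`, `ratios`, `counts` (NULL without wbc),
#'   `residual_norm`.
#' @export
deconvolve <- function(betas, panel, wbc = NULL, method = "nnls") {
  est <- estimate_fractions(betas, panel_matrix(panel, "mean"),
                            method = method)
  counts <- if (!is.null(wbc)) absolute_counts(est$fractions, wbc) else NULL
  list(fractions = est$fractions, ratios = derived_indices(est$fractions),
       counts = counts, residual_norm = est$residual_norm)
}
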