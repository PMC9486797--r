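#' @keywords internal
"_PACKAGE"

# canonical six-cell ordering used throughout
LEUKOCYTE_TYPES <- c("CD4T", "CD8T", "Bcell", "NK", "Mono", "Neu")

#' Construct and validate a cell-type methylation reference panel
#'
#' A reference panel holds, for each CpG and each leukocyte type, the mean
#' and standard deviation of the beta value in purified cells of that type.
#' It is both the generative source for synthetic cell-specific methylomes
#' and the design matrix for reference-based deconvolution.
#'
#' @param panel A data frame in long format with columns `cpg_id`,
#'   `cell_type`, `mean`, `sd`, and optionally `is_index` (logical flag for
#'   the sparse exposure-index CpG subset).
#' @return A validated data frame of class `reference_panel`, with
#'   attributes `cpg_ids` and `cell_types` (ordered).
#' @export
reference_panel <- function(panel) {
  required <- c("cpg_id", "cell_type", "mean", "sd")
  if (!all(required %in% names(panel))) {
    stop("panel needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  cell_types <- unique(as.character(panel$cell_type))
  if (anyDuplicated(cell_types)) stop("duplicate cell types", call. = FALSE)
  # keep canonical ordering when the panel uses the standard six labels
  if (setequal(cell_types, LEUKOCYTE_TYPES)) cell_types <- LEUKOCYTE_TYPES
  cpg_ids <- unique(as.character(panel$cpg_id))
  if (any(!is.finite(panel$mean)) || any(panel$mean <= 0) ||
      any(panel$mean >= 1)) {
    stop("panel means must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(panel$sd)) || any(panel$sd < 0)) {
    stop("panel SDs must be >= 0", call. = FALSE)
  }
  if (nrow(panel) != length(cpg_ids) * length(cell_types) ||
      anyDuplicated(panel[c("cpg_id", "cell_type")])) {
    stop("panel must contain exactly one row per (cpg_id, cell_type)",
         call. = FALSE)
  }
  if (!"is_index" %in% names(panel)) panel$is_index <- FALSE
  structure(as.data.frame(panel),
            class = c("reference_panel", "data.frame"),
            cpg_ids = cpg_ids, cell_types = cell_types)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", length(attr(x, "cpg_ids")), "CpGs x",
      length(attr(x, "cell_types")), "cell types;",
      length(panel_index_cpgs(x)), "index CpGs\n")
  invisible(x)
}

#' CpG ids flagged as the exposure-index subset of a panel
#' @param panel A `reference_panel`.
#' @return Character vector of CpG ids.
#' @export
panel_index_cpgs <- function(panel) {
  unique(as.character(panel$cpg_id[panel$is_index]))
}

#' Panel means as a CpG x cell-type matrix
#' @param panel A `reference_panel`.
#' @param what `"mean"` or `"sd"`.
#' @return J x K numeric matrix with CpG rownames, cell-type colnames.
#' @export
panel_matrix <- function(panel, what = c("mean", "sd")) {
  what <- match.arg(what)
  cpg_ids <- attr(panel, "cpg_ids")
  cell_types <- attr(panel, "cell_types")
  m <- matrix(NA_real_, length(cpg_ids), length(cell_types),
              dimnames = list(cpg_ids, cell_types))
  m[cbind(match(panel$cpg_id, cpg_ids), match(panel$cell_type, cell_types))] <-
    panel[[what]]
  m
}

#' Read / write a reference panel in long delimited-text format
#'
#' Files are tab-separated with columns `cpg_id`, `cell_type`, `mean`,
#' `sd`, and optionally `is_index`; lines starting with `#` are comments.
#'
#' @param path File path.
#' @return [read_reference_panel()] returns a `reference_panel`.
#' @export
read_reference_panel <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  reference_panel(df)
}

#' @rdname read_reference_panel
#' @param panel A `reference_panel` to write.
#' @export
write_reference_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default synthetic six-leukocyte reference panel
#'
#' Deterministically generates a synthetic reference panel emulating the
#' statistical structure of published purified-leukocyte methylation
#' references: a block of cell-discriminating CpGs per cell type
#' (near-unmethylated in one lineage, methylated in the rest, or the
#' reverse), a designated "index" subset of CpGs with intermediate,
#' myeloid-hypomethylated levels (the pattern reported for
#' glucocorticoid-responsive neutrophil loci), and a remainder of
#' non-discriminating background CpGs. Means are jittered per cell and SDs
#' drawn uniformly on a per-block scale, all from a fixed internal seed, so
#' every call returns the same panel.
#'
#' This panel is synthetic: probe ids use a `cgs` prefix and do not
#' correspond to real array probes.
#'
#' @param n_cpgs Total number of CpGs (default 500).
#' @param n_index Size of the designated index subset (default 28).
#' @param n_discriminating Cell-discriminating CpGs per cell type
#'   (default 40).
#' @param seed Integer seed fixing the panel (default 20220920).
#' @return A `reference_panel`.
#' @export
default_panel <- function(n_cpgs = 500, n_index = 28,
                          n_discriminating = 40, seed = 20220920) {
  K <- length(LEUKOCYTE_TYPES)
  stopifnot(n_cpgs >= n_index + K * n_discriminating)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  cpg_ids <- sprintf("cgs%05d", seq_len(n_cpgs))
  means <- matrix(NA_real_, n_cpgs, K, dimnames = list(cpg_ids, LEUKOCYTE_TYPES))
  sds <- matrix(NA_real_, n_cpgs, K, dimnames = list(cpg_ids, LEUKOCYTE_TYPES))

  # index block: intermediate methylation, hypomethylated in myeloid cells
  idx <- seq_len(n_index)
  lymph <- LEUKOCYTE_TYPES %in% c("CD4T", "CD8T", "Bcell", "NK")
  for (j in idx) {
    lo <- stats::runif(1, 0.25, 0.45)  # myeloid level
    hi <- stats::runif(1, 0.60, 0.85)  # lymphoid level
    means[j, ] <- ifelse(lymph, hi, lo) + stats::runif(K, -0.04, 0.04)
    sds[j, ] <- stats::runif(K, 0.02, 0.05)
  }

  # discriminating blocks: one cell type pulled to an extreme
  pos <- n_index
  for (k in seq_len(K)) {
    rows <- pos + seq_len(n_discriminating)
    pos <- pos + n_discriminating
    for (j in rows) {
      if (stats::runif(1) < 0.5) {
        target <- stats::runif(1, 0.03, 0.15); others <- stats::runif(1, 0.70, 0.92)
      } else {
        target <- stats::runif(1, 0.85, 0.97); others <- stats::runif(1, 0.08, 0.30)
      }
      means[j, ] <- others + stats::runif(K, -0.05, 0.05)
      means[j, k] <- target
      sds[j, ] <- stats::runif(K, 0.01, 0.04)
    }
  }

  # background: shared level with mild cell-type jitter
  rows <- (pos + 1):n_cpgs
  for (j in rows) {
    base <- stats::runif(1, 0.10, 0.90)
    means[j, ] <- base + stats::runif(K, -0.06, 0.06)
    sds[j, ] <- stats::runif(K, 0.02, 0.08)
  }

  means[] <- pmin(pmax(means, 0.02), 0.98)
  # keep all (mean, sd) pairs feasible for a Beta law
  sds[] <- pmin(sds, 0.9 * sqrt(means * (1 - means)))

  long <- data.frame(
    cpg_id = rep(cpg_ids, K),
    cell_type = rep(LEUKOCYTE_TYPES, each = n_cpgs),
    mean = as.vector(means),
    sd = as.vector(sds),
    is_index = rep(cpg_ids %in% cpg_ids[idx], K),
    stringsAsFactors = FALSE
  )
  reference_panel(long)
}
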