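# Synthetic whole-blood cohort generation: cell-specific methylomes from a
# reference panel, Dirichlet cell fractions, exposure effects injected into
# designated cell types, and fraction-weighted mixing into whole blood.

#' Sample a Dirichlet vector matrix (internal)
#' @noRd
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Mean cell-fraction vector with a target neutrophil level
#'
#' Non-neutrophil cells keep a fixed reference composition (CD4T .14,
#' CD8T .08, B .04, NK .04, Mono .10, relative) rescaled to fill the
#' non-neutrophil mass `1 - neu`.
#'
#' @param neu Target mean neutrophil fraction in (0, 1).
#' @return Named length-6 simplex vector in canonical cell order.
#' @export
mean_fractions <- function(neu = 0.6) {
  stopifnot(neu > 0, neu < 1)
  rel <- c(CD4T = 0.14, CD8T = 0.08, Bcell = 0.04, NK = 0.04, Mono = 0.10)
  out <- c(rel / sum(rel) * (1 - neu), Neu = neu)
  out[LEUKOCYTE_TYPES]
}

#' Sample per-subject cell fraction vectors from a Dirichlet law
#'
#' Draws from Dirichlet(alpha0 * mean_fractions). The total concentration
#' `alpha0` controls between-sample variability of the cellular landscape:
#' larger values give less variability.
#'
#' @param alpha0 Total concentration parameter, > 0 (study values 18, 73,
#'   127).
#' @param mean_fractions Length-K simplex vector of mean fractions, all
#'   entries > 0.
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @return n x K matrix; rows sum to 1.
#' @export
sample_cell_fractions <- function(alpha0, mean_fractions, n, seed = NULL) {
  stopifnot(alpha0 > 0, n >= 1)
  if (any(mean_fractions <= 0)) {
    stop("mean fractions must all be positive", call. = FALSE)
  }
  if (abs(sum(mean_fractions) - 1) > 1e-8) {
    stop("mean fractions must sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  w <- rdirichlet(n, alpha0 * mean_fractions)
  colnames(w) <- names(mean_fractions)
  w
}

#' Sample cell-specific methylomes from a reference panel
#'
#' Each subject's (CpG, cell type) beta value is drawn independently from
#' the Beta distribution whose shapes are the method-of-moments fit to the
#' panel mean/SD for that cell. Panel entries with SD below `sd_floor` are
#' treated as degenerate and return the mean exactly.
#'
#' @param panel A [reference_panel()].
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @param sd_floor SD below which the distribution is treated as a point
#'   mass at the mean (default 1e-8).
#' @return List of n J x K matrices (CpG rownames, cell-type colnames).
#' @export
sample_cell_methylomes <- function(panel, n, seed = NULL, sd_floor = 1e-8) {
  stopifnot(inherits(panel, "reference_panel"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  M <- panel_matrix(panel, "mean")
  S <- panel_matrix(panel, "sd")
  draw_methylome_set(M, S, n, sd_floor)
}

# vectorised engine shared by sample_cell_methylomes and generate_cohort:
# draws n J x K methylomes for one mean/SD matrix pair
#' @noRd
draw_methylome_set <- function(M, S, n, sd_floor = 1e-8) {
  J <- nrow(M); K <- ncol(M)
  degen <- S < sd_floor
  a <- matrix(NA_real_, J, K); b <- matrix(NA_real_, J, K)
  if (any(!degen)) {
    sh <- moments_to_beta_shapes(M[!degen], S[!degen])
    a[!degen] <- sh$a; b[!degen] <- sh$b
  }
  lapply(seq_len(n), function(i) {
    x <- M # degenerate entries keep the mean
    x[!degen] <- stats::rbeta(sum(!degen), a[!degen], b[!degen])
    dimnames(x) <- dimnames(M)
    x
  })
}

#' Inject an exposure effect into a sampled cell methylome
#'
#' Additive per-CpG shift of designated cell-type columns, clipped to
#' `[eps, 1 - eps]`. This is the post-hoc injection mode; cohort generation
#' defaults to shifting the Beta mean before shape conversion instead (see
#' [generate_cohort()]).
#'
#' @param methylome J x K beta matrix with CpG rownames and cell-type
#'   colnames.
#' @param target_cells Character vector of cell-type labels to shift.
#' @param delta Numeric shift, either length 1, length J, or named by CpG
#'   id (unnamed CpGs get 0).
#' @param eps Clipping floor/ceiling margin (default 0.001).
#' @return The shifted methylome.
#' @export
inject_exposure_effect <- function(methylome, target_cells, delta,
                                   eps = 0.001) {
  if (!all(target_cells %in% colnames(methylome))) {
    stop("unknown cell label(s): ",
         paste(setdiff(target_cells, colnames(methylome)), collapse = ", "),
         call. = FALSE)
  }
  d <- expand_delta(delta, rownames(methylome))
  for (ct in target_cells) {
    methylome[, ct] <- pmin(pmax(methylome[, ct] + d, eps), 1 - eps)
  }
  methylome
}

# delta -> length-J vector aligned to cpg_ids (names resolve; scalar recycles)
#' @noRd
expand_delta <- function(delta, cpg_ids) {
  if (!is.null(names(delta))) {
    unknown <- setdiff(names(delta), cpg_ids)
    if (length(unknown)) {
      stop("effect names not in panel: ", paste(utils::head(unknown, 3),
           collapse = ", "), call. = FALSE)
    }
    d <- stats::setNames(rep(0, length(cpg_ids)), cpg_ids)
    d[names(delta)] <- delta
    unname(d)
  } else if (length(delta) == 1) {
    rep(delta, length(cpg_ids))
  } else {
    stopifnot(length(delta) == length(cpg_ids))
    delta
  }
}

#' Mix a cell-specific methylome into a whole-blood profile
#'
#' The whole-blood beta vector is the fraction-weighted mixture
#' `Y = X %*% w` of the subject's cell-specific beta matrix.
#'
#' @param methylome J x K beta matrix.
#' @param w Length-K fraction vector (simplex).
#' @return Length-J named beta vector.
#' @export
mix_whole_blood <- function(methylome, w) {
  if (ncol(methylome) != length(w)) {
    stop("dimension mismatch: ", ncol(methylome), " cell columns vs ",
         length(w), " fractions", call. = FALSE)
  }
  drop(methylome %*% w)
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n0,n1 Unexposed / exposed group sizes (>= 2).
#' @param alpha0 Dirichlet total concentration (> 0; study values 18, 73,
#'   127).
#' @param neutrophil_mean_fraction Target mean neutrophil fraction.
#' @param effect Exposure effect: either a named numeric vector of per-CpG
#'   deltas applied to `target_cells`, or a data frame with columns
#'   `cpg_id`, `cell_type` (a cell label or `"all"`), `delta`. `NULL` draws
#'   the default hypomethylation effect, deltas uniform on
#'   `[-0.15, -0.05]`, over the panel's index CpGs in neutrophils.
#' @param target_cells Cells receiving `effect` when it is a vector
#'   (default `"Neu"`).
#' @param effect_mode `"mean_shift"` (shift the Beta mean before shape
#'   conversion; default) or `"additive"` (post-hoc shift with clipping).
#' @param wbc Logical; simulate total white-cell counts (cells/ul)?
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n0, n1, alpha0 = 18,
                              neutrophil_mean_fraction = 0.6,
                              effect = NULL, target_cells = "Neu",
                              effect_mode = c("mean_shift", "additive"),
                              wbc = FALSE, seed = 1L) {
  stopifnot(n0 >= 2, n1 >= 2, alpha0 > 0,
            neutrophil_mean_fraction > 0, neutrophil_mean_fraction < 1)
  effect_mode <- match.arg(effect_mode)
  if (!is.null(effect) && !is.data.frame(effect) &&
      any(abs(effect) > 1)) {
    stop("effect deltas must have |delta| <= 1", call. = FALSE)
  }
  structure(list(n0 = n0, n1 = n1, alpha0 = alpha0,
                 neutrophil_mean_fraction = neutrophil_mean_fraction,
                 effect = effect, target_cells = target_cells,
                 effect_mode = effect_mode, wbc = wbc,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# canonicalise config$effect into data.frame(cpg_id, cell_type, delta);
# draws the default neutrophil hypomethylation effect when NULL
#' @noRd
resolve_effect <- function(config, panel) {
  eff <- config$effect
  if (is.null(eff)) {
    idx <- panel_index_cpgs(panel)
    if (!length(idx)) stop("panel has no index CpGs for the default effect",
                           call. = FALSE)
    delta <- stats::runif(length(idx), -0.15, -0.05)
    return(data.frame(cpg_id = idx, cell_type = "Neu", delta = delta,
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(eff)) {
    stopifnot(all(c("cpg_id", "cell_type", "delta") %in% names(eff)))
    return(eff)
  }
  if (is.null(names(eff))) stop("vector effects must be named by cpg_id",
                                call. = FALSE)
  do.call(rbind, lapply(config$target_cells, function(ct) {
    data.frame(cpg_id = names(eff), cell_type = ct, delta = unname(eff),
               stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic whole-blood methylation cohort
#'
#' Produces whole-blood beta values for `n0` unexposed and `n1` exposed
#' subjects: cell-specific methylomes sampled from the panel's Beta laws,
#' an exposure effect applied to designated CpG/cell combinations in
#' exposed subjects only, Dirichlet cell fractions, and fraction-weighted
#' mixing. In the default `"mean_shift"` mode the effect shifts the Beta
#' mean (clipped to `[0.001, 0.999]`) before moment matching, so samples
#' stay in `[0, 1]` naturally; `"additive"` shifts sampled values and
#' clips.
#'
#' @param config A [simulation_config()].
#' @param panel A [reference_panel()] (default [default_panel()]).
#' @return A list of class `cohort_dataset`: `betas` (J x N), `labels`
#'   (0/1, length N), `true_fractions` (N x K), `wbc` (or NULL), `effects`
#'   (resolved effect table), `seed`, `config`.
#' @export
generate_cohort <- function(config, panel = default_panel()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(panel, "reference_panel"))
  set.seed(config$seed)
  cells <- attr(panel, "cell_types")
  cpgs <- attr(panel, "cpg_ids")
  n0 <- config$n0; n1 <- config$n1; N <- n0 + n1
  effects <- resolve_effect(config, panel)
  bad <- setdiff(effects$cell_type, c(cells, "all"))
  if (length(bad)) stop("unknown cell label(s) in effect: ",
                        paste(bad, collapse = ", "), call. = FALSE)

  M <- panel_matrix(panel, "mean")
  S <- panel_matrix(panel, "sd")

  # exposed-group mean/SD matrices under the mean-shift mode
  M1 <- M
  D <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  for (r in seq_len(nrow(effects))) {
    ct <- effects$cell_type[r]
    cols <- if (identical(ct, "all")) cells else ct
    D[effects$cpg_id[r], cols] <- D[effects$cpg_id[r], cols] +
      effects$delta[r]
  }
  if (config$effect_mode == "mean_shift") {
    M1 <- pmin(pmax(M + D, 0.001), 0.999)
  }

  X0 <- draw_methylome_set(M, S, n0)
  X1 <- draw_methylome_set(if (config$effect_mode == "mean_shift") M1 else M,
                           S, n1)
  if (config$effect_mode == "additive") {
    X1 <- lapply(X1, function(x) pmin(pmax(x + D, 0.001), 0.999))
  }

  mf <- mean_fractions(config$neutrophil_mean_fraction)
  if (!identical(names(mf), cells)) mf <- stats::setNames(rep(1 / length(cells), length(cells)), cells)
  W <- rdirichlet(N, config$alpha0 * mf)
  colnames(W) <- cells

  betas <- matrix(NA_real_, length(cpgs), N,
                  dimnames = list(cpgs, c(sprintf("ctrl%03d", seq_len(n0)),
                                          sprintf("case%03d", seq_len(n1)))))
  for (j in seq_len(n0)) betas[, j] <- mix_whole_blood(X0[[j]], W[j, ])
  for (k in seq_len(n1)) betas[, n0 + k] <- mix_whole_blood(X1[[k]], W[n0 + k, ])
  rownames(W) <- colnames(betas)

  wbc <- if (isTRUE(config$wbc)) {
    stats::rlnorm(N, meanlog = log(7000), sdlog = 0.3)
  } else NULL

  structure(list(betas = betas,
                 labels = stats::setNames(rep(0:1, c(n0, n1)), colnames(betas)),
                 true_fractions = W, wbc = wbc, effects = effects,
                 seed = config$seed, config = config),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:", nrow(x$betas), "CpGs x", ncol(x$betas),
      "samples (", sum(x$labels == 0), "unexposed /", sum(x$labels == 1),
      "exposed ), seed", x$seed, "\n")
  invisible(x)
}

#' Write / read a cohort as delimited text plus a sample sheet
#'
#' `write_cohort()` writes `betas.tsv` (rows = CpGs, columns = samples),
#' `samples.tsv` (sample_id, exposed, wbc, true_frac_* columns), and, when
#' jsonlite is available, a `config.json` seed/provenance sidecar into
#' `dir`.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(cpg_id = rownames(cohort$betas),
                                cohort$betas, check.names = FALSE),
                     file.path(dir, "betas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ss <- data.frame(sample_id = colnames(cohort$betas),
                   exposed = unname(cohort$labels))
  if (!is.null(cohort$wbc)) ss$wbc <- cohort$wbc
  tf <- cohort$true_fractions
  colnames(tf) <- paste0("true_frac_", colnames(tf))
  ss <- cbind(ss, as.data.frame(tf, row.names = NULL))
  utils::write.table(ss, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- cohort$config
    cfg$effect <- NULL # resolved table written instead
    jsonlite::write_json(list(seed = cohort$seed, config = unclass(cfg),
                              effects = cohort$effects),
                         file.path(dir, "config.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param dir Directory written by `write_cohort()`.
#' @export
read_cohort_betas <- function(dir) {
  df <- utils::read.delim(file.path(dir, "betas.tsv"), check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cpg_id
  m
}
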