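# Statistical power of an index-score exposure test as a function of mean
# neutrophil fraction, sample size, and Dirichlet concentration: per
# replicate, generate a small synthetic cohort over the index CpGs, score
# every sample with a fixed coefficient vector, and run a two-sample
# Welch t-test on the scores.

#' Fixed index coefficients used inside the power loop
#'
#' A pre-specified sparse linear score over the panel's index CpGs:
#' negative weights (hypomethylation in exposed subjects raises the
#' score), intercept 0. The power of the score t-test is invariant to
#' rescaling the weights, so only their sign pattern matters here; any
#' trained [fit_elastic_net()] model can be substituted.
#'
#' @param panel A [reference_panel()] with flagged index CpGs.
#' @param weight Common coefficient value (default -5).
#' @return An `exposure_index_model` with fixed coefficients.
#' @export
fixed_index_model <- function(panel, weight = -5) {
  idx <- panel_index_cpgs(panel)
  if (!length(idx)) stop("panel has no index CpGs", call. = FALSE)
  structure(list(intercept = 0,
                 coefficients = stats::setNames(rep(weight, length(idx)), idx),
                 family = "neutrophil_cpg", alpha = NA_real_,
                 lambda = NA_real_, folds = NA_integer_, seed = NA_integer_),
            class = "exposure_index_model")
}

#' Power of the exposure test at one design point
#'
#' Repeatedly generates a cohort of `N` samples (equal split, `N/2`
#' exposed) at the given mean neutrophil fraction and Dirichlet
#' concentration, scores each sample with `index_model` on the whole-blood
#' betas of the index CpGs, tests for a mean score difference with a
#' Welch t-test at level `type1_rate`, and returns the rejection
#' proportion.
#'
#' @param fraction Mean neutrophil fraction in (0, 1).
#' @param N Total sample size (even; split N/2 exposed, N/2 unexposed).
#' @param alpha0 Dirichlet total concentration.
#' @param effect Per-CpG neutrophil methylation shift: a single delta
#'   applied to all index CpGs, or a named vector over index CpG ids.
#'   Use 0 for the null (type-I error) configuration.
#' @param reps Number of simulation replicates.
#' @param seed Integer seed.
#' @param panel Reference panel (default: index-CpG subset of
#'   [default_panel()]).
#' @param index_model Scoring model (default [fixed_index_model()]).
#' @param type1_rate Test level (default 0.05).
#' @return List: `power`, `rejections`, `reps`.
#' @export
run_power_cell <- function(fraction, N, alpha0, effect, reps, seed,
                           panel = NULL, index_model = NULL,
                           type1_rate = 0.05) {
  stopifnot(N %% 2 == 0, N >= 4, reps >= 1,
            fraction > 0, fraction < 1)
  if (is.null(panel)) panel <- index_subpanel()
  if (is.null(index_model)) index_model <- fixed_index_model(panel)
  idx <- panel_index_cpgs(panel)
  if (length(effect) == 1 && is.null(names(effect))) {
    effect <- stats::setNames(rep(effect, length(idx)), idx)
  }
  n <- N / 2
  rejections <- 0L
  for (r in seq_len(reps)) {
    cfg <- simulation_config(
      n0 = n, n1 = n, alpha0 = alpha0,
      neutrophil_mean_fraction = fraction,
      effect = effect, target_cells = "Neu",
      seed = derive_seed(seed, r))
    co <- generate_cohort(cfg, panel)
    sc <- ndmi_score(index_model, co$betas)
    wt <- welch_t_test(sc[co$labels == 1], sc[co$labels == 0])
    if (wt$p.value < type1_rate) rejections <- rejections + 1L
  }
  list(power = rejections / reps, rejections = rejections, reps = reps)
}

# index-CpG-only view of the default panel (cached per session)
#' @noRd
index_subpanel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- default_panel()
      cache <<- reference_panel(as.data.frame(p)[p$is_index, ])
    }
    cache
  }
})

# deterministic sub-seed derivation, kept below 2^31
#' @noRd
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 7919) %%
               2147483647)
}

#' Configuration for a power grid sweep
#'
#' @param neutrophil_fractions Grid of mean neutrophil fractions
#'   (default `seq(0.20, 0.80, by = 0.05)`).
#' @param sample_sizes Total sample sizes (default `c(20, 40, 60, 80)`).
#' @param alpha0_values Dirichlet concentrations (default
#'   `c(18, 73, 127)`).
#' @param reps Replicates per grid cell (default 1000).
#' @param type1_rate Test level (default 0.05).
#' @param effect Per-CpG neutrophil shift passed to [run_power_cell()]
#'   (default -0.10 at every index CpG).
#' @param seed Master seed; per-cell seeds are derived deterministically.
#' @return A list of class `power_grid_config`.
#' @export
power_grid_config <- function(neutrophil_fractions = seq(0.20, 0.80, 0.05),
                              sample_sizes = c(20, 40, 60, 80),
                              alpha0_values = c(18, 73, 127),
                              reps = 1000, type1_rate = 0.05,
                              effect = -0.10, seed = 1L) {
  stopifnot(all(neutrophil_fractions > 0), all(neutrophil_fractions < 1),
            reps >= 1, type1_rate > 0, type1_rate < 1)
  structure(list(neutrophil_fractions = neutrophil_fractions,
                 sample_sizes = sample_sizes,
                 alpha0_values = alpha0_values, reps = reps,
                 type1_rate = type1_rate, effect = effect,
                 seed = as.integer(seed)),
            class = "power_grid_config")
}

#' Run the full factorial power sweep
#'
#' @param config A [power_grid_config()].
#' @param panel,index_model Passed to [run_power_cell()].
#' @return Long-format data frame: `neu_fraction`, `N`, `alpha0`, `reps`,
#'   `rejections`, `power`.
#' @export
run_power_grid <- function(config, panel = NULL, index_model = NULL) {
  stopifnot(inherits(config, "power_grid_config"))
  grid <- expand.grid(neu_fraction = config$neutrophil_fractions,
                      N = config$sample_sizes,
                      alpha0 = config$alpha0_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- run_power_cell(grid$neu_fraction[i], grid$N[i],
                           grid$alpha0[i], config$effect, config$reps,
                           seed = derive_seed(config$seed, i),
                           panel = panel, index_model = index_model,
                           type1_rate = config$type1_rate)
    cbind(grid[i, , drop = FALSE],
          reps = cell$reps, rejections = cell$rejections,
          power = cell$power)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
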