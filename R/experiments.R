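# Pre-registered simulation experiments used by the analysis drivers, the
# test suite, and the acceptance script. Each experiment fixes its own
# study conditions (cohort sizes, effect magnitudes, replicate counts) and
# takes only a seed, so every caller runs the identical design.

#' Reconstruct the published immune-parameter comparison table
#'
#' Recomputes the Welch t p-value for every continuous variable of the
#' bundled summary table from its printed per-group mean/SD/n, and the
#' uncorrected chi-squared p-values for the gender and tumor-grade tables.
#'
#' @return List: `continuous` (data frame with `computed_p` alongside the
#'   printed p), `p_gender`, `p_tumor_grade`.
#' @export
reconstruct_summary_table <- function() {
  tab <- ips_summary_table()
  cont <- tab$continuous
  cont$computed_p <- vapply(seq_len(nrow(cont)), function(i) {
    welch_t_test(mean_x = cont$mean_exposed[i], sd_x = cont$sd_exposed[i],
                 n_x = cont$n_exposed[i],
                 mean_y = cont$mean_unexposed[i],
                 sd_y = cont$sd_unexposed[i],
                 n_y = cont$n_unexposed[i])$p.value
  }, numeric(1))
  list(continuous = cont,
       p_gender = chi_squared_test(tab$gender)$p.value,
       p_tumor_grade = chi_squared_test(tab$tumor_grade)$p.value)
}

#' Deconvolution recovery benchmark
#'
#' Two conditions on the default panel: (i) noiseless forward-mixed
#' samples (whole blood constructed exactly as panel-mean times fraction),
#' where recovery should be essentially exact, and (ii) a beta-sampling
#' cohort from [generate_cohort()] with no exposure effect, where recovery
#' is limited by biological sampling noise.
#'
#' @param n Samples per condition (default 40).
#' @param seed Integer seed.
#' @param panel Reference panel (default [default_panel()]).
#' @return List: `noiseless_max_error`, `noisy_mae`, `n`, `n_cpgs`.
#' @export
benchmark_deconvolution <- function(n = 40, seed = 1L,
                                    panel = default_panel()) {
  M <- panel_matrix(panel)
  W <- sample_cell_fractions(18, mean_fractions(0.6), n, seed = seed)
  Y <- M %*% t(W)
  exact <- estimate_fractions(Y, M)
  co <- generate_cohort(simulation_config(
    ceiling(n / 2), floor(n / 2),
    effect = stats::setNames(0, attr(panel, "cpg_ids")[1]),
    seed = derive_seed(seed, 2)), panel)
  est <- estimate_fractions(co$betas, M)
  list(noiseless_max_error = max(abs(exact$fractions - W)),
       noisy_mae = mean(abs(est$fractions - co$true_fractions)),
       n = n, n_cpgs = nrow(M))
}

#' Cell-specific differential-methylation recovery experiment
#'
#' Replicated two-class cohorts at the discovery-cohort scale (76
#' unexposed, 59 exposed) carrying 50 neutrophil-specific loci (cell-level
#' hypomethylation, deltas uniform on [-0.30, -0.20]) and 50
#' non-cell-specific loci (uniform shift in all six cell types, deltas on
#' [-0.15, -0.11]) among 400 null background CpGs. Each replicate runs the
#' EWAS filter, the interaction screen on passing loci against the true
#' cell fractions, and the partition; recovery is the fraction of
#' neutrophil-effect loci assigned to the neutrophil set and of global
#' loci routed to the non-cell-specific set.
#'
#' Cell-level effect magnitudes are chosen so the *observed* whole-blood
#' delta-betas land on the >= 0.10 scale of the screening filter
#' (neutrophil loci: fraction x delta ~ 0.12-0.18). Effects are planted
#' only on loci with intermediate-or-higher methylation in every cell
#' type (all panel means >= 0.35), since a 0.2-0.3 hypomethylation shift
#' is not expressible at an already-unmethylated locus — mirroring the
#' intermediate-methylation character of glucocorticoid-responsive
#' neutrophil loci.
#'
#' @param reps Number of replicate cohorts (default 20).
#' @param seed Integer seed.
#' @param panel Reference panel (default [default_panel()]).
#' @return List: `per_rep` data frame (`neu_recovered`, `glob_routed`,
#'   out of 50 each), `neu_recovery` and `glob_noncellspecific`
#'   (aggregate proportions), `reps`.
#' @export
dmc_recovery_experiment <- function(reps = 20, seed = 1L,
                                    panel = default_panel()) {
  cpgs <- attr(panel, "cpg_ids")
  M <- panel_matrix(panel)
  eligible <- cpgs[apply(M, 1, min) >= 0.35]
  free <- setdiff(eligible, panel_index_cpgs(panel))
  if (length(free) < 100) stop("panel has too few effect-eligible CpGs",
                               call. = FALSE)
  set.seed(derive_seed(seed, 1))
  pool <- sample(free, 100)
  neu_cpgs <- pool[1:50]
  glob_cpgs <- pool[51:100]
  per <- lapply(seq_len(reps), function(r) {
    s <- derive_seed(seed, 100 + r)
    set.seed(s)
    eff <- rbind(
      data.frame(cpg_id = neu_cpgs, cell_type = "Neu",
                 delta = stats::runif(50, -0.30, -0.20)),
      data.frame(cpg_id = glob_cpgs, cell_type = "all",
                 delta = stats::runif(50, -0.15, -0.11)))
    co <- suppressWarnings(generate_cohort(
      simulation_config(76, 59, effect = eff, seed = s), panel))
    ew <- ewas_screen(co)
    ints <- interaction_screen(co, co$true_fractions,
                               cpgs = ew$cpg_id[ew$passes_filter])
    part <- partition_dmcs(ew, ints)
    data.frame(
      neu_recovered = length(intersect(part$cell_specific$Neu, neu_cpgs)),
      glob_routed = length(intersect(part$non_cell_specific, glob_cpgs)))
  })
  per <- do.call(rbind, per)
  list(per_rep = per,
       neu_recovery = sum(per$neu_recovered) / (50 * reps),
       glob_noncellspecific = sum(per$glob_routed) / (50 * reps),
       reps = reps)
}

#' Null calibration of the cell-specific screen
#'
#' Effect-free cohorts at discovery scale; the interaction screen is run
#' on all loci passing the nominal-p EWAS filter (delta-beta filter
#' disabled, otherwise almost nothing passes under the null) and the
#' proportion of those loci called cell-specific is returned. Under
#' correct FDR control this false-call rate stays at or below the FDR
#' threshold.
#'
#' @param reps Number of null cohorts (default 10).
#' @param seed Integer seed.
#' @param panel Reference panel.
#' @return List: `false_call_rate`, `tested` (total loci screened),
#'   `reps`.
#' @export
dmc_null_experiment <- function(reps = 10, seed = 1L,
                                panel = default_panel()) {
  cpgs <- attr(panel, "cpg_ids")
  calls <- 0L; tested <- 0L
  for (r in seq_len(reps)) {
    co <- generate_cohort(simulation_config(
      76, 59, effect = stats::setNames(0, cpgs[1]),
      seed = derive_seed(seed, 200 + r)), panel)
    ew <- ewas_screen(co, db_threshold = 0)
    pass <- ew$cpg_id[ew$passes_filter]
    if (!length(pass)) next
    ints <- interaction_screen(co, co$true_fractions, cpgs = pass)
    part <- partition_dmcs(ew, ints)
    calls <- calls + length(unique(unlist(part$cell_specific)))
    tested <- tested + length(pass)
  }
  list(false_call_rate = if (tested) calls / tested else 0,
       tested = tested, reps = reps)
}

#' Held-out comparison of the neutrophil-CpG and composition indices
#'
#' Replicate cohorts (70 + 70) carry the default neutrophil
#' hypomethylation effect on the panel's index CpGs. Each replicate:
#' deconvolve all samples, split half/half stratified by exposure, train
#' an elastic-net index on (i) the index-CpG betas and (ii) the nine
#' composition features, and score the held-out half. Under this
#' generator exposure perturbs methylation but not cell composition, so
#' the composition index carries no signal beyond deconvolution noise —
#' the expected ordering is methylation index above composition index.
#'
#' @param reps Replicate cohorts (default 20).
#' @param seed Integer seed.
#' @param panel Reference panel.
#' @return List: `per_rep` (data frame `auc_neu`, `auc_comp`),
#'   `mean_auc_neu`, `mean_auc_comp`, `reps`.
#' @export
index_benchmark_experiment <- function(reps = 20, seed = 1L,
                                       panel = default_panel()) {
  idx <- panel_index_cpgs(panel)
  M <- panel_matrix(panel)
  per <- lapply(seq_len(reps), function(r) {
    s <- derive_seed(seed, 300 + r)
    co <- generate_cohort(simulation_config(70, 70, seed = s), panel)
    W <- estimate_fractions(co$betas, M)$fractions
    comp <- suppressWarnings(build_composition_features(
      list(fractions = W, ratios = derived_indices(W))))
    ids <- colnames(co$betas)
    train <- ids[c(1:35, 71:105)]
    test <- setdiff(ids, train)
    m_neu <- fit_elastic_net(t(co$betas[idx, train]), co$labels[train],
                             seed = s, family = "neutrophil_cpg")
    auc_neu <- roc_auc(ndmi_score(m_neu, t(co$betas[idx, test])),
                       co$labels[test])$auc
    ctr <- intersect(train, rownames(comp))
    cte <- intersect(test, rownames(comp))
    m_comp <- fit_elastic_net(comp[ctr, ], co$labels[ctr], seed = s,
                              family = "composition")
    auc_comp <- roc_auc(ndmi_score(m_comp, comp[cte, ]),
                        co$labels[cte])$auc
    data.frame(auc_neu = auc_neu, auc_comp = auc_comp)
  })
  per <- do.call(rbind, per)
  list(per_rep = per, mean_auc_neu = mean(per$auc_neu),
       mean_auc_comp = mean(per$auc_comp), reps = reps)
}
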