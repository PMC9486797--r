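#!/usr/bin/env Rscript
# Sweeps the power of the index-score exposure test across mean
# neutrophil fraction, total sample size, and Dirichlet concentration,
# with a fixed -0.10 neutrophil hypomethylation at every index CpG.
# Scaled to 200 replicates per cell on a reduced grid; pass --full for
# the complete 13 x 4 x 3 grid at 1000 replicates.

suppressPackageStartupMessages(library(ndmi))
dir.create("results", showWarnings = FALSE)
full <- any(commandArgs(trailingOnly = TRUE) == "--full")

cfg <- if (full) {
  power_grid_config(reps = 1000, effect = -0.10, seed = 401)
} else {
  power_grid_config(neutrophil_fractions = seq(0.2, 0.8, 0.1),
                    sample_sizes = c(20, 40, 80),
                    alpha0_values = c(18, 127),
                    reps = 200, effect = -0.10, seed = 401)
}
grid <- run_power_grid(cfg)
write.table(grid, "results/power_surface.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("power by neutrophil fraction (rows) and N (columns), alpha0 = 18:\n")
print(xtabs(power ~ neu_fraction + N, grid[grid$alpha0 == 18, ]))
cat("\nalpha0 = 127:\n")
print(xtabs(power ~ neu_fraction + N, grid[grid$alpha0 == 127, ]))
cat("\nPower rises with the neutrophil carrier fraction and with N, and\n")
cat("tighter cell-fraction distributions (higher alpha0) help at low\n")
cat("fractions; below ~20-30% neutrophils detection degrades sharply at\n")
cat("small N.\n")
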