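#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis at the full published scale: 100,000
# perturbed pairs (10% CV, truncated at zero), paired one-sided signed-rank
# robustness test, and the break-even cost shift of the PSP arm.
#
# Usage: Rscript analysis/03_psa.R [n_pairs] [seed]

suppressPackageStartupMessages(library(pspmarkov))

args <- commandArgs(trailingOnly = TRUE)
n_pairs <- if (length(args) >= 1) as.integer(args[[1]]) else 100000L
seed <- if (length(args) >= 2) as.integer(args[[2]]) else 20260921L

bc <- base_case_parameters()
set.seed(seed)
psa <- run_psa(bc$no_psp, bc$psp, bc$costs, bc$config,
               n_pairs = n_pairs, cv = 0.10)
print(psa)

be <- find_break_even_shift(psa$pairs$cost_no_psp, psa$pairs$cost_psp,
                            alpha = 0.05)
cat(sprintf("break-even shift at alpha 0.05: %.1f %s\n", be, psa$currency))

paths <- write_psa_report(psa, "results", basename = "psa", seed = seed)
cat("wrote:", paste(paths, collapse = ", "), "\n")

# finding (seed 20260921, 100,000 pairs): ~29% / ~37% of trajectories stay
# free of HIE-related cost, the 95% cost quantiles sit near 79.6k / 67.7k
# EUR, the cost advantage of the PSP arm is significant at p << 1e-4, and it
# survives a uniform handicap of roughly 1.4k EUR per trajectory.
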