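#!/usr/bin/env Rscript
# Full-scale confined-arena protocol: 50 trials per condition, 250 agents,
# 4e5 steps (about 22 h of model time per trial). This is the overnight
# companion to scripts/acceptance.R -- expect many CPU-hours on one core.
#
# Usage: Rscript scripts/full_experiment.R --seed <int> --out <path> \
#            [--trials N] [--agents N] [--steps N]

suppressPackageStartupMessages(library(wormblob))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, out = "results/full_experiment.json",
            trials = 50L, agents = 250L, steps = 400000L)
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt)) stop("unknown argument: ", args[i])
  opt[[key]] <- if (key == "out") args[i + 1] else as.integer(args[i + 1])
  i <- i + 2
}
dir.create(dirname(opt$out), recursive = TRUE, showWarnings = FALSE)

ex <- run_experiment(conditions = c("oval", "dumbbell", "dumbbell_pegs"),
                     n_trials = opt$trials, base_seed = opt$seed,
                     params = wb_params(), n_agents = opt$agents,
                     n_steps = opt$steps)
print(ex)

med <- vapply(ex$trips, median, numeric(1))
out <- list(
  median_trips_oval = list(value = unname(med[["oval"]]), n = opt$trials),
  median_trips_dumbbell = list(value = unname(med[["dumbbell"]]),
                               n = opt$trials),
  median_trips_dumbbell_pegs = list(value = unname(med[["dumbbell_pegs"]]),
                                    n = opt$trials),
  p_oval_vs_dumbbell = list(
    value = rank_sum_test(ex$trips$oval, ex$trips$dumbbell)$p_value,
    n = opt$trials),
  p_pegs_vs_dumbbell = list(
    value = rank_sum_test(ex$trips$dumbbell_pegs, ex$trips$dumbbell)$p_value,
    n = opt$trials),
  trips = ex$trips
)
jsonlite::write_json(out, opt$out, auto_unbox = TRUE, digits = NA)
cat("wrote", opt$out, "\n")
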