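#!/usr/bin/env Rscript
# Re-runs the training-budget calibration: the smallest step count on the
# rounding lattice (multiples of 500 below 10k, of 5k above) at which every
# seed's frozen greedy policy escapes from the threat cell on the
# condition-1 training map. Tabular and hierarchical Q-learning are
# calibrated with and without practice runs.

suppressPackageStartupMessages(library(subgoalsim))
dir.create("results", showWarnings = FALSE)

cells <- expand.grid(algorithm = c("q", "hss_q", "sarsa", "mb_i"),
                     practice = c(FALSE, TRUE), stringsAsFactors = FALSE)
caps <- c(q = 200000, hss_q = 20000, sarsa = 200000, mb_i = 20000)

rows <- NULL
for (i in seq_len(nrow(cells))) {
  a <- cells$algorithm[i]; pr <- cells$practice[i]
  cal <- calibrate_training_steps(a, practice = pr, n_seeds = 100,
                                  cap = caps[[a]])
  rows <- rbind(rows, data.frame(algorithm = a, practice = pr,
                                 steps = cal$steps))
  cat(sprintf("%-8s %-14s: %s steps\n", a,
              if (pr) "with practice" else "random only",
              format(cal$steps, big.mark = ",")))
}
write.csv(rows, "results/calibration.csv", row.names = FALSE)
cat("\nWrote results/calibration.csv\n")
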