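#!/usr/bin/env Rscript
# Writes the canonical arena maps for the four experimental conditions
# (training and test phases) as plain-text grids with JSON sidecars, and
# summarizes the region partition used by the hierarchical agents.

suppressPackageStartupMessages(library(subgoalsim))

dir.create("results/maps", showWarnings = FALSE, recursive = TRUE)

for (cond in 1:4) for (phase in c("training", "test")) {
  m <- build_condition_map(cond, phase)
  path <- sprintf("results/maps/condition%d_%s.txt", cond, phase)
  write_gridmap(m, path)
  cat(sprintf("condition %d %-8s: %3d accessible cells, %2d one-way blocked transitions%s\n",
              cond, phase, sum(m$accessible), nrow(m$oneway),
              if (is.na(m$shelter)) ", no shelter" else ""))
}

p <- region_partition()
tab <- table(factor(p$assignment[build_condition_map(1, "training")$accessible],
                    levels = 1:10, labels = p$names))
cat("\nRegion partition (10 regions, ", nrow(p$actions),
    " directed region-action pairs):\n", sep = "")
print(tab)
write.csv(data.frame(from = p$names[p$actions[, 1]], to = p$names[p$actions[, 2]]),
          "results/maps/region_actions.csv", row.names = FALSE)
cat("\nMaps written to results/maps/\n")
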