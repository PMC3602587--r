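#!/usr/bin/env Rscript
# Assay-development QC over the simulated campaign: growth-kinetics
# linearity and seeding selection, the nephelometry solubility-limit rule,
# and control statistics (S/N, Z') for every screening condition.

library(effectorscreen)

dir.create("results", showWarnings = FALSE)

growth <- utils::read.csv("simdata/growth.csv")
sel <- assess_growth(growth)
cat("Growth kinetics: selected seeding density",
    format(sel$selected_density, big.mark = ","), "cells/well at a",
    sel$selected_horizon, "h horizon\n")
utils::write.csv(sel$per_density, "results/growth_linearity.csv",
                 row.names = FALSE)

tb <- utils::read.csv("simdata/turbidity.csv")
bl <- utils::read.csv("simdata/turbidity_baseline.csv")
sol <- solubility_limit(tb$conc_uM, tb$turbidity_ntu, bl$turbidity_ntu)
cat(sprintf("Solubility: baseline %.1f NTU, threshold %.1f NTU, limit %s\n",
            sol$baseline_mean, sol$threshold, sol$limit_label))

plates <- read_plate_table("simdata/screen_plates.csv")
conds <- unique(plates[, c("cell_line", "effector_uM")])
for (i in seq_len(nrow(conds))) {
  p <- plates[plates$cell_line == conds$cell_line[i] &
                plates$effector_uM == conds$effector_uM[i], ]
  rep <- qc_report(p)
  cat(sprintf("  %s %3g uM effector: S/N %s, Z' = %.2f (%s)\n",
              conds$cell_line[i], conds$effector_uM[i], rep$s_n$label,
              rep$zprime, rep$band))
}
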