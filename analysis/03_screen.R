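#!/usr/bin/env Rscript
# Primary-screen analysis: percent-inhibition normalization per condition,
# duplicate concordance, dual-condition hit selection on the primary line,
# and cross-line refinement. Compares the recovered hit sets against the
# simulation's planted truth.

library(effectorscreen)

dir.create("results", showWarnings = FALSE)
plates <- read_plate_table("simdata/screen_plates.csv")

# duplicate concordance per condition (the screen ran in duplicate)
for (line in unique(plates$cell_line)) {
  for (eff in unique(plates$effector_uM)) {
    p <- plates[plates$cell_line == line & plates$effector_uM == eff &
                  plates$role == "sample" & !is.na(plates$compound_id), ]
    st <- control_stats(plates[plates$cell_line == line &
                                 plates$effector_uM == eff, ])
    p$pct_i <- percent_inhibition(p$signal, st$mu_high, st$mu_low)
    w <- stats::reshape(p[, c("compound_id", "replicate", "pct_i")],
                        idvar = "compound_id", timevar = "replicate",
                        direction = "wide")
    r2 <- tryCatch(replicate_concordance(w$pct_i.1, w$pct_i.2),
                   error = function(e) NA)
    cat(sprintf("  %s %3g uM: duplicate R^2 = %.3f\n", line, eff, r2))
  }
}

prof <- screen_profiles(plates)
utils::write.csv(prof, "results/screen_scatter.csv", row.names = FALSE)
ref <- refine_across_cell_lines(prof, "Y79", "RB355")
utils::write.csv(ref$agonists, "results/hits_agonists.csv", row.names = FALSE)
utils::write.csv(ref$antagonists, "results/hits_antagonists.csv",
                 row.names = FALSE)
cat(sprintf("Selected %d agonist and %d antagonist candidates after",
            nrow(ref$agonists), nrow(ref$antagonists)), "refinement\n")

truth <- utils::read.csv("simdata/truth_screen.csv")
ta <- truth$compound_id[truth$class == "agonist"]
tn <- truth$compound_id[truth$class == "antagonist"]
sens <- (sum(ref$agonists$compound_id %in% ta) +
           sum(ref$antagonists$compound_id %in% tn)) /
  (length(ta) + length(tn))
fp <- sum(!ref$agonists$compound_id %in% ta) +
  sum(!ref$antagonists$compound_id %in% tn)
cat(sprintf("Against planted truth: sensitivity %.3f, %d false positive(s)\n",
            sens, fp))
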