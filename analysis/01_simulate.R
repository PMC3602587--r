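#!/usr/bin/env Rscript
# Simulates the full synthetic screening campaign: a 6,912-compound library
# in duplicate against two retinoblastoma cell lines with and without the
# companion effector (88 agonists and 67 antagonists planted), a dedicated
# control run, follow-up dose-response series across a five-line panel,
# a nephelometry turbidity series, growth-kinetics curves and nuclei images.
# Writes simdata/ plus the ground-truth manifest.

library(effectorscreen)

# 5% well-level CV: a typical fluorescence HTS noise level, so the campaign
# exercises the pipeline under realistic rather than idealized conditions.
cfg <- run_config(seed = 20260929, n_compounds = 6912,
                  planted = c(agonist = 88, antagonist = 67),
                  noise_cv = 5, dr_noise_sd = 2)
paths <- run_simulate(cfg, "simdata")

cat("Simulated dataset written to simdata/\n")
cat(sprintf("  %d compounds, planted: %s\n", cfg$n_compounds,
            paste(names(cfg$planted), cfg$planted, collapse = ", ")))
cat(sprintf("  %d files, seed %d\n", length(paths), cfg$seed))
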