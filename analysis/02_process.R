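#!/usr/bin/env Rscript
# Stage 2 — run the propulsion-extraction pipeline.
#
# Summarizes per-step propulsion peak (N/kg) and impulse (N/kg*s) into
# per-condition means, applies the step-count and participant exclusion
# rules (>= 23 valid steps per leg per condition; a participant with two or
# more failing conditions is excluded), computes propulsion symmetry, and
# writes the long-format observation table for the mixed models.

suppressMessages(library(propulsr))

cfg <- load_run_config()
cfg$outdir <- "results"
cfg$seed <- 20260930L

obs <- run_process(cfg)

cat(sprintf("observation table: %d rows, %d participants\n",
            nrow(obs), length(unique(obs$participant_id))))
cws_rows <- obs$is_cws & obs$leg == "paretic"
cat(sprintf("stroke symmetry at CWS: peak %.2f, impulse %.2f (cohort means)\n",
            mean(obs$peak_symmetry[cws_rows], na.rm = TRUE),
            mean(obs$impulse_symmetry[cws_rows], na.rm = TRUE)))
cat("wrote observations.csv, exclusion_report.csv, step_audit.csv\n")
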