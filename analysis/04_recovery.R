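#!/usr/bin/env Rscript
# Stage 4 — parameter-recovery summary.
#
# The study deposited no raw data, so validity rests on recovery: cohorts
# are generated with the documented fixed effects and random-effect SDs,
# run through the full pipeline, and refitted; the Monte-Carlo mean of each
# estimate should sit on its generative value. This is a reduced version
# (20 replicates) of the check in scripts/acceptance.R.

suppressMessages(library(propulsr))

params <- default_params()
nrep <- 20L
est <- function(f, term) f$fixed$estimate[f$fixed$term == term]

rows <- vector("list", nrep)
for (r in seq_len(nrep)) {
  ds <- generate_cohort(params, "stroke", seed = child_seed(424242L, r),
                        mode = "metrics")
  obs <- process_dataset(ds)$observations
  fi <- fit_symmetry_model(obs, "impulse", "stroke", df_method = "none")
  fl <- suppressWarnings(fit_leg_model(obs, "impulse", df_method = "none"))
  fn <- fit_per_leg_posthoc(obs, "peak", "non_paretic", df_method = "none")
  fp <- fit_per_leg_posthoc(obs, "peak", "paretic", df_method = "none")
  rows[[r]] <- data.frame(
    quantity = c("impulse_symmetry_speed", "impulse_symmetry_interaction",
                 "impulse_speed", "impulse_leg",
                 "peak_slope_non_paretic", "peak_slope_paretic"),
    estimate = c(est(fi, "speed"), est(fi, "speed:sym_cws"),
                 est(fl, "speed"), est(fl, "leg_paretic"),
                 est(fn, "speed"), est(fp, "speed")),
    replicate = r)
}
all <- do.call(rbind, rows)
summ <- aggregate(estimate ~ quantity, all,
                  function(x) c(mean = mean(x), sd = sd(x)))
summ <- data.frame(quantity = summ$quantity,
                   mc_mean = summ$estimate[, "mean"],
                   mc_sd = summ$estimate[, "sd"])
summ$generative <- c(0.12, -0.12, 0.39, -0.715, 1.6, 1.2)[
  match(summ$quantity, c("impulse_speed", "impulse_leg",
                         "impulse_symmetry_speed",
                         "impulse_symmetry_interaction",
                         "peak_slope_non_paretic", "peak_slope_paretic"))]
write.csv(summ, "results/recovery_summary.csv", row.names = FALSE)
print(summ, digits = 3)
cat("\nwrote results/recovery_summary.csv\n")
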