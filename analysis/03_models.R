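#!/usr/bin/env Rscript
# Stage 3 — fit the mixed-model suite.
#
# Fits the symmetry models (gait speed x symmetry-at-CWS, random intercept
# and speed slope per participant), the per-leg speed-by-leg models, the
# control models, and — when the speed-by-leg interaction is significant —
# the per-leg post-hoc fits. Kenward-Roger degrees of freedom. Writes the
# fit JSON, a human-readable report, and residual diagnostics.

suppressMessages(library(propulsr))

cfg <- load_run_config()
cfg$outdir <- "results"
cfg$seed <- 20260930L
cfg$df_method <- "kenward-roger"

fits <- suppressWarnings(run_model(cfg))

cat("fitted models:", paste(names(fits)[!vapply(fits, is.null, TRUE)],
                            collapse = ", "), "\n\n")
show <- function(name, term, label) {
  f <- fits[[name]]
  if (is.null(f)) return(invisible())
  fx <- f$fixed[f$fixed$term == term, ]
  cat(sprintf("%-46s beta = %8.3g  SE = %.2g  t = %.3g(%.1f)  p = %.3g\n",
              label, fx$estimate, fx$se, fx$t, fx$df, fx$p))
}
show("symmetry_peak_stroke", "speed", "peak symmetry ~ speed (stroke)")
show("symmetry_impulse_stroke", "speed", "impulse symmetry ~ speed (stroke)")
show("symmetry_impulse_stroke", "speed:sym_cws",
     "impulse symmetry: speed x symmetry-at-CWS")
show("leg_peak", "speed:leg_paretic", "peak: speed x leg interaction")
show("posthoc_peak_non_paretic", "speed", "peak ~ speed, non-paretic leg")
show("posthoc_peak_paretic", "speed", "peak ~ speed, paretic leg")
show("leg_impulse", "speed", "impulse ~ speed (both legs)")
show("leg_impulse", "leg_paretic", "impulse: paretic leg effect")
show("control_peak", "speed", "control peak ~ speed")
show("control_impulse", "speed", "control impulse ~ speed")

# residual diagnostics for the primary models
diag_rows <- list()
for (nm in names(fits)) {
  f <- fits[[nm]]
  if (is.null(f)) next
  d <- compute_diagnostics(f)
  diag_rows[[nm]] <- data.frame(model = nm, shapiro_w = d$shapiro_w,
                                shapiro_p = d$shapiro_p,
                                resid_sd = sd(d$residuals))
}
write.csv(do.call(rbind, diag_rows), "results/diagnostics_summary.csv",
          row.names = FALSE)

dir.create("results/figures", showWarnings = FALSE)
f <- fits$symmetry_impulse_stroke
if (!is.null(f)) {
  d <- compute_diagnostics(f)
  grDevices::png("results/figures/impulse_symmetry_diagnostics.png",
                 width = 900, height = 320)
  op <- par(mfrow = c(1, 3))
  plot(d$qq$theoretical, d$qq$sample, xlab = "theoretical quantiles",
       ylab = "standardized residuals", main = "Q-Q"); abline(0, 1, lty = 2)
  hist(d$residuals, main = "residuals", xlab = "residual")
  plot(d$fitted, d$residuals, xlab = "fitted", ylab = "residual",
       main = "residuals vs fitted"); abline(h = 0, lty = 2)
  par(op); grDevices::dev.off()
  cat("\nwrote results/figures/impulse_symmetry_diagnostics.png\n")
}
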