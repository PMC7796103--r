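#!/usr/bin/env Rscript
# Full pipeline on a synthetic trial set: simulate -> digitize ->
# reconstruct -> endpoints -> pool -> PH diagnostics -> surrogacy.
#
# Uses the generator defaults (hazards calibrated to pooled ICI trials in
# advanced HCC: median PFS ~4.9, median OS ~15.4 months; PFS more
# heterogeneous across trials than OS) with a trial-level surrogacy
# correlation of 0.7. Writes the rendered report tables under
# results/pipeline/.
#
# Finding: pooled medians recover the generator's scale, per-arm hazards
# between PFS and OS are strongly non-proportional (the PFS hazard acts
# early, the OS hazard late), and the RMST-based surrogacy fits show the
# expected intermediate R2 for rho ~ 0.7.

library(surromet)
dir.create("results", showWarnings = FALSE)

report <- run_pipeline(list(
  seed = 20260922,
  sim = list(n_trials = 12, arms_per_trial = 1, n_per_arm = 300,
             trial_effect_corr = 0.7)))
print(report)
render_tables(report, "results/pipeline", format = "csv")
cat("\nPH summary: non-proportional hazards in",
    format_pct(report$ph$nonph_pct), "% of arms\n")
cat("AIC-selected time function for the pooled endpoint contrast:",
    report$ph$pooled$chosen_time_fn, "\n")
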