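#!/usr/bin/env Rscript
# Trial-level R2 recovery across surrogacy strengths.
#
# Simulates trial sets at trial-level correlations rho^2 in {0, 0.5, 0.9}
# (20 trials, 500 patients/arm) and regresses arm-level 12-month OS RMST on
# PFS RMST with sample-size weights, replicating 50 times per setting.
# Writes results/surrogacy_recovery.csv.
#
# Finding: mean estimated R2 tracks rho^2 (slight upward shift at rho^2 = 0
# from residual structural coupling of the endpoints plus small-sample bias;
# slight attenuation at high rho^2 from within-trial estimation noise).

library(surromet)
dir.create("results", showWarnings = FALSE)

rows <- list()
for (rho2 in c(0, 0.5, 0.9)) {
  r2s <- vapply(1:50, function(i) {
    cfg <- sim_config(n_trials = 20, arms_per_trial = 1, n_per_arm = 500,
                      trial_effect_corr = sqrt(rho2),
                      seed = 50000 * round(10 * rho2) + i)
    set <- simulate_trial_set(cfg)
    x <- vapply(set, function(z) rmst(km_estimate(z$ipd_pfs), 12)$value,
                numeric(1))
    y <- vapply(set, function(z) rmst(km_estimate(z$ipd_os), 12)$value,
                numeric(1))
    weighted_linear_fit(x, y, rep(500, length(x)))$r2
  }, numeric(1))
  rows[[as.character(rho2)]] <- data.frame(
    rho2 = rho2, mean_r2 = mean(r2s), sd_r2 = sd(r2s), n_reps = length(r2s))
}
rec <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
write.csv(rec, "results/surrogacy_recovery.csv", row.names = FALSE)
print(rec, digits = 3)
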