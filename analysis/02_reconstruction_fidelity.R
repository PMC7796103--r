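#!/usr/bin/env Rscript
# Reconstruction fidelity of the Guyot inversion under emulated digitization.
#
# Simulates exponential arms, digitizes their KM curves (grid sampling +
# rounding, quarterly numbers-at-risk), reconstructs pseudo-IPD, and measures
# sup-norm deviation and event-count error across rounding precisions.
# Writes results/reconstruction_fidelity.csv.
#
# Finding: at 3-4 decimal rounding the reconstructed curves stay within
# ~0.01-0.02 sup-norm of the originals with exact risk-table conservation;
# fidelity degrades as rounding coarsens to 2 decimals.

library(surromet)
dir.create("results", showWarnings = FALSE)
set.seed(20260922)

rows <- list()
for (rounding in c(4, 3, 2)) {
  for (rep_i in 1:10) {
    t <- rexp(200, 0.1)
    cens <- 24 - runif(200, 0, 12)
    ipd0 <- pseudo_ipd("sim", "OS", pmin(t, cens), t <= cens)
    km0 <- km_estimate(ipd0)
    curve <- digitize(km0, grid_step = 0.25,
                      risk_times = seq(0, floor(km0$max_followup), 3),
                      rounding = rounding)
    rep <- validate_reconstruction(reconstruct(curve), curve)
    rows[[length(rows) + 1L]] <- data.frame(
      rounding = rounding, rep = rep_i, sup_norm = rep$sup_norm,
      events_error = abs(rep$events_delta),
      risk_conserved = all(rep$risk_match))
  }
}
fid <- do.call(rbind, rows)
write.csv(fid, "results/reconstruction_fidelity.csv", row.names = FALSE)
agg <- aggregate(sup_norm ~ rounding, fid, mean)
cat("mean sup-norm by rounding precision:\n")
print(agg)
cat("risk tables conserved in all runs:", all(fid$risk_conserved), "\n")
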