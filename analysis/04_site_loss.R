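#!/usr/bin/env Rscript
# Photoinduced site loss and its suppression by domain redundancy.
#
# Per-event domain inactivation with probability q is calibrated (closed
# form) so that 1x tiles lose 12.1% of detectable sites between the first
# and second 20,000-frame windows; the same q applied to 10x tiles at
# [I]/10 (identical total per-site event rate) predicts the protected loss.
# Writes results/site_loss.csv (per-seed) and prints the summary.

library(repaintsim)
dir.create("results", showWarnings = FALSE)

lambda <- default_imager()$k_on * 0.4e-9
q <- calibrate_inactivation(0.121, lambda, 2000)
cat(sprintf("calibrated per-event inactivation q = %.4f\n", q))

n_seeds <- 20
rows <- lapply(seq_len(n_seeds), function(s) {
  r1 <- scenario_site_loss(q, 1, 0.4e-9, n_tiles = 300, seed = 100 + s)
  r10 <- scenario_site_loss(q, 10, 0.04e-9, n_tiles = 300, seed = 200 + s)
  data.frame(seed = s, loss_1x = r1$percent_loss,
             loss_10x = r10$percent_loss)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/site_loss.csv", row.names = FALSE)
cat(sprintf("1x RD:  %.2f +/- %.2f %% loss (mean +/- SD over %d seeds)\n",
            mean(tab$loss_1x), sd(tab$loss_1x), n_seeds))
cat(sprintf("10x RD: %.2f +/- %.2f %% loss — %.0f-fold suppression\n",
            mean(tab$loss_10x), sd(tab$loss_10x),
            mean(tab$loss_1x) / mean(tab$loss_10x)))
cat(sprintf("closed-form expectation for 10x: %.2f %%\n",
            100 * expected_site_loss(lambda, 10, q, c(0, 2000), c(2000, 4000))))
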