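#!/usr/bin/env Rscript

# Step 1: generate the working datasets.
#
# Two synthetic effect-size tables in the layout of a nudge-unit trial
# archive (one estimated effect in percentage points per row, with its
# standard error, trial and domain labels):
#   (a) "complete"  — comprehensively reported: 2-component mixture truth,
#                     no suppression;
#   (b) "suppressed" — same truth, but negative estimates are reported with
#                     probability omega = 0.2 (sign-mechanism suppression).
# Both use 241 effects at ~1.9 effects per trial. Outputs go to
# results/data/ with latent-truth sidecar tables.

library(selmix)

out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

truth <- mixture_params(weights = c(0.7, 0.3), means = c(0.5, 3.0),
                        taus = c(0.6, 2.5))
truth_sel <- mixture_params(weights = c(0.7, 0.3), means = c(0.5, 3.0),
                            taus = c(0.6, 2.5), omega = 0.2)

complete <- simulate_dataset(sim_config(
  truth = truth, n_target = 241, seed = 20260101,
  domain_labels = c("health", "revenue", "education", "benefits")))
write_simulation(complete, file.path(out_dir, "complete.csv"))

suppressed <- simulate_dataset(sim_config(
  truth = truth_sel, selection = sel_sign(), n_target = 241,
  seed = 20260102,
  domain_labels = c("health", "revenue", "education", "benefits")))
write_simulation(suppressed, file.path(out_dir, "suppressed.csv"))

for (nm in c("complete", "suppressed")) {
  sim <- get(nm)
  s <- summarize_effects(sim$dataset)
  cat(sprintf(
    "%-10s: %d effects in %d trials; mean effect %.2f pp; %d generated\n",
    nm, s$n_effects, s$n_trials, s$mean_effect, sim$n_generated))
}
cat(sprintf("suppressed run discarded %d of %d candidate estimates (%.0f%%)\n",
            suppressed$n_generated - suppressed$n_retained,
            suppressed$n_generated,
            100 * (1 - suppressed$n_retained / suppressed$n_generated)))
cat("datasets written to", out_dir, "\n")
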