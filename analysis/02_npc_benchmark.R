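#!/usr/bin/env Rscript
# Nuclear-pore (Nup96) benchmark.
#
# Simulates 120 NPCs (double ring, 8 corners x 2 sites at 14.3 nm, rings
# 50 nm apart, ~50% labeling), runs the drift-corrected pick/cluster
# pipeline at the 2 px (260 nm) pick radius, pairs corner clusters by
# mutual nearest neighbors, fits the axial two-component mixture, and
# extracts bright/dark kinetics normalized by the expected 16 x 50% = 8
# labeled copies.

suppressMessages(library(paintbench))

seed <- 1L
out <- "results/npc"
res <- run_scenario(scenario_config("npc", seed = seed), out)

cat(sprintf("Corner-pair distance: %.2f nm (design: 14.3 nm; %d pairs)\n",
            res$pair_distance, res$n_pairs))
cat(sprintf("Ring separation (z mixture fit): %.2f nm (design: 50 nm)\n",
            res$ring_separation))
ks <- res$kinetics
cat(sprintf("Kinetics over %d pores: tau_b = %.3f s, tau_d(norm) = %.1f s\n",
            ks$n_picks, ks$tau_b, ks$tau_d_norm))
cat(sprintf("  -> k_off = %.2f /s, k_on = %.2e /(M s) (truth: %.1f /s, %.1e)\n",
            ks$k_off, ks$k_on, res$config$k_off, res$config$k_on))
# The benchmark normalization rule (16 copies x 50% = 8 effective sites)
# undercounts the double-ring geometry, which carries 2 x 16 copies and
# so ~16 labeled sites per pore; with the geometric count the recovered
# association rate doubles back onto truth:
geo <- estimate_rates(kinetics_summary(ks$tau_b, ks$tau_d_raw,
                                       ks$c_pM, n_sites = 32 * 0.5))
cat(sprintf("  with the geometric site count (32 x 50%% = 16): k_on = %.2e /(M s)\n",
            geo$k_on))
cat("Tables written under", out, "\n")
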