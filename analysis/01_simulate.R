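#!/usr/bin/env Rscript
# Stage 1: build the ground-truth cohort.
#
# The study cohort is synthetic: a DHS-like two-stage sample of ~400
# enumeration-area clusters with on average 8 children aged 6-59 months
# each. Fixed effects are the published joint-model point estimates; the
# random-effect covariance uses the published variances (0.104, 0.314) with
# the cross covariance capped at the positive-semidefinite boundary (the
# printed 1.000 is incompatible with the printed variances). Haemoglobin,
# HAZ and altitude are backfilled consistently with the simulated outcomes
# so the derivation stage can be exercised end to end.

suppressPackageStartupMessages(library(bivglmm))

seed <- 1L
config <- analysis_config(seed = seed)
dir.create("results", showWarnings = FALSE)

truth <- default_truth(n_clusters = 400, mean_children = 8, seed = seed)
cohort <- simulate_cohort(truth)
cohort <- backfill_biomarkers(cohort, config, seed = seed)
# drop the generator's outcome columns: stage 2 re-derives them from the
# biomarkers, as with real survey data
cohort$stunted <- NULL
cohort$anaemic <- NULL

write_children_table(cohort, "results/cohort.csv")
write_run_manifest("results/simulation_manifest.json", seed, config,
                   extra = list(
                     n_children = nrow(cohort),
                     n_clusters = truth$n_clusters,
                     sigma = list(sigma11 = truth$Sigma[1, 1],
                                  sigma12 = truth$Sigma[1, 2],
                                  sigma22 = truth$Sigma[2, 2])))

cat(sprintf("Simulated %d children in %d clusters -> results/cohort.csv\n",
            nrow(cohort), truth$n_clusters))
cat(sprintf("Ground truth: sigma11 = %.3f, sigma22 = %.3f, sigma12 = %.4f (PSD-capped)\n",
            truth$Sigma[1, 1], truth$Sigma[2, 2], truth$Sigma[1, 2]))
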