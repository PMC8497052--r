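#!/usr/bin/env Rscript
# Emergence of a community in the spatially decoupled model at
# P = 180 mm/y: competitive exclusion without mutations versus a
# finite-width mutation-selection equilibrium with slow trait diffusion.
#
# Writes: results/emergence_metrics.csv, results/emergence_distributions.csv

library(drycomm)
dir.create("results", showWarnings = FALSE)

em <- run_emergence(params = dc_params(P = 180), Dchi_values = c(0, 1e-6),
                    N = 128, t_end = 1e7)

tab <- do.call(rbind, lapply(names(em$results), function(nm) {
  r <- em$results[[nm]]
  cbind(data.frame(Dchi = sub("Dchi_", "", nm),
                   n_occupied = r$n_occupied,
                   n_above_threshold = r$n_above_threshold),
        r$metrics)
}))
write.csv(tab, "results/emergence_metrics.csv", row.names = FALSE)
print(tab, digits = 4)

dists <- data.frame(
  chi = (1:128) / 128,
  B_Dchi0 = em$results[[1]]$run$B,
  B_Dchi1e6 = em$results[[2]]$run$B)
write.csv(dists, "results/emergence_distributions.csv", row.names = FALSE)

cat(sprintf("\nWithout mutations %d bin(s) hold the biomass (competitive
exclusion); with Dchi = 1e-6 the stationary community spans %d bins
above the seedling density threshold (FR = %.2f).\n",
            em$results[[1]]$n_occupied,
            em$results[[2]]$n_above_threshold,
            em$results[[2]]$metrics$FR))
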