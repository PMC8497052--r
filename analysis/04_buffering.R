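#!/usr/bin/env Rscript
# Buffering of community structure by spatial re-patterning: once a
# patterned community exists, further drying thins the vegetation
# patches or removes patches (wavelength transitions) while composition
# and richness stay almost unchanged.  Run at N = 64 groups to keep the
# ~10-stage sweep to a few minutes per stage.
#
# Writes: results/buffering_branch.csv

library(drycomm)
dir.create("results", showWarnings = FALSE)
params <- dc_params(N = 64)

## converged patterned community at 80 mm/y (downshift protocol)
ds <- run_downshift(P_sequence = c(100, 80), params = params, N = 64,
                    nx = 128, seed = 1, t_uniform = 1e7, t_spatial = 2e5)
start <- ds$stages[[2]]$run$state

bf <- run_buffering(P_sweep = seq(80, 45, by = -5), params = params,
                    N = 64, start_state = start, nx = 128, seed = 1,
                    t_per_stage = 2e5)
write.csv(bf$table, "results/buffering_branch.csv", row.names = FALSE)
print(bf$table, digits = 4)

tab <- bf$table[bf$table$event != "collapse" & !is.na(bf$table$chi_max), ]
cat(sprintf("\nAcross %d stages spanning %g-%g mm/y the modal trait moves
by only %.3f and richness by %.3f, while patch width falls from %.1f to
%.1f m: spatial self-organisation absorbs the stress.\n",
            nrow(tab), max(tab$P), min(tab$P),
            diff(range(tab$chi_max)), diff(range(tab$FR)),
            max(tab$patch_width, na.rm = TRUE),
            min(tab$patch_width, na.rm = TRUE)))
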