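#!/usr/bin/env Rscript
# smFRET burst analysis on synthetic usALEX photon streams.
#
# Simulates apo-like (E* 0.51) and holo-like (E* 0.68) measurements,
# detects bursts, fits the FRET populations, computes the
# outside-the-main-population fraction, runs burst variance analysis on a
# static and a dynamic control, and fits a Hill (n = 1) titration.

suppressMessages(library(bindmech))
dir.create("results", showWarnings = FALSE)
seed <- 7041776

analyse <- function(label, E, seed) {
  cfg <- sim_config(seed = seed, E1 = E, E2 = NULL)
  st <- simulate_photon_stream(cfg, 4)
  b <- all_photon_burst_search(st)
  da <- b$E_star[b$S_star > 0.3 & b$S_star < 0.8 & is.finite(b$E_star)]
  fit <- fit_population_gaussian(da, 1)
  data.frame(state = label, E_true = E, n_bursts = length(da),
             E_mean = fit$mean, sigma = fit$sigma,
             outside_pct = 100 * fraction_outside(da, fit, 1))
}
pops <- rbind(analyse("apo", 0.51, seed), analyse("holo", 0.68, seed + 1))
write.csv(pops, "results/smfret_populations.csv", row.names = FALSE)
cat("FRET populations (all-photon burst search, S* gate 0.3-0.8):\n")
print(pops, row.names = FALSE, digits = 3)

# burst variance analysis: static calibration and a dynamic positive
# control switching between E 0.4 and 0.6 at 1000 s^-1
static_cfg <- sim_config(seed = seed + 2, E1 = 0.5, E2 = NULL,
                         background = c(DD = 100, DA = 60, AA = 80))
bs <- bva(all_photon_burst_search(simulate_photon_stream(static_cfg, 4)),
          n = 5)
dyn_cfg <- sim_config(seed = seed + 3, E1 = 0.4, E2 = 0.6,
                      k_12 = 1000, k_21 = 1000)
bd <- bva(dual_channel_burst_search(simulate_photon_stream(dyn_cfg, 20)),
          n = 5)
bva_tab <- rbind(
  data.frame(control = "static", n_bursts = nrow(bs),
             mean_sd = mean(bs$sd_E),
             mean_semicircle = mean(bs$semicircle),
             excess = mean(bs$sd_E - bs$semicircle),
             excess_se = sd(bs$sd_E - bs$semicircle) / sqrt(nrow(bs))),
  data.frame(control = "dynamic", n_bursts = nrow(bd),
             mean_sd = mean(bd$sd_E),
             mean_semicircle = mean(bd$semicircle),
             excess = mean(bd$sd_E - bd$semicircle),
             excess_se = sd(bd$sd_E - bd$semicircle) / sqrt(nrow(bd))))
write.csv(bva_tab, "results/smfret_bva.csv", row.names = FALSE)
cat("\nBurst variance analysis (window n = 5):\n")
print(bva_tab, row.names = FALSE, digits = 3)
cat(sprintf("  dynamic control exceeds the semicircle by %.1f SE\n",
            bva_tab$excess[2] / bva_tab$excess_se[2]))

# Hill titration at the ITC-scale affinity
ladder <- c(7.8, 15.6, 31.25, 62.5, 125, 250, 500, 1000) * 1e-9
tt <- simulate_titration(35e-9, ladder, n_bursts_per_point = 500,
                         seed = seed + 4)
hf <- hill_titration_fit(tt$L, tt$fraction_closed)
tt$fit <- tt$L / (hf$K_d + tt$L)
write.csv(tt, "results/smfret_titration.csv", row.names = FALSE)
cat(sprintf("\nHill (n = 1) titration: K_d = %.1f +/- %.1f nM (truth 35)\n",
            1e9 * hf$K_d, 1e9 * hf$K_d_se))
cat("wrote results/smfret_populations.csv, results/smfret_bva.csv,",
    "results/smfret_titration.csv\n")
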