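#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input used by the downstream stages.
# All randomness is seeded; rerunning reproduces the files byte for byte.
suppressPackageStartupMessages(library(pentarho))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

scheme <- olpvrii_photocycle_scheme()

# Flash-photolysis matrix on the default grids (330-730 nm / 0.7 us - 1 s):
# one noiseless reference and one at SNR 100 (single-acquisition noise,
# 25-pulse averaging).
ds0 <- gen_photocycle_dataset(scheme)
sigma <- max(abs(ds0$delta_a)) / 100
ds <- gen_photocycle_dataset(scheme, noise = noise_spec(sigma, seed = 1))
write_trace_csv(ds0, "results/data/photocycle_noiseless.csv")
write_trace_csv(ds, "results/data/photocycle_snr100.csv")

# pH-series absorption spectra for both protonation transitions at SNR 50.
ph_acid <- seq(1.93, 7.58, length.out = 20)
ph_alk <- seq(7.58, 12.93, length.out = 20)
spa0 <- gen_titration_spectra(3.34, mode = "acceptor", ph_grid = ph_acid)
spb0 <- gen_titration_spectra(10.36, mode = "rsb", ph_grid = ph_alk)
spa <- gen_titration_spectra(3.34, mode = "acceptor", ph_grid = ph_acid,
                             noise_sigma = max(abs(spa0$spectra)) / 50,
                             seed = 2)
spb <- gen_titration_spectra(10.36, mode = "rsb", ph_grid = ph_alk,
                             noise_sigma = max(abs(spb0$spectra)) / 50,
                             seed = 3)
write_spectra_csv(spa, "results/data/titration_acidic.csv")
write_spectra_csv(spb, "results/data/titration_alkaline.csv")

# Flash-induced BLM photocurrent: four components with the printed time
# constants (positive rise, negative decay) at SNR 50.
taus_blm <- c(24e-6, 6e-3, 90e-3, 950e-3)
comps <- cbind(c(1, 0.8, -0.8, -0.6), taus_blm)
tg <- 10^seq(log10(2e-6), 1, by = 0.04)
tr0 <- gen_photocurrent(comps, tg)
tr <- gen_photocurrent(comps, tg,
                       noise_sigma = max(abs(tr0$current)) / 50, seed = 4)
write_current_csv(tr, "results/data/blm_current.csv")

# Stand-in pentamer: ideal C5 assembly with the 2.212 A water pentagon,
# protein atoms jittered to reproduce the deposited model's 0.17-0.20 A
# inter-protomer RMSD.
pent <- gen_ideal_pentamer(pentagon_radius = 2.212, jitter_sd = 0.075,
                           seed = 11)
write_structure(pent, "results/data/pentamer.pdb")

# Cylinder-confined particle ensembles: a water-like uniform profile and
# cation/anion profiles built from Gaussian barriers on opposite ends of
# the pore (lower anion barrier on the cytoplasmic side).
edges <- seq(-20, 20, by = 1)
centers <- (edges[-1] + edges[-length(edges)]) / 2
rt <- 1.9872e-3 * 310
g_cat <- 1.5 * exp(-((centers + 12) / 4)^2) +
         0.4 * exp(-((centers - 12) / 4)^2)
g_an <- 0.4 * exp(-((centers + 12) / 4)^2) +
        1.5 * exp(-((centers - 12) / 4)^2)
ps_w <- gen_pore_particles(edges, rep(1, length(centers)), 8, 1500, 120,
                           seed = 21, species = "water")
ps_cat <- gen_pore_particles(edges, exp(-g_cat / rt), 8, 1500, 120,
                             seed = 22, species = "cation")
ps_an <- gen_pore_particles(edges, exp(-g_an / rt), 8, 1500, 120,
                            seed = 23, species = "anion")
write_particles_csv(ps_w, "results/data/particles_water.csv")
write_particles_csv(ps_cat, "results/data/particles_cation.csv")
write_particles_csv(ps_an, "results/data/particles_anion.csv")

cat("wrote synthetic inputs to results/data/\n")
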