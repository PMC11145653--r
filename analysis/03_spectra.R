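#!/usr/bin/env Rscript
# Absorption and fluorescence spectra of the CP24 model: secular Redfield
# (with lifetime broadening) and pure second-order cumulant absorption,
# both from the packaged Hamiltonian plus the synthetic average spectral
# density of 02_spectral_densities.R.
#
# Transition-dipole orientations are synthetic (fixed seed, unit random
# directions) with the experimental magnitudes 5.7 D (Chl-a) and 4.6 D
# (Chl-b); no published orientations are reproduced here. Spectra are
# peak-normalized; no rigid shift is applied.

library(excitonkit)
dir.create("results", showWarnings = FALSE)

h <- table2_fixture()
basis <- diagonalize(h)
set.seed(5)
dirs <- matrix(rnorm(33), 11, 3)
dirs <- dirs / sqrt(rowSums(dirs^2))
mags <- ifelse(grepl("^a", h$labels), 5.7, 4.6)
basis <- exciton_dipoles(basis, dirs * mags)

traj <- gen_site_trajectory(noise_model(seed = 101), 2e5, dt = 1,
                            n_sites = 11, labels = h$labels)
Jbar <- average_sd(spectral_density(traj, 300))
lambda_bar <- unname(reorganization_energy(Jbar))

g <- lineshape_g(Jbar, 300, tgrid = seq(0, 1500, by = 1.5))
ex <- exciton_g_and_lambda(g, lambda_bar, basis$coefficients)
rates <- redfield_rates(basis, Jbar, 300)
tau <- lifetimes(rates)
cat(sprintf("exciton lifetimes: %.0f - %.0f fs\n", min(tau), max(tau)))

grid <- seq(14000, 18500, by = 5)
abs_red <- absorption_redfield(basis, ex, tau, grid)
abs_cum <- absorption_cumulant(basis, ex, grid)
flu_red <- fluorescence_redfield(basis, ex, tau, grid, temperature = 300)

write_spectrum(abs_red, "results/absorption_redfield.tsv")
write_spectrum(abs_cum, "results/absorption_cumulant.tsv")
write_spectrum(flu_red, "results/fluorescence_redfield.tsv")

cat(sprintf("absorption peaks: Redfield %.0f cm^-1, cumulant %.0f cm^-1\n",
            grid[which.max(abs_red$intensity)],
            grid[which.max(abs_cum$intensity)]))
cat(sprintf("fluorescence peak: %.0f cm^-1\n",
            grid[which.max(flu_red$intensity)]))

# low-temperature absorption for comparison
g77 <- lineshape_g(Jbar, 77, tgrid = seq(0, 1500, by = 1.5))
ex77 <- exciton_g_and_lambda(g77, lambda_bar, basis$coefficients)
tau77 <- lifetimes(redfield_rates(basis, Jbar, 77))
abs77 <- absorption_redfield(basis, ex77, tau77, grid)
write_spectrum(abs77, "results/absorption_redfield_77K.tsv")
cat(sprintf("77 K absorption peak: %.0f cm^-1\n",
            grid[which.max(abs77$intensity)]))
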