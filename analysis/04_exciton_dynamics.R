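#!/usr/bin/env Rscript
# Ensemble-averaged wave-packet (NISE) exciton dynamics on the CP24 model:
# a 40 ps synthetic site-energy trajectory (OU noise, sigma 710 cm^-1,
# tau_c 50 fs, means from the packaged Hamiltonian) is split into 1000
# overlapping 6 ps realizations; each pigment is excited in turn and the
# ensemble-averaged site populations are followed.
#
# Reported: per-pigment 1/e relaxation times toward the equal-population
# plateau of the pigment's coupling cluster, and the maximum population
# crossing between the two stromal-side clusters.

library(excitonkit)
dir.create("results", showWarnings = FALSE)

h <- table2_fixture()
model <- noise_model(seed = 1)
traj <- gen_site_trajectory(model, n_frames = 40000, dt = 1, n_sites = 11,
                            means = h$energies, labels = h$labels)
traces <- ensemble_dynamics(traj, h$couplings, window_len = 6000, n = 1000)

part <- coupling_clusters(h, threshold = 30)
rows <- lapply(h$labels, function(lab) {
  cl <- cluster_of(part, lab)
  data.frame(pigment = lab, cluster_size = length(cl),
             relaxation_fs = if (length(cl) >= 2)
               relaxation_time(traces[[lab]], cluster_size = length(cl))
             else NA_real_)
})
relax <- do.call(rbind, rows)
print(relax)
write.csv(relax, "results/relaxation_times.csv", row.names = FALSE)
cat(sprintf("max relaxation time in clusters: %.2f ps\n",
            max(relax$relaxation_fs, na.rm = TRUE) / 1000))

# population trace for the fastest-relaxing pigment (a603 -> b609 first)
write_population_trace(traces[["a603"]], "results/population_a603.tsv")

A <- c("b601", "a602", "a603", "b609")
B <- c("b608", "a610", "a611", "a612")
cross <- c(vapply(A, function(l) max_population_on(traces[[l]], B), 1),
           vapply(B, function(l) max_population_on(traces[[l]], A), 1))
cat(sprintf("max stromal inter-cluster crossing within 6 ps: %.3f\n",
            max(cross)))
cat("note: with an independent pure-OU bath all of the fluctuation\n",
    "variance sits at low frequencies, which overestimates inter-cluster\n",
    "transfer relative to a structured (intramolecular-mode) bath.\n")
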