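#!/usr/bin/env Rscript
# Structural descriptors on synthetic chlorophyll-like geometries:
# Mg coordination with the 2.5 Angstrom cutoff and Wc/Wt water
# classification, Mg-Mg distances, RMSF of a jittered trajectory, and
# PCA + K-means representative-frame selection.

library(excitonkit)
dir.create("results", showWarnings = FALSE)

# three toy pigments on a 20 Angstrom grid, one with an axial water each side
pigs <- list(
  toy_pigment("chl-a-like", pose = list(R = diag(3), t = c(0, 0, 0)),
              label = "p1")$structure,
  toy_pigment("chl-b-like", pose = list(R = diag(3), t = c(20, 0, 0)),
              label = "p2")$structure,
  toy_pigment("chl-a-like", pose = list(R = diag(3), t = c(0, 20, 0)),
              label = "p3")$structure
)
waters <- data.frame(resname = "HOH", atom = "O",
                     x = c(0, 20, 0), y = c(0, 0, 20),
                     z = c(-2.1, 2.3, 2.7))
recs <- mg_coordination(pigs, waters, cutoff = 2.5)
for (r in recs) print(r)

d <- mg_distance_matrix(pigs)
write.csv(round(d, 3), "results/mg_distances.csv")
cat(sprintf("mean Mg-Mg distance: %.1f Angstrom\n",
            mean(d[upper.tri(d)])))

# RMSF of an isotropically jittered copy of p1 (sd 0.3 Angstrom)
set.seed(20)
ref <- pigs[[1]]$positions
nf <- 2000
jit <- array(rnorm(nf * nrow(ref) * 3, sd = 0.3), c(nf, nrow(ref), 3)) +
  aperm(array(ref, c(nrow(ref), 3, nf)), c(3, 1, 2))
r <- rmsf(jit)
# the rigid-body fit removes 6 of the 3N fluctuation degrees of freedom
expected <- 0.3 * sqrt(3) * sqrt(1 - 6 / (3 * nrow(ref)))
cat(sprintf("RMSF of jittered toy: mean %.3f Angstrom (expected ~%.3f)\n",
            mean(r), expected))

# representative frames from five synthetic conformational basins
centers <- matrix(rnorm(5 * 9, sd = 25), 5)
frames <- do.call(rbind, lapply(1:5, function(b)
  sweep(matrix(rnorm(60 * 9, sd = 0.5), 60), 2, centers[b, ], "+")))
sel <- select_frames(frames, k = 5, seed = 3)
cat("selected representative frames:", sel, "\n")
writeLines(as.character(sel), "results/selected_frames.txt")
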