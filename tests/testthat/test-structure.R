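# planar toy chlorophyll: ring in the xy-plane, tail below it
toy_struct <- function(tail_z = -1.8, label = "toy") {
  toy_pigment("chl-a-like", label = label)$structure
}

posed_struct <- function(t, R = diag(3), label = "p") {
  toy_pigment("chl-a-like", pose = list(R = R, t = t),
              label = label)$structure
}

test_that("Mg coordination applies the 2.5 Angstrom cutoff and counting rule", {
  st <- toy_struct()
  lig <- data.frame(resname = c("HOH", "HOH"), atom = c("O", "O"),
                    x = c(0, 0), y = c(0, 0), z = c(2.4, 2.6))
  rec <- mg_coordination(st, lig)[[1]]
  expect_equal(nrow(rec$ligands), 1)            # 2.4 in, 2.6 out
  expect_equal(rec$ligands$distance, 2.4)
  expect_equal(rec$coordination_number, 5)

  # no candidates: implicit four ring nitrogens only
  none <- mg_coordination(st, lig[0, ])[[1]]
  expect_equal(none$coordination_number, 4)

  # two waters on opposite sides: six-coordinated, one Wc and one Wt
  lig2 <- data.frame(resname = "HOH", atom = "O",
                     x = c(0, 0), y = c(0, 0), z = c(-2.1, 2.3))
  rec2 <- mg_coordination(st, lig2)[[1]]
  expect_equal(rec2$coordination_number, 6)
  # tail sits at z < 0, so the z = -2.1 water is cis (Wc)
  expect_equal(rec2$ligands$side, c("Wc", "Wt"))
})

test_that("water side classification is geometric and flips under mirroring", {
  st <- toy_struct()                             # tail below the ring plane
  expect_equal(classify_water_side(st, c(0, 0, -2.2)), "Wc")
  expect_equal(classify_water_side(st, c(0, 0, 2.2)), "Wt")
  expect_equal(classify_water_side(st, c(1.2, 0.5, 0.02)), "ambiguous")

  # mirroring the whole structure through the ring plane flips the labels
  mirrored <- st
  mirrored$positions[, 3] <- -mirrored$positions[, 3]
  expect_equal(classify_water_side(mirrored, c(0, 0, -2.2)), "Wt")

  # invariance under a global rotation + translation
  R <- rot_zxz(0.4, 1.1, 2.0)
  t0 <- c(5, -3, 8)
  stR <- posed_struct(t0, R)
  w <- drop(R %*% c(0, 0, -2.2)) + t0
  expect_equal(classify_water_side(stR, w), "Wc")
  recR <- mg_coordination(stR, data.frame(resname = "HOH", atom = "O",
                                          x = w[1], y = w[2], z = w[3]))[[1]]
  expect_equal(recR$coordination_number, 5)
  expect_equal(recR$ligands$distance, 2.2, tolerance = 1e-9)
})

test_that("Mg-Mg distances are Euclidean, symmetric and translation-invariant", {
  s1 <- posed_struct(c(0, 0, 0), label = "p1")
  s2 <- posed_struct(c(3, 4, 0), label = "p2")
  d <- mg_distance_matrix(list(s1, s2))
  expect_equal(d["p1", "p2"], 5)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(p1 = 0, p2 = 0))

  shift <- c(10, -20, 7)
  d2 <- mg_distance_matrix(list(posed_struct(shift, label = "p1"),
                                posed_struct(c(3, 4, 0) + shift, label = "p2")))
  expect_equal(d2, d)
  expect_error(mg_distance_matrix(list(s1)), "at least 2")
})

test_that("RMSF recovers Gaussian jitter and vanishes for rigid motion", {
  n_at <- 60
  set.seed(14)
  ref <- matrix(rnorm(n_at * 3, sd = 5), n_at)

  # static trajectory
  static <- aperm(array(ref, c(n_at, 3, 4)), c(3, 1, 2))
  expect_equal(max(rmsf(static)), 0)

  # rigid-body translated copies vanish after alignment
  shifts <- matrix(rnorm(30), 10)
  trans <- array(0, c(10, n_at, 3))
  for (f in 1:10) trans[f, , ] <- sweep(ref, 2, shifts[f, ], "+")
  expect_lt(max(rmsf(trans)), 1e-8)

  # rigidly rotated copies vanish after alignment too
  rots <- array(0, c(10, n_at, 3))
  for (f in 1:10) rots[f, , ] <- ref %*% t(rot_zxz(f / 10, f / 20, 0))
  expect_lt(max(rmsf(rots)), 1e-6)

  # isotropic Gaussian jitter of sd sigma: RMSF ~ sigma * sqrt(3)
  sigma <- 0.3
  nf <- 1e4
  jit <- array(rnorm(nf * n_at * 3, sd = sigma), c(nf, n_at, 3)) +
    aperm(array(ref, c(n_at, 3, nf)), c(3, 1, 2))
  r <- rmsf(jit)
  expect_lt(max(abs(r - sigma * sqrt(3)) / (sigma * sqrt(3))), 0.05)

  expect_error(rmsf(jit[1, , , drop = FALSE]), "2 frames")
})

test_that("frame selection finds one representative per conformational basin", {
  set.seed(15)
  k <- 5
  centers <- matrix(rnorm(k * 6, sd = 30), k)     # 2 Mg atoms, flattened
  frames_per <- 40
  x <- do.call(rbind, lapply(seq_len(k), function(b)
    sweep(matrix(rnorm(frames_per * 6, sd = 0.5), frames_per), 2,
          centers[b, ], "+")))
  basin <- rep(seq_len(k), each = frames_per)
  sel <- select_frames(x, k = k, seed = 3)
  expect_length(sel, k)
  expect_setequal(basin[sel], seq_len(k))          # one per basin

  # determinism under a fixed seed
  expect_identical(sel, select_frames(x, k = k, seed = 3))

  expect_length(select_frames(x, k = 1, seed = 1), 1)
  expect_error(select_frames(x[1:3, ], k = 5), "exceeds")
})

test_that("pigment structures enforce their geometric invariants", {
  expect_error(pigment_structure(c("C1", "C2", "C3"), diag(3),
                                 mg_atom = "MG", ring_atoms = c("C1", "C2", "C3"),
                                 tail_atom = "C1"), "Mg")
  expect_error(pigment_structure(c("MG", "C1", "C2", "T"),
                                 matrix(rnorm(12), 4),
                                 mg_atom = "MG", ring_atoms = c("C1", "C2"),
                                 tail_atom = "T"), "ring")
})

test_that("pigment structures round-trip through a PDB file", {
  skip_if_not_installed("bio3d")
  p <- toy_pigment("chl-a-like", pose = list(R = diag(3), t = c(3, 2, 1)))
  st <- p$structure
  lines <- vapply(seq_along(st$atom_names), function(i)
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, st$atom_names[i], "CLA", "A", 601L,
            st$positions[i, 1], st$positions[i, 2], st$positions[i, 3]), "")
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  got <- read_pigment_structures(f, resnames = "CLA",
                                 ring_names = paste0("C", 1:12),
                                 tail_name = "C1T")
  expect_length(got, 1)
  expect_equal(mg_position(got[[1]]), mg_position(st), tolerance = 1e-3,
               ignore_attr = TRUE)
  # side classification survives the round trip
  w <- mg_position(st) + c(0, 0, -2.2)
  expect_equal(classify_water_side(got[[1]], w), "Wc")
})
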