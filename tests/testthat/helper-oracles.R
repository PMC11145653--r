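# Independent numerical oracles used to cross-check the package's own
# linear-algebra paths. These deliberately avoid the code under test.

# cyclic Jacobi eigensolver for symmetric matrices (values only)
jacobi_eigenvalues <- function(A, tol = 1e-12, max_sweeps = 50) {
  A <- as.matrix(A)
  n <- nrow(A)
  for (sweep in seq_len(max_sweeps)) {
    off <- sqrt(sum(A[upper.tri(A)]^2))
    if (off < tol) break
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      if (abs(A[p, q]) < 1e-300) next
      theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
      t <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
      if (theta == 0) t <- 1
      c <- 1 / sqrt(t^2 + 1)
      s <- t * c
      G <- diag(n)
      G[p, p] <- c; G[q, q] <- c; G[p, q] <- s; G[q, p] <- -s
      A <- t(G) %*% A %*% G
    }
  }
  sort(diag(A))
}

# complex matrix exponential by scaled-and-squared Taylor series
expm_taylor <- function(A, order = 20, squarings = 12) {
  B <- A / 2^squarings
  X <- diag(1 + 0i, nrow(A))
  term <- X
  for (k in seq_len(order)) {
    term <- term %*% B / k
    X <- X + term
  }
  for (k in seq_len(squarings)) X <- X %*% X
  X
}

# ideal point-dipole coupling in cm^-1 (dipoles in Debye, centers in A)
dipole_coupling_oracle <- function(d1, d2, r1, r2) {
  kc <- excitonkit::exciton_constants$coulomb_cm1_A
  dpe <- excitonkit::exciton_constants$debye_per_eA
  R <- r2 - r1
  Rn <- sqrt(sum(R^2))
  Rh <- R / Rn
  d1e <- d1 / dpe
  d2e <- d2 / dpe
  kc * (sum(d1e * d2e) - 3 * sum(d1e * Rh) * sum(d2e * Rh)) / Rn^3
}

# rotation matrix from z-x-z Euler angles
rot_zxz <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3)
  Rz(a) %*% Rx(b) %*% Rz(c)
}

# random orthonormal matrix (QR of a Gaussian matrix)
random_orthonormal <- function(n) {
  qr.Q(qr(matrix(rnorm(n * n), n)))
}

HBAR <- excitonkit::exciton_constants$hbar_cm1_fs
KB <- excitonkit::exciton_constants$kB_cm1_K

ou_model <- function(sigma = 710, tau_c = 50, seed = 1) {
  noise_model(sigma = sigma,
              modes = list(list(type = "overdamped", tau_c = tau_c,
                                weight = 1)),
              seed = seed)
}

# symmetric dimer Hamiltonian
dimer_h <- function(E = 16000, V = 100) {
  exciton_hamiltonian(matrix(c(E, V, V, E), 2), c("s1", "s2"))
}
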