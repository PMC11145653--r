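om_grid <- seq(0, 3000, by = 5)

test_that("Redfield rates obey detailed balance and the dimer closed form", {
  J <- parametric_sd(list(list(type = "overdamped", lambda = 100, gamma = 100)),
                     omega = om_grid)

  # silent bath: no transfer
  b2 <- diagonalize(dimer_h(16000, 100))
  k0 <- redfield_rates(b2, parametric_sd(list(), om_grid), 300)
  expect_true(all(k0$k == 0))

  # dimer: hand-evaluated downhill rate pi J(2V) (n+1) / hbar
  k <- redfield_rates(b2, J, 300)
  beta <- 1 / (KB * 300)
  Jat <- approx(J$omega, J$J[, 1], xout = 200)$y
  nocc <- 1 / (exp(beta * 200) - 1)
  expect_equal(k$k[1, 2], pi * Jat * (nocc + 1) / HBAR, tolerance = 1e-12)
  # detailed balance, exact
  expect_lt(abs(k$k[2, 1] / k$k[1, 2] - exp(-beta * 200)), 1e-10)

  # detailed balance across all pairs of a larger system
  h <- table2_fixture()
  bb <- diagonalize(h)
  kk <- redfield_rates(bb, J, 300)
  for (mu in 1:10) for (nu in (mu + 1):11) {
    dE <- bb$energies[nu] - bb$energies[mu]
    if (kk$k[mu, nu] == 0) next
    expect_lt(abs(kk$k[nu, mu] / kk$k[mu, nu] - exp(-beta * dE)), 1e-10)
  }

  # transition energy beyond the grid is an extrapolation error
  Jnarrow <- parametric_sd(list(list(type = "overdamped", lambda = 10,
                                     gamma = 10)), seq(0, 100, 5))
  expect_error(redfield_rates(b2, Jnarrow, 300), "grid")
})

test_that("lifetimes are reciprocal total depopulation rates", {
  b2 <- diagonalize(dimer_h(16000, 100))
  k0 <- redfield_rates(b2, parametric_sd(list(), om_grid), 300)
  expect_true(all(is.infinite(lifetimes(k0))))

  J <- parametric_sd(list(list(type = "overdamped", lambda = 100, gamma = 100)),
                     omega = om_grid)
  k <- redfield_rates(b2, J, 300)
  expect_equal(lifetimes(k), c(1 / k$k[2, 1], 1 / k$k[1, 2]))

  # 3-state toy with a fixed printed rate table: row-sum reciprocals
  ktab <- matrix(c(0, 2e-3, 1e-3,
                   4e-3, 0, 5e-4,
                   2e-4, 3e-4, 0), 3, 3, byrow = TRUE)
  rm3 <- structure(list(k = ktab, temperature = 300), class = "rate_matrix")
  expect_equal(lifetimes(rm3), 1 / colSums(ktab))
})

test_that("lineshape function g(t) has the correct limits", {
  tg <- seq(0, 2000, by = 2)
  # silent bath
  g0 <- lineshape_g(parametric_sd(list(), om_grid), 300, tg)
  expect_true(all(g0$g == 0))

  J <- parametric_sd(list(list(type = "overdamped", lambda = 200, gamma = 100)),
                     omega = seq(0, 2500, by = 2))
  g <- lineshape_g(J, 300, tgrid = seq(0, 10, by = 0.5))
  expect_equal(g$g[1, 1], 0 + 0i)

  # short-time: Re g = <d eps^2> t^2 / (2 hbar^2)
  beta <- 1 / (KB * 300)
  om <- J$omega[-1]
  var_eps <- sum(J$J[-1, 1] / tanh(beta * om / 2)) * diff(J$omega[1:2]) / pi
  t0 <- 2
  expect_equal(Re(g$g[g$tgrid == t0, 1]), 0.5 * var_eps * (t0 / HBAR)^2,
               tolerance = 0.01)

  # long-time imaginary drift -lambda t / hbar
  gl <- lineshape_g(J, 300, tgrid = seq(0, 4000, by = 4))
  nt <- length(gl$tgrid)
  slope <- (Im(gl$g[nt, 1]) - Im(gl$g[nt - 1, 1])) / 4
  lam <- unname(reorganization_energy(J))
  expect_equal(slope, -lam / HBAR, tolerance = 1e-3)

  # exact linearity in J
  J3 <- J
  J3$J <- 3 * J3$J
  g3 <- lineshape_g(J3, 300, tgrid = seq(0, 10, by = 0.5))
  expect_equal(g3$g, 3 * g$g, tolerance = 1e-12)

  expect_error(lineshape_g(J, 300, tgrid = seq(10, 100, 10)), "start at 0")
})

test_that("exciton transformation uses |c|^4 participation weighting", {
  J <- parametric_sd(list(list(type = "overdamped", lambda = 120, gamma = 80)),
                     omega = om_grid)
  g <- lineshape_g(J, 300, seq(0, 500, by = 5))

  # localized exciton keeps the site values
  C_loc <- diag(2)
  exl <- exciton_g_and_lambda(g, c(120, 120), C_loc)
  expect_equal(exl$g$g[, 1], g$g[, 1])
  expect_equal(exl$lambda, c(120, 120))

  # symmetric dimer halves lambda
  b <- diagonalize(dimer_h(16000, 100))
  exd <- exciton_g_and_lambda(g, 120, b$coefficients)
  expect_equal(exd$lambda, c(60, 60), tolerance = 1e-12, ignore_attr = TRUE)

  # participation weights sum to the inverse participation ratio <= 1
  set.seed(6)
  C5 <- random_orthonormal(5)
  ex5 <- exciton_g_and_lambda(g, rep(100, 5), C5)
  w <- colSums(C5^4)
  expect_true(all(w <= 1 + 1e-12))
  expect_equal(ex5$lambda, 100 * w, ignore_attr = TRUE)
})

test_that("absorption lineshapes have correct centers, moments and norms", {
  h1 <- exciton_hamiltonian(matrix(16000, 1, 1), "m")
  b1 <- exciton_dipoles(diagonalize(h1), matrix(c(0, 5.7, 0), 1))
  grid <- seq(14000, 18000, by = 2)

  # silent bath, infinite lifetime, tiny damping: delta-like line at E1
  g0 <- lineshape_g(parametric_sd(list(), om_grid), 300, seq(0, 3000, by = 1))
  ex0 <- exciton_g_and_lambda(g0, 0, b1$coefficients)
  sp0 <- absorption_redfield(b1, ex0, Inf, grid, extra_damping_fs = 200)
  expect_lte(abs(grid[which.max(sp0$intensity)] - 16000), diff(grid[1:2]))
  expect_equal(max(sp0$intensity), 1)          # normalized peak exactly 1

  # Drude bath: first moment close to the site energy
  J <- parametric_sd(list(list(type = "overdamped", lambda = 150, gamma = 40)),
                     omega = seq(0, 2500, by = 2))
  g <- lineshape_g(J, 300, seq(0, 1500, by = 1.5))
  lam <- unname(reorganization_energy(J))
  ex <- exciton_g_and_lambda(g, lam, b1$coefficients)
  sp <- absorption_cumulant(b1, ex, grid)
  m1 <- sum(grid * sp$intensity) / sum(sp$intensity)
  expect_lt(abs(m1 - 16000) / 16000, 0.02)

  # integrated area invariant under the rigid shift
  sps <- absorption_cumulant(b1, ex, grid, normalize = FALSE, shift_eV = 0.05)
  spn <- absorption_cumulant(b1, ex, grid, normalize = FALSE)
  expect_equal(sum(sps$intensity), sum(spn$intensity), tolerance = 1e-3)
  # and the peak moves down by the shift
  expect_equal(grid[which.max(spn$intensity)] -
                 grid[which.max(sps$intensity)],
               0.05 * 8065.544, tolerance = diff(grid[1:2]) * 2)
})

test_that("fluorescence obeys Boltzmann weighting and the Stokes shift", {
  expect_equal(sum(boltzmann_populations(c(15900, 16100, 16400), 300)), 1)
  # low temperature: only the lowest exciton contributes
  p_cold <- boltzmann_populations(c(15900, 16100), 1)
  expect_equal(p_cold, c(1, 0), tolerance = 1e-12)

  # monomer Stokes shift ~ 2 lambda for a smooth slow Drude bath
  h1 <- exciton_hamiltonian(matrix(16000, 1, 1), "m")
  b1 <- exciton_dipoles(diagonalize(h1), matrix(c(0, 5.7, 0), 1))
  J <- parametric_sd(list(list(type = "overdamped", lambda = 300, gamma = 15)),
                     omega = seq(0, 2500, by = 5))
  g <- lineshape_g(J, 300, seq(0, 1000, by = 1))
  lam <- unname(reorganization_energy(J))
  ex <- exciton_g_and_lambda(g, lam, b1$coefficients)
  grid <- seq(13000, 19000, by = 2)
  pa <- grid[which.max(absorption_cumulant(b1, ex, grid)$intensity)]
  pf <- grid[which.max(fluorescence_redfield(b1, ex, Inf, grid, 300)$intensity)]
  expect_lt(abs((pa - pf) - 2 * lam) / (2 * lam), 0.10)
})

test_that("cumulant and Redfield absorption coincide for infinite lifetimes", {
  h <- table2_fixture()
  b <- diagonalize(h)
  set.seed(8)
  dirs <- matrix(rnorm(33), 11, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  b <- exciton_dipoles(b, dirs * ifelse(grepl("^a", h$labels), 5.7, 4.6))
  J <- parametric_sd(list(list(type = "overdamped", lambda = 150, gamma = 80)),
                     omega = om_grid)
  g <- lineshape_g(J, 300, seq(0, 1200, by = 2))
  ex <- exciton_g_and_lambda(g, unname(reorganization_energy(J)),
                             b$coefficients)
  grid <- seq(14500, 18500, by = 5)
  s_red <- absorption_redfield(b, ex, Inf, grid)
  s_cum <- absorption_cumulant(b, ex, grid)
  expect_lt(max(abs(s_red$intensity - s_cum$intensity)), 1e-8)
  expect_true(all(s_red$intensity >= 0))
})

test_that("integrated monomer intensity scales with dipole strength", {
  h1 <- exciton_hamiltonian(matrix(16000, 1, 1), "m")
  J <- parametric_sd(list(list(type = "overdamped", lambda = 100, gamma = 60)),
                     omega = om_grid)
  g <- lineshape_g(J, 300, seq(0, 1200, by = 2))
  grid <- seq(14000, 18000, by = 5)
  area <- function(d) {
    b <- exciton_dipoles(diagonalize(h1), matrix(c(0, d, 0), 1))
    ex <- exciton_g_and_lambda(g, unname(reorganization_energy(J)),
                               b$coefficients)
    sum(absorption_cumulant(b, ex, grid, normalize = FALSE)$intensity)
  }
  expect_equal(area(5.7) / area(4.6), (5.7 / 4.6)^2, tolerance = 1e-6)
})

test_that("full pipeline places the CP24 absorption band in the exciton range", {
  h <- table2_fixture()
  b <- diagonalize(h)
  set.seed(5)
  dirs <- matrix(rnorm(33), 11, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  b <- exciton_dipoles(b, dirs * ifelse(grepl("^a", h$labels), 5.7, 4.6))
  tj <- gen_site_trajectory(noise_model(seed = 2), 2e5, dt = 1, n_sites = 11,
                            labels = h$labels)
  Jbar <- average_sd(spectral_density(tj, 300))
  lam <- unname(reorganization_energy(Jbar))
  g <- lineshape_g(Jbar, 300, seq(0, 1500, by = 1.5))
  ex <- exciton_g_and_lambda(g, lam, b$coefficients)
  tau <- lifetimes(redfield_rates(b, Jbar, 300))
  grid <- seq(14000, 18500, by = 5)
  sp <- absorption_redfield(b, ex, tau, grid)
  peak <- grid[which.max(sp$intensity)]
  expect_gte(peak, 15900)
  expect_lte(peak, 16600)
})
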