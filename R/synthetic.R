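#' Noise model for synthetic site-energy fluctuations
#'
#' Describes the stochastic process standing in for QM/MM energy-gap
#' trajectories: Gaussian marginals of standard deviation `sigma` whose
#' correlation structure is a weighted mixture of overdamped
#' (Ornstein-Uhlenbeck, correlation time `tau_c` in fs) and underdamped
#' (damped stochastic oscillator at `omega0` with width `gamma0`, both in
#' cm^-1) components. The default — a single OU mode with sigma = 710
#' cm^-1 (about 0.088 eV, the scale of reported chlorophyll site-energy
#' fluctuations) and tau_c = 50 fs — emulates the dominant fast
#' electrostatic component of a protein bath.
#'
#' @param sigma marginal standard deviation, cm^-1 (>= 0).
#' @param modes list of components: `list(type = "overdamped", tau_c =,
#'   weight =)` or `list(type = "underdamped", omega0 =, gamma0 =,
#'   weight =)`; variance weights must sum to 1.
#' @param seed integer seed making generated trajectories reproducible.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma = 710,
                        modes = list(list(type = "overdamped", tau_c = 50,
                                          weight = 1)),
                        seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  w <- vapply(modes, function(m) m$weight, 1)
  if (abs(sum(w) - 1) > 1e-9) stop("mode weights must sum to 1")
  structure(list(sigma = sigma, modes = modes, seed = as.integer(seed)),
            class = "noise_model")
}

# unit-variance stationary AR recursions for the two mode types
.gen_mode <- function(m, n_frames, dt) {
  type <- match.arg(m$type, c("overdamped", "underdamped"))
  if (type == "overdamped") {
    rho <- exp(-dt / m$tau_c)
    innov <- rnorm(n_frames) * sqrt(1 - rho^2)
    drop(stats::filter(innov, rho, method = "recursive",
                       init = rnorm(1)))         # stationary start
  } else {
    gamma_fs <- m$gamma0 / .HBAR                  # rad/fs damping rate
    omega_fs <- m$omega0 / .HBAR
    osc <- sqrt(max(omega_fs^2 - (gamma_fs / 2)^2, 1e-12))
    r <- exp(-gamma_fs * dt / 2)
    a1 <- 2 * r * cos(osc * dt)
    a2 <- -r^2
    # innovation sd giving unit stationary variance of the AR(2)
    se <- sqrt((1 + a2) * ((1 - a2)^2 - a1^2) / (1 - a2))
    burn <- min(ceiling(20 / (gamma_fs * dt)), 5e4)
    x <- drop(stats::filter(rnorm(n_frames + burn) * se, c(a1, a2),
                            method = "recursive"))
    x[(burn + 1):(burn + n_frames)]
  }
}

#' Generate synthetic site-energy fluctuation trajectories
#'
#' Independent trajectories per site: each is a weighted sum of the model's
#' stationary Gaussian components scaled to marginal standard deviation
#' `sigma`, added to the per-site mean energies. Output is bit-reproducible
#' for a given model seed; the global RNG state is restored on exit.
#'
#' @param model a [noise_model()].
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing, fs.
#' @param n_sites number of independent pigments.
#' @param means mean site energies, cm^-1 (scalar or one per site).
#' @param labels pigment labels.
#' @return A [site_trajectory()].
#' @export
gen_site_trajectory <- function(model, n_frames, dt = 1, n_sites = 1,
                                means = 0, labels = NULL) {
  stopifnot(inherits(model, "noise_model"), n_frames >= 2)
  if (length(means) == 1) means <- rep(means, n_sites)
  if (length(means) != n_sites) stop("need one mean per site")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(model$seed)
  v <- matrix(0, n_frames, n_sites)
  for (s in seq_len(n_sites)) {
    x <- numeric(n_frames)
    if (model$sigma > 0) {
      for (m in model$modes)
        x <- x + sqrt(m$weight) * .gen_mode(m, n_frames, dt)
      x <- x * model$sigma
    }
    v[, s] <- means[s] + x
  }
  site_trajectory(v, dt, labels)
}

#' Analytic spectral density of a noise model
#'
#' The exact spectral density that the estimation convention of
#' [spectral_density()] assigns to the model's stationary process: each OU
#' component maps onto a Drude-Lorentz term with lambda = beta sigma_k^2 /
#' (2 pi), gamma = hbar / tau_c, and each underdamped component onto a
#' Brownian-oscillator term of the same reorganization energy. Useful as
#' the ground truth in parameter-recovery checks.
#'
#' @param model a [noise_model()].
#' @param omega frequency grid, cm^-1.
#' @param temperature temperature, K.
#' @return A [new_spectral_density()].
#' @export
model_spectral_density <- function(model, omega = seq(0, 2500, by = 10),
                                   temperature = 300) {
  beta <- 1 / (.KB * temperature)
  modes <- lapply(model$modes, function(m) {
    lam <- beta * model$sigma^2 * m$weight / (2 * pi)
    if (match.arg(m$type, c("overdamped", "underdamped")) == "overdamped")
      list(type = "overdamped", lambda = lam, gamma = .HBAR / m$tau_c)
    else
      list(type = "underdamped", lambda = lam, omega0 = m$omega0,
           gamma0 = m$gamma0)
  })
  parametric_sd(modes, omega, temperature)
}

#' Packaged time-averaged CP24 exciton Hamiltonian
#'
#' The 11-chlorophyll (six Chl-a, five Chl-b) time-averaged system
#' Hamiltonian of the minor plant antenna complex CP24, shipped as a
#' plain-text fixture (site energies and TrEsp couplings in cm^-1) and
#' symmetrized on load.
#'
#' @return An [exciton_hamiltonian()] with 11 sites.
#' @examples
#' h <- table2_fixture()
#' h$energies[["b601"]]   # 17037.9
#' @export
table2_fixture <- function() {
  parse_hamiltonian(system.file("extdata", "cp24_table2_hamiltonian.csv",
                                package = "excitonkit", mustWork = TRUE))
}

#' Toy chlorophyll-like pigment with transition charges
#'
#' A planar 12-atom ring (radius 2.4 Angstrom) carrying transition charges
#' q_i proportional to sin(phi_i), which produces a net transition dipole
#' along the molecular y axis; the charges are rescaled to 5.7 D
#' (chl-a-like) or 4.6 D (chl-b-like). The returned structure adds a
#' central Mg and an out-of-plane phytyl-tail reference atom so the same
#' toy serves the coordination analysis.
#'
#' @param kind `"chl-a-like"` or `"chl-b-like"`.
#' @param pose list with rotation matrix `R` (3 x 3) and translation `t`
#'   (length 3, Angstrom) applied rigidly to the geometry.
#' @param label pigment label.
#' @return List with `structure` (a [pigment_structure()]) and `charges`
#'   (a rescaled [transition_charge_set()]).
#' @export
toy_pigment <- function(kind = c("chl-a-like", "chl-b-like"),
                        pose = list(R = diag(3), t = c(0, 0, 0)),
                        label = "toy") {
  kind <- match.arg(kind)
  phi <- 2 * pi * (0:11) / 12
  ring <- cbind(2.4 * cos(phi), 2.4 * sin(phi), 0)
  q <- 0.05 * sin(phi)
  pos <- rbind(MG = c(0, 0, 0), ring, TAIL = c(1.5, 0, -1.8))
  names_all <- c("MG", paste0("C", 1:12), "C1T")
  pos <- pos %*% t(pose$R)
  pos <- sweep(pos, 2, pose$t, "+")
  cs <- transition_charge_set(pos[2:13, ], q, names_all[2:13],
                              pigment_type = if (kind == "chl-a-like")
                                "chl-a" else "chl-b")
  list(
    structure = pigment_structure(names_all, pos, mg_atom = "MG",
                                  ring_atoms = paste0("C", 1:12),
                                  tail_atom = "C1T", label = label),
    charges = rescale_charges(cs)
  )
}
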